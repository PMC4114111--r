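# -- drawing primitives ------------------------------------------------------
# Every figure spec is lowered to a flat list of primitives; the SVG writer
# and the PNG device consume the same list, and the SVG output is a pure,
# byte-deterministic function of the primitives.

prim_line <- function(x1, y1, x2, y2, color = "#000000", width = 1,
                      opacity = 1, class = "") {
  list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
       color = color, width = width, opacity = opacity, class = class)
}
prim_polyline <- function(x, y, color = "#000000", width = 1,
                          opacity = 1, class = "") {
  list(kind = "polyline", x = x, y = y, color = color, width = width,
       opacity = opacity, class = class)
}
prim_rect <- function(x, y, w, h, fill, class = "") {
  list(kind = "rect", x = x, y = y, w = w, h = h, fill = fill, class = class)
}
prim_circle <- function(x, y, r, fill, opacity = 1, class = "") {
  list(kind = "circle", x = x, y = y, r = r, fill = fill,
       opacity = opacity, class = class)
}
prim_text <- function(x, y, s, size = 11, anchor = "start", rotate = 0,
                      color = "#000000", class = "") {
  list(kind = "text", x = x, y = y, s = s, size = size, anchor = anchor,
       rotate = rotate, color = color, class = class)
}

assert_finite_prims <- function(prims) {
  for (p in prims) {
    num <- unlist(p[names(p) %in% c("x", "y", "x1", "y1", "x2", "y2",
                                    "w", "h", "r")])
    if (length(num) && any(!is.finite(num)))
      stop_viva("render", "non-finite coordinate reached the drawing layer")
  }
  invisible(TRUE)
}

# -- SVG writer --------------------------------------------------------------

svg_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_write <- function(prims, width, height, path) {
  assert_finite_prims(prims)
  fx <- function(v) fmt_num(v, 2)
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>',
            width, height))
  for (p in prims) {
    cls <- if (nzchar(p$class)) sprintf(' class="%s"', p$class) else ""
    out <- c(out, switch(p$kind,
      line = sprintf(
        '<line%s x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
        cls, fx(p$x1), fx(p$y1), fx(p$x2), fx(p$y2), p$color,
        fx(p$width), fx(p$opacity)),
      polyline = sprintf(
        '<polyline%s points="%s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
        cls, paste(fx(p$x), fx(p$y), sep = ",", collapse = " "),
        p$color, fx(p$width), fx(p$opacity)),
      rect = sprintf(
        '<rect%s x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        cls, fx(p$x), fx(p$y), fx(p$w), fx(p$h), p$fill),
      circle = sprintf(
        '<circle%s cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="%s"/>',
        cls, fx(p$x), fx(p$y), fx(p$r), p$fill, fx(p$opacity)),
      text = {
        tr <- if (p$rotate != 0)
          sprintf(' transform="rotate(%s %s %s)"', fx(p$rotate), fx(p$x), fx(p$y))
        else ""
        sprintf(
          '<text%s x="%s" y="%s" font-family="Helvetica,sans-serif" font-size="%s" text-anchor="%s" fill="%s"%s>%s</text>',
          cls, fx(p$x), fx(p$y), fx(p$size), p$anchor, p$color, tr,
          svg_escape(p$s))
      }))
  }
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# -- PNG writer (secondary format; raster output, not byte-deterministic) ----

png_write <- function(prims, width, height, path) {
  assert_finite_prims(prims)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, width), ylim = c(height, 0),
                        xaxs = "i", yaxs = "i")
  op <- function(o) grDevices::adjustcolor
  for (p in prims) {
    switch(p$kind,
      line = graphics::segments(p$x1, p$y1, p$x2, p$y2,
        col = grDevices::adjustcolor(p$color, alpha.f = p$opacity),
        lwd = p$width),
      polyline = graphics::lines(p$x, p$y,
        col = grDevices::adjustcolor(p$color, alpha.f = p$opacity),
        lwd = p$width),
      rect = graphics::rect(p$x, p$y + p$h, p$x + p$w, p$y,
        col = p$fill, border = NA),
      circle = graphics::symbols(p$x, p$y, circles = rep(p$r, length(p$x)),
        inches = FALSE, add = TRUE, bg = p$fill, fg = NA),
      text = graphics::text(p$x, p$y, p$s, cex = p$size / 12,
        adj = switch(p$anchor, start = 0, middle = 0.5, end = 1),
        srt = -p$rotate, col = p$color))
  }
  invisible(path)
}

# -- figure layout -----------------------------------------------------------

heat_color <- function(r) {
  ramp <- grDevices::colorRamp(c("#313695", "#FFFFFF", "#A50026"))
  out <- rep("#BBBBBB", length(r))
  ok <- is.finite(r)
  if (any(ok)) {
    rgbm <- ramp(pmin(1, pmax(0, (r[ok] + 1) / 2)))
    out[ok] <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3],
                              maxColorValue = 255)
  }
  out
}

legend_prims <- function(legend, x, y) {
  prims <- list()
  for (i in seq_along(legend$levels)) {
    yy <- y + (i - 1) * 18
    prims <- c(prims, list(
      prim_rect(x, yy, 12, 12, legend$colors[i], class = "legend-swatch"),
      prim_text(x + 18, yy + 10,
                sprintf("%s (n=%d)", legend$levels[i], legend$counts[i]),
                size = 11, class = "legend-label")))
  }
  prims
}

layout_visova <- function(spec) {
  p <- length(spec$variables)
  ax_gap <- 110
  margin_l <- 60; margin_r <- 200; margin_t <- 30; margin_b <- 110
  plot_h <- 360
  width <- margin_l + ax_gap * max(1, p - 1) + margin_r
  height <- margin_t + plot_h + margin_b
  ax_x <- margin_l + (seq_len(p) - 1) * ax_gap
  ypos <- function(v) margin_t + (1 - v) * plot_h   # v in [0,1], 1 at top

  prims <- list()
  for (j in seq_len(p)) {
    ax <- spec$axes[[j]]
    cls <- if (isTRUE(ax$degenerate)) "axis degenerate" else "axis"
    prims <- c(prims, list(
      prim_line(ax_x[j], margin_t, ax_x[j], margin_t + plot_h,
                color = "#888888", class = cls),
      prim_text(ax_x[j], margin_t + plot_h + 14, ax$name, size = 10,
                anchor = "end", rotate = -45, class = "axis-label")))
    if (!isTRUE(ax$degenerate))
      prims <- c(prims, list(
        prim_text(ax_x[j] + 3, margin_t + 8, fmt_num(ax$hi, 2), size = 8,
                  color = "#888888", class = "axis-range"),
        prim_text(ax_x[j] + 3, margin_t + plot_h, fmt_num(ax$lo, 2),
                  size = 8, color = "#888888", class = "axis-range")))
  }

  color_of <- stats::setNames(spec$legend$colors, spec$legend$levels)
  for (tr in spec$trajectories) {
    segs <- split_gaps(tr$y)
    for (sg in segs) {
      if (length(sg) < 2L) next
      prims <- c(prims, list(prim_polyline(
        ax_x[sg], ypos(tr$y[sg]), color = unname(color_of[tr$level]),
        width = 0.6, opacity = spec$options$trajectory_opacity,
        class = "trajectory")))
    }
  }

  for (pr in spec$profiles) {
    for (j in seq_len(p)) {
      if (!is.na(pr$se_lo[j]))
        prims <- c(prims, list(
          prim_line(ax_x[j], ypos(pr$se_lo[j]), ax_x[j], ypos(pr$se_hi[j]),
                    color = pr$color, width = 2.5, class = "whisker"),
          prim_line(ax_x[j] - 4, ypos(pr$se_lo[j]), ax_x[j] + 4,
                    ypos(pr$se_lo[j]), color = pr$color, width = 1.5,
                    class = "whisker-cap"),
          prim_line(ax_x[j] - 4, ypos(pr$se_hi[j]), ax_x[j] + 4,
                    ypos(pr$se_hi[j]), color = pr$color, width = 1.5,
                    class = "whisker-cap")))
    }
    segs <- split_gaps(pr$y)
    for (sg in segs) {
      if (length(sg) < 2L) next
      prims <- c(prims, list(prim_polyline(
        ax_x[sg], ypos(pr$y[sg]), color = pr$color, width = 3.5,
        class = "profile")))
    }
    ok <- which(!is.na(pr$y))
    if (length(ok) == 1L)
      prims <- c(prims, list(prim_circle(ax_x[ok], ypos(pr$y[ok]), 3,
                                         pr$color, class = "profile")))
  }

  prims <- c(prims, legend_prims(spec$legend, width - margin_r + 40,
                                 margin_t + 10))
  list(prims = prims, width = width, height = height)
}

split_gaps <- function(y) {
  ok <- !is.na(y)
  if (!any(ok)) return(list())
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in seq_along(runs$values))
    if (runs$values[i]) out[[length(out) + 1L]] <- starts[i]:ends[i]
  out
}

layout_heatmap <- function(spec) {
  p <- length(spec$variables)
  cell <- max(6, min(24, floor(600 / p)))
  dend_h <- if (nrow(spec$merge) > 0) 90 else 20
  margin <- 140
  width <- dend_h + p * cell + margin
  height <- dend_h + p * cell + margin
  x0 <- dend_h; y0 <- dend_h

  prims <- list()
  for (i in seq_len(p)) {
    cols <- heat_color(spec$r[i, ])
    for (j in seq_len(p))
      prims <- c(prims, list(prim_rect(
        x0 + (j - 1) * cell, y0 + (i - 1) * cell, cell, cell,
        cols[j], class = "cell")))
  }
  for (i in seq_len(p)) {
    prims <- c(prims, list(
      prim_text(x0 + p * cell + 4, y0 + (i - 0.3) * cell,
                spec$variables[i], size = min(10, cell), class = "row-label"),
      prim_text(x0 + (i - 0.3) * cell, y0 + p * cell + 6,
                spec$variables[i], size = min(10, cell), anchor = "end",
                rotate = -60, class = "col-label")))
  }

  if (nrow(spec$merge) > 0) {
    segs <- dendro_segments(spec$merge, spec$height, spec$leaf_index)
    hmax <- max(spec$height)
    if (hmax <= 0) hmax <- 1
    # leaf position k (1-based along ordered axis) -> pixel center
    posx <- function(k) x0 + (k - 0.5) * cell
    posh <- function(h) dend_h * (1 - h / hmax) # 0 height at matrix edge
    for (s in segs) {
      prims <- c(prims, list(
        # top dendrogram
        prim_line(posx(s$x1), posh(s$h1), posx(s$x2), posh(s$h2),
                  color = "#444444", class = "dendrogram"),
        # left dendrogram (mirrored)
        prim_line(posh(s$h1), posx(s$x1), posh(s$h2), posx(s$x2),
                  color = "#444444", class = "dendrogram")))
    }
  }

  # color key
  key_y <- y0 + p * cell + 90
  for (k in 0:40) {
    r <- -1 + k / 20
    prims <- c(prims, list(prim_rect(x0 + k * 4, key_y, 4, 10,
                                     heat_color(r), class = "key")))
  }
  prims <- c(prims, list(
    prim_text(x0, key_y + 24, "-1", size = 9, class = "key-label"),
    prim_text(x0 + 80, key_y + 24, "0", size = 9, anchor = "middle",
              class = "key-label"),
    prim_text(x0 + 164, key_y + 24, "+1", size = 9, anchor = "end",
              class = "key-label")))
  list(prims = prims, width = width, height = max(height, key_y + 40))
}

# dendrogram as (x, height) segments over ordered leaf positions:
# each merge draws two stems and one crossbar
dendro_segments <- function(merge, height, leaf_index) {
  p <- length(leaf_index)
  posk <- integer(p); posk[leaf_index] <- seq_len(p)  # variable -> position
  cx <- numeric(nrow(merge)); ch <- numeric(nrow(merge))
  where <- function(id) if (id < 0) c(posk[-id], 0) else c(cx[id], ch[id])
  segs <- list()
  for (s in seq_len(nrow(merge))) {
    a <- where(merge[s, 1]); b <- where(merge[s, 2])
    h <- height[s]
    segs <- c(segs, list(
      list(x1 = a[1], h1 = a[2], x2 = a[1], h2 = h),
      list(x1 = b[1], h1 = b[2], x2 = b[1], h2 = h),
      list(x1 = a[1], h1 = h, x2 = b[1], h2 = h)))
    cx[s] <- (a[1] + b[1]) / 2
    ch[s] <- h
  }
  segs
}

layout_pca_grid <- function(spec) {
  panel <- 240; pad <- 50
  n_panels <- length(spec$panels) + if (!is.null(spec$view3d)) 1L else 0L
  per_row <- min(2L, n_panels)
  n_rows <- ceiling(n_panels / per_row)
  width <- pad + per_row * (panel + pad) + 180
  height <- pad + n_rows * (panel + pad)

  color_of <- stats::setNames(spec$legend$colors, spec$legend$levels)
  prims <- list()
  draw_panel <- function(px, py, x, y, xlab, ylab, cls) {
    rngx <- range(x); rngy <- range(y)
    if (diff(rngx) == 0) rngx <- rngx + c(-1, 1)
    if (diff(rngy) == 0) rngy <- rngy + c(-1, 1)
    sx <- function(v) px + (v - rngx[1]) / diff(rngx) * panel
    sy <- function(v) py + panel - (v - rngy[1]) / diff(rngy) * panel
    out <- list(
      prim_rect(px, py, panel, panel, "#FFFFFF", class = cls),
      prim_line(px, py + panel, px + panel, py + panel, color = "#333333",
                class = "frame"),
      prim_line(px, py, px, py + panel, color = "#333333", class = "frame"),
      prim_text(px + panel / 2, py + panel + 30, xlab, size = 11,
                anchor = "middle", class = "panel-xlab"),
      prim_text(px - 8, py + panel / 2, ylab, size = 11, anchor = "middle",
                rotate = -90, class = "panel-ylab"))
    for (i in seq_along(x))
      out <- c(out, list(prim_circle(
        sx(x[i]), sy(y[i]), 2.5,
        unname(color_of[spec$levels[i]]), opacity = 0.7, class = "point")))
    out
  }

  k <- 0L
  pc_lab <- function(d) sprintf("PC%d (%.1f%%)", d, 100 * spec$explained[d])
  for (pn in spec$panels) {
    row <- k %/% per_row; col <- k %% per_row
    px <- pad + col * (panel + pad); py <- pad + row * (panel + pad)
    prims <- c(prims, draw_panel(px, py, pn$x, pn$y,
                                 pc_lab(pn$xdim), pc_lab(pn$ydim), "panel"))
    k <- k + 1L
  }
  if (!is.null(spec$view3d)) {
    row <- k %/% per_row; col <- k %% per_row
    px <- pad + col * (panel + pad); py <- pad + row * (panel + pad)
    prims <- c(prims, draw_panel(px, py, spec$view3d$u, spec$view3d$v,
                                 "PC1-PC2 (isometric)", "PC3 + depth",
                                 "panel panel3d"))
  }
  prims <- c(prims, legend_prims(spec$legend, width - 160, pad))
  list(prims = prims, width = width, height = height)
}

# -- render entry point ------------------------------------------------------

#' Render a figure spec to a file
#'
#' SVG is the canonical format: the output is a pure function of the spec
#' and is byte-identical across reruns and platforms. PNG is offered as a
#' raster convenience. Returns a manifest record with a content hash, so
#' reports can assert end-to-end determinism.
#'
#' @param spec a `visova_spec`, `heatmap_spec` or `pca_grid_spec`
#' @param path output file path
#' @param format `"svg"` or `"png"`
#' @return (invisibly) a manifest record: list with `file`, `type`,
#'   `format`, `variables`, `levels`, `counts`, `options`, `md5`
#' @export
render_figure <- function(spec, path, format = c("svg", "png")) {
  format <- match.arg(format)
  lay <- switch(spec$type,
    visova = layout_visova(spec),
    corr_heatmap = layout_heatmap(spec),
    pca_grid = layout_pca_grid(spec),
    stop_viva("render", sprintf("unknown figure type %s", sQuote(spec$type))))

  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_viva("io", sprintf("output directory does not exist: %s", dir))
  if (format == "svg") svg_write(lay$prims, lay$width, lay$height, path)
  else png_write(lay$prims, lay$width, lay$height, path)

  rec <- list(
    file = basename(path), type = spec$type, format = format,
    variables = spec$variables %||% character(0),
    levels = spec$legend$levels %||% character(0),
    counts = spec$legend$counts %||% integer(0),
    options = spec$options %||% list(),
    md5 = unname(tools::md5sum(path)))
  invisible(rec)
}
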