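#' Build a VISOVA parallel-coordinates figure spec
#'
#' VISOVA integrates parallel coordinates with analysis-of-variance-style
#' group profiles: one vertical axis per variable (in correlation-cluster
#' leaf order), a thin trajectory per subject across the axes, and a thick
#' per-group profile polyline through the group means with standard-error
#' whiskers at each axis.
#'
#' Axis scaling maps each variable to `[0, 1]`:
#' * `"minmax"` (default): observed minimum to maximum;
#' * `"zscore"`: mean +/- 3 SD, clipped;
#' * `"robust"`: 5th to 95th percentile, clipped (for outlier-heavy
#'   phenotypes).
#'
#' A zero-range axis is flagged degenerate and drawn at 0.5. Subjects must
#' have at least 2 non-missing values to contribute a trajectory; missing
#' axes leave a gap. Only assigned subjects are drawn (profiles are
#' computed from them alone). Trajectories are ordered by subject id, so
#' input row order never leaks into the output; when more than
#' `max_subjects` subjects are drawable, a deterministic hash of the
#' subject id picks the subsample.
#'
#' @param table a `phenotype_table`
#' @param assignment a `group_assignment`
#' @param profiles a `group_profile` over the same variables
#' @param ordering a `variable_ordering` over the same variables
#' @param options list: `axis_scaling`, `se_mult` (default 1),
#'   `max_subjects` (default 2000), `trajectory_opacity` (default 0.25)
#' @return a `visova_spec` (list, consumed by [render_figure()])
#' @export
build_visova <- function(table, assignment, profiles, ordering,
                         options = list()) {
  axis_scaling <- options$axis_scaling %||% "minmax"
  if (!axis_scaling %in% c("minmax", "zscore", "robust"))
    stop_viva("config", sprintf("unknown axis scaling %s", sQuote(axis_scaling)))
  se_mult <- options$se_mult %||% 1
  max_subjects <- options$max_subjects %||% 2000
  opacity <- options$trajectory_opacity %||% 0.25

  variables <- ordering$leaf_order
  if (!setequal(variables, unique(as.character(profiles$variable))))
    stop_viva("config", "profiles and ordering cover different variables")

  m <- table_matrix(table, variables)
  assigned <- !is.na(assignment$assignment)
  drawable <- assigned & rowSums(!is.na(m)) >= 2L
  if (!any(drawable))
    stop_viva("render", "no drawable subjects (need >= 2 non-missing values)")

  mv <- m[drawable, , drop = FALSE]
  axes <- lapply(seq_along(variables), function(j) {
    x <- mv[, j]; x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(list(name = variables[j], lo = NA_real_, hi = NA_real_,
                  degenerate = TRUE))
    rng <- switch(axis_scaling,
      minmax = range(x),
      zscore = mean(x) + c(-3, 3) * stats::sd(x),
      robust = unname(stats::quantile(x, c(0.05, 0.95), type = 7)))
    degenerate <- !is.finite(rng[1]) || !is.finite(rng[2]) || rng[1] == rng[2]
    list(name = variables[j], lo = rng[1], hi = rng[2],
         degenerate = degenerate)
  })
  norm1 <- function(x, ax) {
    if (ax$degenerate) return(ifelse(is.na(x), NA_real_, 0.5))
    pmin(1, pmax(0, (x - ax$lo) / (ax$hi - ax$lo)))
  }

  ids <- table$subject_ids[drawable]
  lev <- assignment$assignment[drawable]
  ord <- order(ids)
  ids <- ids[ord]; lev <- lev[ord]; mv <- mv[ord, , drop = FALSE]
  if (length(ids) > max_subjects) {
    keep <- order(vapply(ids, stable_hash, 0), ids)[seq_len(max_subjects)]
    keep <- sort(keep)
    ids <- ids[keep]; lev <- lev[keep]; mv <- mv[keep, , drop = FALSE]
  }
  trajectories <- lapply(seq_along(ids), function(i) {
    y <- vapply(seq_along(variables),
                function(j) norm1(mv[i, j], axes[[j]]), 0)
    list(subject = ids[i], level = lev[i], y = y)
  })

  prof_lines <- lapply(assignment$levels, function(l) {
    sub <- profiles[profiles$level == l, ]
    sub <- sub[match(variables, as.character(sub$variable)), ]
    y <- lo <- hi <- rep(NA_real_, length(variables))
    for (j in seq_along(variables)) {
      ax <- axes[[j]]
      if (!is.na(sub$mean[j])) y[j] <- norm1(sub$mean[j], ax)
      if (!is.na(sub$se[j])) {
        lo[j] <- norm1(sub$mean[j] - se_mult * sub$se[j], ax)
        hi[j] <- norm1(sub$mean[j] + se_mult * sub$se[j], ax)
      }
    }
    list(level = l, color = unname(assignment$colors[l]),
         y = y, se_lo = lo, se_hi = hi)
  })

  structure(list(
    type = "visova", variables = variables, axes = axes,
    trajectories = trajectories, profiles = prof_lines,
    legend = list(levels = assignment$levels,
                  colors = unname(assignment$colors[assignment$levels]),
                  counts = unname(assignment$counts)),
    options = list(axis_scaling = axis_scaling, se_mult = se_mult,
                   max_subjects = max_subjects,
                   trajectory_opacity = opacity)),
    class = c("visova_spec", "figure_spec"))
}

# deterministic 31-bit polynomial string hash (platform-independent)
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  h
}

#' Build a clustered correlation heatmap spec
#'
#' Rows and columns are permuted to the dendrogram leaf order so planted
#' or discovered correlation blocks appear as contiguous diagonal blocks;
#' dendrograms are drawn on both margins. The diverging color scale is
#' fixed to `[-1, 1]` with white at 0; undefined cells are grey.
#'
#' @param corr a `corr_matrix`
#' @param ordering a `variable_ordering` over the same variables
#' @return a `heatmap_spec` (list, consumed by [render_figure()])
#' @export
build_corr_heatmap <- function(corr, ordering) {
  if (!identical(sort(corr$variables), sort(ordering$variables)))
    stop_viva("config", "heatmap ordering covers different variables")
  idx <- match(ordering$leaf_order, corr$variables)
  r <- corr$r[idx, idx, drop = FALSE]
  structure(list(
    type = "corr_heatmap", variables = ordering$leaf_order,
    r = r, method = corr$method,
    merge = ordering$merge, height = ordering$height,
    leaf_index = ordering$leaf_index),
    class = c("heatmap_spec", "figure_spec"))
}

#' Build PCA group-projection views
#'
#' `choose(dims, 2)` pairwise score scatter panels plus (for `dims >= 3`)
#' one fixed-azimuth 3D view (isometric projection, kept static for
#' deterministic output). Points are colored by grouping level; axes are
#' labelled with the component index and explained-variance fraction.
#'
#' @param pca a `pca_result` with at least `dims` components
#' @param assignment a `group_assignment` (matched to scores by subject id)
#' @param dims number of leading components to display (default 3)
#' @return a `pca_grid_spec` (list, consumed by [render_figure()])
#' @export
build_pca_views <- function(pca, assignment, dims = 3) {
  if (dims > ncol(pca$scores))
    stop_viva("analytics", sprintf(
      "requested %d display dimensions but PCA has %d components",
      dims, ncol(pca$scores)))
  ids <- rownames(pca$scores)
  lev <- assignment$assignment[match(ids, assignment$subject_ids)]
  keep <- !is.na(lev)
  s <- pca$scores[keep, seq_len(dims), drop = FALSE]
  ids <- ids[keep]; lev <- lev[keep]
  ord <- order(ids)
  s <- s[ord, , drop = FALSE]; ids <- ids[ord]; lev <- lev[ord]

  pairs <- utils::combn(dims, 2)
  panels <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    list(xdim = i, ydim = j, x = s[, i], y = s[, j])
  })
  view3d <- NULL
  if (dims >= 3) {
    x <- s[, 1]; y <- s[, 2]; z <- s[, 3]
    view3d <- list(u = (x - y) * cos(pi / 6),
                   v = z + (x + y) * sin(pi / 6),
                   dims = 1:3)
  }
  counts <- vapply(assignment$levels, function(l) sum(lev == l), 0L)
  structure(list(
    type = "pca_grid", dims = dims, panels = panels, view3d = view3d,
    levels = lev, subject_ids = ids,
    explained = pca$explained[seq_len(dims)],
    legend = list(levels = assignment$levels,
                  colors = unname(assignment$colors[assignment$levels]),
                  counts = unname(counts))),
    class = c("pca_grid_spec", "figure_spec"))
}
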