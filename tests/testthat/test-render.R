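visova_fixture <- function(n = 40, p = 5, seed = 2, missing_rate = 0.1) {
  tab <- make_random_table(n, p, missing_rate = missing_rate, seed = seed)
  a <- assign_groups(tab, grp_grouping())
  vars <- sprintf("v%02d", seq_len(p))
  prof <- group_profiles(tab, a, vars)
  vo <- cluster_variables(correlation_matrix(tab, vars))
  list(tab = tab, a = a, prof = prof, vo = vo, vars = vars)
}

test_that("VISOVA spec has one axis per variable, one profile per level", {
  f <- visova_fixture()
  spec <- build_visova(f$tab, f$a, f$prof, f$vo)
  expect_length(spec$axes, 5)
  expect_length(spec$profiles, 3)
  expect_identical(spec$legend$levels, c("A", "B", "C"))
  expect_identical(spec$variables, f$vo$leaf_order)
  # every normalized coordinate lies in [0,1]
  for (tr in spec$trajectories)
    expect_true(all(tr$y >= 0 & tr$y <= 1, na.rm = TRUE))
  # a subject missing one axis gets a gap there
  miss <- which(is.na(f$tab$data$v03))[1]
  skip_if(is.na(miss))
  id <- f$tab$subject_ids[miss]
  tr <- Filter(function(t) t$subject == id, spec$trajectories)
  if (length(tr) == 1)
    expect_true(is.na(tr[[1]]$y[match("v03", spec$variables)]))
})

test_that("profile polylines pass through the group means after normalization", {
  f <- visova_fixture(missing_rate = 0)
  spec <- build_visova(f$tab, f$a, f$prof, f$vo)
  for (pr in spec$profiles) {
    sub <- f$prof[f$prof$level == pr$level, ]
    sub <- sub[match(spec$variables, as.character(sub$variable)), ]
    for (j in seq_along(spec$variables)) {
      ax <- spec$axes[[j]]
      back <- ax$lo + pr$y[j] * (ax$hi - ax$lo)   # inverse transform
      expect_equal(back, sub$mean[j], tolerance = 1e-9)
    }
  }
})

test_that("degenerate axes are flagged and drawn at 0.5", {
  tab <- make_random_table(20, 3, missing_rate = 0, seed = 5)
  tab$data$v02 <- 4  # zero range
  a <- assign_groups(tab, grp_grouping())
  vars <- c("v01", "v02", "v03")
  prof <- group_profiles(tab, a, vars)
  expect_warning(vo <- cluster_variables(correlation_matrix(tab, vars)),
                 class = "viva_analytics_warning")
  spec <- build_visova(tab, a, prof, vo)
  j <- match("v02", spec$variables)
  expect_true(spec$axes[[j]]$degenerate)
  for (tr in spec$trajectories) expect_equal(tr$y[j], 0.5)
})

test_that("SVG rendering is byte-deterministic and row-order independent", {
  f <- visova_fixture()
  spec <- build_visova(f$tab, f$a, f$prof, f$vo)
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  r1 <- render_figure(spec, p1)
  r2 <- render_figure(spec, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(r1$md5, r2$md5)

  # permute subject rows: identical bytes (primitives sorted by id)
  perm <- sample(n_subjects(f$tab))
  tabp <- f$tab
  tabp$data <- f$tab$data[perm, , drop = FALSE]
  rownames(tabp$data) <- NULL
  tabp$subject_ids <- f$tab$subject_ids[perm]
  ap <- assign_groups(tabp, grp_grouping())
  profp <- group_profiles(tabp, ap, f$vars)
  vop <- cluster_variables(correlation_matrix(tabp, f$vars))
  specp <- build_visova(tabp, ap, profp, vop)
  p3 <- withr::local_tempfile(fileext = ".svg")
  render_figure(specp, p3)
  expect_identical(readLines(p1), readLines(p3))
})

test_that("a 5-axis VISOVA SVG contains exactly 5 axis elements", {
  f <- visova_fixture(p = 5)
  spec <- build_visova(f$tab, f$a, f$prof, f$vo)
  path <- withr::local_tempfile(fileext = ".svg")
  render_figure(spec, path)
  svg <- readLines(path)
  expect_equal(sum(grepl('class="axis"', svg)), 5)
  expect_equal(sum(grepl('class="profile"', svg)), 3)
})

test_that("heatmap permutes the matrix to leaf order with block structure", {
  r <- diag(5)
  # plant blocks on interleaved variables so leaf order must reorder them
  blk1 <- c(1, 3, 5); blk2 <- c(2, 4)
  r[blk1, blk1] <- 0.9; r[blk2, blk2] <- 0.9; diag(r) <- 1
  corr <- corr_fixture(r, letters[1:5])
  vo <- cluster_variables(corr)
  hm <- build_corr_heatmap(corr, vo)
  expect_identical(hm$variables, vo$leaf_order)
  # permuted matrix is block-contiguous
  pos1 <- match(letters[blk1], hm$variables)
  expect_equal(diff(range(pos1)), 2)
  sub <- hm$r[sort(pos1), sort(pos1)]
  expect_true(all(sub[upper.tri(sub)] == 0.9))
  path <- withr::local_tempfile(fileext = ".svg")
  rec <- render_figure(hm, path)
  expect_equal(sum(grepl('class="cell"', readLines(path))), 25)

  # 1x1 degenerate heatmap renders a single cell
  c1 <- corr_fixture(diag(1), "only")
  hm1 <- build_corr_heatmap(c1, cluster_variables(c1))
  path1 <- withr::local_tempfile(fileext = ".svg")
  render_figure(hm1, path1)
  expect_equal(sum(grepl('class="cell"', readLines(path1))), 1)
})

test_that("PCA views: pairwise panels plus a 3D view only when dims >= 3", {
  tab <- make_random_table(60, 6, missing_rate = 0, seed = 9)
  a <- assign_groups(tab, grp_grouping())
  pc <- pca_projection(tab, sprintf("v%02d", 1:6))
  v3 <- build_pca_views(pc, a, dims = 3)
  expect_length(v3$panels, 3)
  expect_false(is.null(v3$view3d))
  v2 <- build_pca_views(pc, a, dims = 2)
  expect_length(v2$panels, 1)
  expect_null(v2$view3d)
  expect_error(build_pca_views(pc, a, dims = 10),
               class = "viva_analytics_error")
  path <- withr::local_tempfile(fileext = ".svg")
  render_figure(v3, path)
  svg <- readLines(path)
  expect_equal(sum(grepl('class="panel"', svg)), 3)
  expect_equal(sum(grepl('class="panel panel3d"', svg)), 1)
})

test_that("non-finite coordinates never reach the drawing layer", {
  prims <- list(visova:::prim_line(0, 0, NaN, 1))
  expect_error(visova:::svg_write(prims, 10, 10, tempfile()),
               "non-finite", class = "viva_render_error")
})

test_that("PNG rendering writes a file", {
  skip_if_not(capabilities("png"))
  f <- visova_fixture()
  spec <- build_visova(f$tab, f$a, f$prof, f$vo)
  path <- withr::local_tempfile(fileext = ".png")
  rec <- render_figure(spec, path, format = "png")
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
})
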