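test_that("group profiles handle zero-variance and tiny levels", {
  d <- data.frame(id = sprintf("s%d", 1:6),
                  grp = c("A", "A", "A", "A", "A", "B"),
                  v01 = c(7, 7, 7, 7, 7, 3), stringsAsFactors = FALSE)
  dict <- data.frame(name = c("id", "grp", "v01"), label = "",
                     kind = c("identifier", "factor", "numeric"),
                     units = "", source = "t", stringsAsFactors = FALSE)
  tab <- visova:::new_phenotype_table(d, dict)
  a <- assign_groups(tab, grp_grouping(c("A", "B")))
  p <- group_profiles(tab, a, "v01")
  pa <- p[p$level == "A", ]; pb <- p[p$level == "B", ]
  expect_equal(pa$mean, 7); expect_equal(pa$se, 0); expect_equal(pa$n, 5L)
  expect_equal(pb$mean, 3); expect_true(is.na(pb$se)); expect_equal(pb$n, 1L)
  expect_error(group_profiles(tab, a, character(0)),
               class = "viva_resolve_error")
})

test_that("profiles and correlations equal brute-force oracles", {
  for (seed in 1:8) {
    tab <- make_random_table(sample(10:50, 1), sample(3:12, 1),
                             missing_rate = 0.25, seed = seed)
    a <- assign_groups(tab, grp_grouping())
    vars <- setdiff(names(tab$data), c("id", "grp"))

    prof <- group_profiles(tab, a, vars)
    oracle <- oracle_profiles(tab$data, a$assignment, a$levels, vars)
    for (i in seq_len(nrow(prof))) {
      key <- paste(prof$level[i], prof$variable[i])
      expect_equal(prof$mean[i], unname(oracle[[key]]["mean"]),
                   tolerance = 1e-12)
      expect_equal(prof$se[i], unname(oracle[[key]]["se"]),
                   tolerance = 1e-12)
      expect_equal(prof$n[i], unname(oracle[[key]]["n"]))
    }

    cm <- correlation_matrix(tab, vars)
    expect_equal(unname(cm$r), oracle_pairwise_cor(tab$data, vars),
                 tolerance = 1e-12)
    expect_true(all(abs(cm$r[!cm$undefined]) <= 1 + 1e-12))
    expect_equal(cm$r, t(cm$r))
    expect_equal(cm$n, t(cm$n))
  }
})

test_that("perfect linear dependence gives r of +/- 1; dead variables flag", {
  d <- data.frame(id = sprintf("s%d", 1:10), grp = "A",
                  a = 1:10, b = 2 * (1:10), c = -(1:10),
                  dead = NA_real_, flat = 5,
                  stringsAsFactors = FALSE)
  dict <- data.frame(name = names(d), label = "",
                     kind = c("identifier", "factor", rep("numeric", 5)),
                     units = "", source = "t", stringsAsFactors = FALSE)
  tab <- visova:::new_phenotype_table(d, dict)
  cm <- correlation_matrix(tab, c("a", "b", "c", "dead", "flat"))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_true(all(cm$undefined["dead", ]))
  expect_true(all(cm$undefined["flat", ]))   # zero-variance margin
  expect_equal(cm$r["a", "a"], 1)
})

test_that("clustering keeps planted blocks contiguous and breaks ties by index", {
  # identity correlation: all off-diagonal distances equal -> input order
  eye <- corr_fixture(diag(6))
  vo <- cluster_variables(eye)
  expect_identical(vo$leaf_order, eye$variables)

  # two planted blocks stay contiguous in the leaf order
  r <- diag(5)
  r[1:3, 1:3] <- 0.9; r[4:5, 4:5] <- 0.9; diag(r) <- 1
  vo2 <- cluster_variables(corr_fixture(r, letters[1:5]))
  pos1 <- match(c("a", "b", "c"), vo2$leaf_order)
  pos2 <- match(c("d", "e"), vo2$leaf_order)
  expect_equal(diff(range(pos1)), 2)
  expect_equal(diff(range(pos2)), 1)

  # degenerate sizes
  expect_identical(cluster_variables(corr_fixture(diag(2)))$leaf_order,
                   c("v01", "v02"))
  expect_identical(cluster_variables(corr_fixture(diag(1),
                                                  "only"))$leaf_order,
                   "only")

  # undefined cells resolve to 0 with a warning, not an error
  cu <- corr_fixture(diag(3))
  cu$r[1, 2] <- cu$r[2, 1] <- NA
  cu$undefined[1, 2] <- cu$undefined[2, 1] <- TRUE
  expect_warning(cluster_variables(cu), class = "viva_analytics_warning")
})

test_that("agglomeration matches hclust on tie-free inputs", {
  set.seed(5)
  for (meth in c("average", "complete", "ward")) {
    for (i in 1:5) {
      p <- sample(4:12, 1)
      r <- stats::cov2cor(crossprod(matrix(rnorm(p * p * 3), ncol = p)))
      nm <- paste0("v", seq_len(p))
      vo <- cluster_variables(corr_fixture(r, nm), meth)
      hc <- stats::hclust(stats::as.dist(1 - (r + t(r)) / 2),
                          method = if (meth == "ward") "ward.D2" else meth)
      hc$labels <- nm
      expect_equal(sort(vo$height), sort(hc$height), tolerance = 1e-10)
      co1 <- as.matrix(stats::cophenetic(as_hclust(vo)))[nm, nm]
      co2 <- as.matrix(stats::cophenetic(hc))[nm, nm]
      expect_equal(co1, co2, tolerance = 1e-10)
    }
  }
})

test_that("leaf order is deterministic and permutation-consistent", {
  set.seed(17)
  p <- 8
  r <- stats::cov2cor(crossprod(matrix(rnorm(p * p * 3), ncol = p)))
  nm <- paste0("v", seq_len(p))
  c1 <- corr_fixture(r, nm)
  expect_identical(cluster_variables(c1)$leaf_order,
                   cluster_variables(c1)$leaf_order)

  # permuting the input permutes the tree consistently: same merge
  # partitions (as variable-name sets) at every height
  perm <- sample(p)
  c2 <- corr_fixture(r[perm, perm], nm[perm])
  v1 <- cluster_variables(c1); v2 <- cluster_variables(c2)
  part <- function(vo) {
    leaves_of <- vector("list", nrow(vo$merge))
    get <- function(id) if (id < 0) vo$variables[-id] else leaves_of[[id]]
    sets <- character(0)
    for (s in seq_len(nrow(vo$merge))) {
      leaves_of[[s]] <- c(get(vo$merge[s, 1]), get(vo$merge[s, 2]))
      sets <- c(sets, paste(sort(leaves_of[[s]]), collapse = "+"))
    }
    sets[order(vo$height)]
  }
  expect_identical(part(v1), part(v2))
  expect_equal(sort(v1$height), sort(v2$height), tolerance = 1e-12)
})

test_that("linkage exports: table sizes and Newick leaves", {
  r <- diag(4); r[1, 2] <- r[2, 1] <- 0.9
  vo <- cluster_variables(corr_fixture(r, c("a", "b", "c", "d")))
  lt <- linkage_table(vo)
  expect_equal(nrow(lt), 3)
  expect_equal(lt$size[nrow(lt)], 4)
  nwk <- as_newick(vo)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("a", "b", "c", "d"))
})

test_that("PCA satisfies its variance-accounting contracts", {
  # two perfectly correlated variables: rank-1 limit
  d <- data.frame(id = sprintf("s%d", 1:20), x = rnorm(20),
                  stringsAsFactors = FALSE)
  d$y <- 2 * d$x
  dict <- data.frame(name = c("id", "x", "y"), label = "",
                     kind = c("identifier", "numeric", "numeric"),
                     units = "", source = "t", stringsAsFactors = FALSE)
  tab <- visova:::new_phenotype_table(d, dict)
  pc <- pca_projection(tab, c("x", "y"))
  expect_equal(pc$explained, c(1, 0), tolerance = 1e-12)

  # trace conservation + monotone explained fractions on random input
  for (seed in 1:5) {
    tab <- make_random_table(30, 8, missing_rate = 0.05, seed = seed)
    pc <- pca_projection(tab, sprintf("v%02d", 1:8))
    expect_equal(sum(pc$explained_all), 1, tolerance = 1e-9)
    expect_true(all(diff(pc$explained_all) <= 1e-12))
    expect_true(all(pc$explained_all >= 0 & pc$explained_all <= 1))
    expect_equal(unname(colSums(pc$loadings^2)),
                 rep(1, ncol(pc$loadings)), tolerance = 1e-9)
    # sign convention: largest-|loading| entry positive
    for (j in seq_len(ncol(pc$loadings)))
      expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }

  # planted rank-2 structure is recovered
  set.seed(33)
  n <- 200; p <- 10
  scores <- matrix(rnorm(n * 2), n, 2)
  load <- matrix(rnorm(2 * p), 2, p)
  x <- scores %*% load + 0.05 * matrix(rnorm(n * p), n, p)
  d <- data.frame(id = sprintf("s%03d", 1:n), x, stringsAsFactors = FALSE)
  names(d) <- c("id", sprintf("v%02d", 1:p))
  dict <- data.frame(name = names(d), label = "",
                     kind = c("identifier", rep("numeric", p)),
                     units = "", source = "t", stringsAsFactors = FALSE)
  tab <- visova:::new_phenotype_table(d, dict)
  pc <- pca_projection(tab, sprintf("v%02d", 1:p))
  expect_gt(sum(pc$explained[1:2]), 0.9)

  # explained fractions are invariant to variable reordering
  pc2 <- pca_projection(tab, sprintf("v%02d", p:1))
  expect_equal(pc$explained_all, pc2$explained_all, tolerance = 1e-9)

  expect_error(pca_projection(tab, sprintf("v%02d", 1:p), k = 99),
               class = "viva_analytics_error")
})
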