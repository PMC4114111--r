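#' Principal component projection of subjects
#'
#' Complete-case PCA: rows with any missing value among the selected
#' variables are dropped (and counted), because a subject score needs all
#' coordinates. In `"correlation"` mode variables are standardized
#' (z-scored) before the eigendecomposition, so every variable carries
#' equal weight regardless of units; `"covariance"` mode centers only.
#'
#' Eigendecompositions are sign-ambiguous, so a fixed convention is
#' applied: within each component the loading of largest absolute value is
#' made positive.
#'
#' @param table a `phenotype_table`
#' @param variables ordered character vector of numeric variables
#' @param k number of components to keep (default: all available)
#' @param scaling `"correlation"` or `"covariance"`
#' @return a `pca_result`: list with `loadings` (variables x k, unit-norm
#'   columns), `scores` (complete subjects x k), `explained` (fraction of
#'   total variance per kept component, non-increasing), `explained_all`
#'   (over all `min(n-1, p)` components; sums to 1), `n_used`,
#'   `n_dropped`, `scaling`
#' @export
pca_projection <- function(table, variables, k = NULL,
                           scaling = c("correlation", "covariance")) {
  scaling <- match.arg(scaling)
  m <- table_matrix(table, variables)
  complete <- stats::complete.cases(m)
  n_used <- sum(complete)
  if (n_used < 2L)
    stop_viva("analytics", sprintf(
      "PCA needs at least 2 complete-case subjects (got %d)", n_used))
  x <- m[complete, , drop = FALSE]

  constant <- apply(x, 2, function(col) stats::sd(col) == 0)
  if (scaling == "correlation" && any(constant))
    stop_viva("analytics", sprintf(
      "zero-variance variable(s) cannot be standardized: %s",
      paste(variables[constant], collapse = ", ")))

  pc <- stats::prcomp(x, center = TRUE, scale. = (scaling == "correlation"))
  ncomp <- length(pc$sdev)
  explained_all <- pc$sdev^2 / sum(pc$sdev^2)

  if (is.null(k)) k <- ncomp
  if (k > ncomp)
    stop_viva("analytics", sprintf(
      "requested %d components but only %d available", k, ncomp))

  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)

  structure(list(loadings = loadings, scores = scores,
                 explained = explained_all[seq_len(k)],
                 explained_all = explained_all,
                 n_used = n_used, n_dropped = nrow(m) - n_used,
                 scaling = scaling, variables = variables),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d subjects (%d dropped) x %d variables, %s mode\n",
              x$n_used, x$n_dropped, length(x$variables), x$scaling))
  cat("explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "),
      "\n")
  invisible(x)
}
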