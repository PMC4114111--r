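#' Pairwise-complete correlation matrix
#'
#' Each entry is computed over the subjects non-missing in *both*
#' variables, so every pair uses all available information. Cells with
#' fewer than 2 complete pairs, or a zero-variance margin over the
#' complete pairs, are undefined: they are flagged and carried as `NA` in
#' `r` (downstream clustering resolves them to 0 with a warning).
#'
#' @param table a `phenotype_table`
#' @param variables ordered character vector (>= 2 numeric variables)
#' @param method `"pearson"` or `"spearman"`
#' @return a `corr_matrix`: list with `variables`, `r` (symmetric
#'   correlations), `n` (symmetric pairwise-complete counts), `undefined`
#'   (logical matrix), `method`
#' @export
correlation_matrix <- function(table, variables,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(variables) < 2L)
    stop_viva("resolve", "correlation_matrix needs at least 2 variables")
  m <- table_matrix(table, variables)
  obs <- !is.na(m)
  n <- crossprod(obs)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                   method = method))
  undefined <- is.na(r) | n < 2L
  r[undefined] <- NA_real_
  diag_def <- !undefined[cbind(seq_along(variables), seq_along(variables))]
  diag(r)[diag_def] <- 1
  dimnames(r) <- dimnames(n) <- list(variables, variables)
  structure(list(variables = variables, r = r, n = n,
                 undefined = undefined, method = method),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d variables, %s, %d undefined cell(s)\n",
              length(x$variables), x$method, sum(x$undefined)))
  invisible(x)
}

#' Write a correlation matrix as TSV
#' @param corr a `corr_matrix`
#' @param path output file
#' @export
write_corr <- function(corr, path) {
  out <- as.data.frame(matrix(fmt_num(corr$r, 10), nrow = nrow(corr$r)))
  names(out) <- corr$variables
  out <- cbind(variable = corr$variables, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
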