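#' Group phenotype profiles: per-level means, standard errors, counts
#'
#' The numerical backbone of a VISOVA display: for every grouping level
#' and variable, the mean over subjects in that level with a non-missing
#' value, the standard error of that mean (sample SD with `n - 1`
#' denominator divided by `sqrt(n)`), and the contributing count.
#' Unassigned subjects are ignored. The mean is reported when `n >= 1`,
#' the SE only when `n >= 2` (`NA` otherwise).
#'
#' @param table a `phenotype_table`
#' @param assignment a `group_assignment` from [assign_groups()]
#' @param variables ordered character vector of numeric variables
#' @return a `group_profile`: data.frame with columns `level` (factor in
#'   the grouping's fixed order), `variable` (factor in input order),
#'   `mean`, `se`, `n`
#' @export
group_profiles <- function(table, assignment, variables) {
  if (length(variables) == 0L)
    stop_viva("resolve", "group_profiles needs at least one variable")
  m <- table_matrix(table, variables)
  lv <- assignment$levels
  grp <- factor(assignment$assignment, levels = lv)

  rows <- vector("list", length(lv))
  for (k in seq_along(lv)) {
    sel <- !is.na(grp) & grp == lv[k]
    sub <- m[sel, , drop = FALSE]
    n <- colSums(!is.na(sub))
    mu <- ifelse(n >= 1L, colMeans(sub, na.rm = TRUE), NA_real_)
    sd <- suppressWarnings(apply(sub, 2, stats::sd, na.rm = TRUE))
    se <- ifelse(n >= 2L, sd / sqrt(n), NA_real_)
    rows[[k]] <- data.frame(level = lv[k], variable = variables,
                            mean = unname(mu), se = unname(se),
                            n = unname(n), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = lv)
  out$variable <- factor(out$variable, levels = variables)
  rownames(out) <- NULL
  class(out) <- c("group_profile", "data.frame")
  out
}

#' Write a group profile as TSV
#' @param profile a `group_profile`
#' @param path output file
#' @export
write_profile <- function(profile, path) {
  out <- as.data.frame(profile)
  out$mean <- fmt_num(out$mean, 10)
  out$se <- fmt_num(out$se, 10)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
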