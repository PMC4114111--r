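#' Detect mean/SD reaction-time variable pairs
#'
#' Reaction-time phenotypes typically come as a (mean, standard deviation)
#' digest of many trials per subject. Pairs are detected by naming
#' convention: two declared numeric variables sharing a stem, one ending
#' in the mean suffix and one in the SD suffix. An override table pairs
#' irregular names explicitly and is honored even when no convention
#' matches.
#'
#' @param dictionary a `data_dictionary`
#' @param conventions list of `c(mean_suffix, sd_suffix)` pairs
#' @param overrides optional data.frame (or TSV path) with columns
#'   `mean_var`, `sd_var`, `stem`
#' @return data.frame with columns `mean_var`, `sd_var`, `stem`, ordered by
#'   dictionary position of `mean_var` (overrides first, in given order)
#' @export
detect_pairs <- function(dictionary,
                         conventions = list(c("MEANRT", "SDRT"),
                                            c("_MEAN", "_SD"),
                                            c("MRT", "SDRT")),
                         overrides = NULL) {
  dictionary <- as_dictionary(dictionary)
  num <- dict_vars(dictionary, "numeric")
  out <- list()

  if (!is.null(overrides)) {
    if (is.character(overrides))
      overrides <- utils::read.delim(overrides, colClasses = "character")
    for (i in seq_len(nrow(overrides))) {
      mv <- overrides$mean_var[i]; sv <- overrides$sd_var[i]
      if (!mv %in% num || !sv %in% num)
        stop_viva("config", sprintf(
          "override pair (%s, %s) not declared numeric in dictionary", mv, sv))
      out[[length(out) + 1L]] <- data.frame(
        mean_var = mv, sd_var = sv,
        stem = overrides$stem[i] %||% mv, stringsAsFactors = FALSE)
    }
  }

  for (mv in num) {
    for (cv in conventions) {
      msuf <- cv[1]; ssuf <- cv[2]
      if (endsWith(mv, msuf)) {
        stem <- substr(mv, 1L, nchar(mv) - nchar(msuf))
        sv <- paste0(stem, ssuf)
        if (sv %in% num && sv != mv) {
          stem_clean <- sub("[_.]+$", "", stem)
          if (stem_clean == "") stem_clean <- stem
          out[[length(out) + 1L]] <- data.frame(
            mean_var = mv, sd_var = sv, stem = stem_clean,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }

  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(mean_var = character(0), sd_var = character(0),
               stem = character(0), stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs$mean_var), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Augment a table with variability measures from mean/SD pairs
#'
#' For each (mean, SD) pair `(mu, sigma)` appends per-subject columns
#' `CV = sigma / mu` (coefficient of variation),
#' `SNR = mu / sigma` (signal-to-noise ratio), and
#' `FF = sigma^2 / mu` (Fano factor), named `<stem>_CV`, `<stem>_SNR`,
#' `<stem>_FF`.
#'
#' Reaction-time means and SDs are physically positive, so non-positive
#' values signal upstream data problems; a derived value whose denominator
#' is not strictly positive is set missing rather than infinite (and when
#' `mu <= 0` the whole triple is missing, so the figures never receive
#' non-finite values). `sigma = 0` with `mu > 0` is a legitimate
#' zero-variability digest: CV and FF are 0 and SNR is missing. Every cell
#' set missing this way is counted in the cleaning log. Input columns are
#' never modified.
#'
#' @param table a `phenotype_table`
#' @param pairs data.frame from [detect_pairs()]
#' @param measures subset of `c("CV", "SNR", "FF")`
#' @return the augmented `phenotype_table` (dictionary extended to declare
#'   the new numeric columns)
#' @export
augment_variability <- function(table, pairs,
                                measures = c("CV", "SNR", "FF")) {
  measures <- match.arg(measures, c("CV", "SNR", "FF"), several.ok = TRUE)
  if (!nrow(pairs)) return(table)

  new_names <- as.vector(outer(pairs$stem, measures,
                               function(s, m) paste0(s, "_", m)))
  clash <- intersect(new_names, names(table$data))
  if (length(clash))
    stop_viva("config", sprintf(
      "derived column name(s) collide with existing variables: %s",
      paste(clash, collapse = ", ")))

  data <- table$data
  dict <- as.data.frame(table$dictionary)
  log_add <- 0L
  for (i in seq_len(nrow(pairs))) {
    mu <- data[[pairs$mean_var[i]]]
    sg <- data[[pairs$sd_var[i]]]
    ok_mu <- !is.na(mu) & mu > 0
    ok_sg <- !is.na(sg) & sg >= 0
    both <- !is.na(mu) & !is.na(sg)
    for (m in measures) {
      val <- rep(NA_real_, length(mu))
      if (m == "CV")  { def <- ok_mu & ok_sg; val[def] <- sg[def]   / mu[def] }
      if (m == "FF")  { def <- ok_mu & ok_sg; val[def] <- sg[def]^2 / mu[def] }
      if (m == "SNR") { def <- ok_mu & !is.na(sg) & sg > 0
                        val[def] <- mu[def] / sg[def] }
      # degenerate inputs (present but invalid) are logged, not silent
      log_add <- log_add + sum(both & !def)
      nm <- paste0(pairs$stem[i], "_", m)
      data[[nm]] <- val
      src <- dict$source[dict$name == pairs$mean_var[i]]
      dict <- rbind(dict, data.frame(
        name = nm, label = sprintf("%s of %s", m, pairs$stem[i]),
        kind = "numeric", units = "", source = src,
        stringsAsFactors = FALSE))
    }
  }

  prov <- table$provenance
  if (log_add > 0L)
    prov$cleaning_log <- rbind(prov$cleaning_log, data.frame(
      subject = "*", variable = "*",
      original = as.character(log_add),
      action = "derived-value-undefined",
      stringsAsFactors = FALSE))
  new_phenotype_table(data, as_dictionary(dict), prov)
}
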