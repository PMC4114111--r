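# fixtures built in code; no data files

# a small dictionary + in-memory table with a factor group attribute,
# numeric phenotypes, and MCAR missingness
make_random_table <- function(n, p, missing_rate = 0.1, seed = 1,
                              n_levels = 3) {
  set.seed(seed)
  vars <- sprintf("v%02d", seq_len(p))
  dict <- data.frame(
    name = c("id", "grp", vars),
    label = "", kind = c("identifier", "factor", rep("numeric", p)),
    units = "", source = "test", stringsAsFactors = FALSE)
  data <- data.frame(id = sprintf("s%03d", seq_len(n)),
                     grp = sample(LETTERS[seq_len(n_levels)], n,
                                  replace = TRUE),
                     stringsAsFactors = FALSE)
  for (v in vars) {
    x <- rnorm(n)
    x[runif(n) < missing_rate] <- NA
    data[[v]] <- x
  }
  visova:::new_phenotype_table(data, visova:::as_dictionary(dict))
}

grp_grouping <- function(levels = c("A", "B", "C")) {
  list(name = "grp", derivation = "factor", source_variable = "grp",
       levels = levels)
}

# corr_matrix fixture straight from an r matrix (all cells defined)
corr_fixture <- function(r, vars = NULL) {
  p <- nrow(r)
  vars <- vars %||% sprintf("v%02d", seq_len(p))
  dimnames(r) <- list(vars, vars)
  structure(list(variables = vars, r = r,
                 n = matrix(100L, p, p, dimnames = list(vars, vars)),
                 undefined = matrix(FALSE, p, p), method = "pearson"),
            class = "corr_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- independent brute-force oracles (direct loops over subjects) ------------

oracle_profiles <- function(data, grp, levels, vars) {
  out <- list()
  for (l in levels) for (v in vars) {
    vals <- c()
    for (i in seq_len(nrow(data)))
      if (!is.na(grp[i]) && grp[i] == l && !is.na(data[[v]][i]))
        vals <- c(vals, data[[v]][i])
    n <- length(vals)
    mu <- if (n >= 1) sum(vals) / n else NA_real_
    se <- if (n >= 2) sqrt(sum((vals - mu)^2) / (n - 1)) / sqrt(n) else NA_real_
    out[[paste(l, v)]] <- c(mean = mu, se = se, n = n)
  }
  out
}

oracle_pairwise_cor <- function(data, vars) {
  p <- length(vars)
  r <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    x <- data[[vars[i]]]; y <- data[[vars[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 2 && sd(x[ok]) > 0 && sd(y[ok]) > 0)
      r[i, j] <- sum((x[ok] - mean(x[ok])) * (y[ok] - mean(y[ok]))) /
        ((sum(ok) - 1) * sd(x[ok]) * sd(y[ok]))
  }
  r
}
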