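#' Specify a synthetic phenome
#'
#' Describes a generative phenotype database with known ground truth, so
#' every analysis in the package can be exercised offline: blocks of
#' variables with exchangeable within-block correlation, factor and
#' continuous subject attributes, additive group effects (optionally
#' monotone across ordered levels), reaction-time-like mean/SD variable
#' pairs with level-specific SD inflation, and completely-at-random
#' missingness.
#'
#' @param n_subjects number of subjects
#' @param blocks list of `list(m = <variable count>, rho = <within-block
#'   correlation in [0, 1)>)`; between-block correlation is 0
#' @param factors list of `list(name, levels, probs)` factor attributes
#' @param continuous list of `list(name, min, max)` continuous attributes
#' @param effects list of `list(attribute, levels (ordered), variables
#'   (name vector or glob), delta (additive shift in SD units), monotone)`;
#'   a monotone effect applies `delta, 2*delta, ...` across the ordered
#'   levels, a plain effect shifts the named level(s) by `delta`
#' @param pairs list of `list(stem, mean_base, sd_base, sd_mult)` where
#'   `sd_mult` is a named per-level SD inflation keyed by the level of
#'   `sd_mult_attribute`; generates `<stem>_MEANRT` / `<stem>_SDRT`
#'   columns on a reaction-time-like scale
#' @param sd_mult_attribute the factor attribute that keys `sd_mult`
#' @param missing_rate fraction of phenotype cells masked at random
#' @param seed integer seed; the same spec and seed always generate a
#'   byte-identical study
#' @return a `synth_spec` list
#' @export
synth_spec <- function(n_subjects,
                       blocks = list(),
                       factors = list(),
                       continuous = list(),
                       effects = list(),
                       pairs = list(),
                       sd_mult_attribute = NULL,
                       missing_rate = 0,
                       seed = 1L) {
  spec <- structure(
    list(n_subjects = as.integer(n_subjects), blocks = blocks,
         factors = factors, continuous = continuous, effects = effects,
         pairs = pairs, sd_mult_attribute = sd_mult_attribute,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "synth_spec")
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  if (is.na(spec$n_subjects) || spec$n_subjects < 1L)
    stop_viva("config", "synth_spec needs n_subjects >= 1")
  for (b in spec$blocks) {
    if (b$m < 1L) stop_viva("config", "block variable count must be >= 1")
    if (b$rho < 0 || b$rho >= 1)
      stop_viva("config", "block correlation rho must be in [0, 1)")
  }
  for (f in spec$factors) {
    if (abs(sum(f$probs) - 1) > 1e-8)
      stop_viva("config", sprintf(
        "factor %s level probabilities must sum to 1", sQuote(f$name)))
    if (length(f$probs) != length(f$levels))
      stop_viva("config", sprintf(
        "factor %s needs one probability per level", sQuote(f$name)))
  }
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stop_viva("config", "missing_rate must be in [0, 1)")
  invisible(spec)
}

#' Read or write a synth spec as JSON
#' @param path JSON file
#' @rdname synth_spec_io
#' @export
read_synth_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  do.call(synth_spec, x)
}

#' @param spec a `synth_spec`
#' @rdname synth_spec_io
#' @export
write_synth_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic phenotype study
#'
#' Base block variables are zero-mean unit-variance normals with
#' exchangeable within-block correlation `rho` (via a shared latent
#' factor: `x = sqrt(rho) * common + sqrt(1 - rho) * noise`) and zero
#' correlation between blocks. Mean/SD pairs are drawn positive on a
#' reaction-time-like scale (`mean_base` around 500, `sd_base` around 100,
#' log-normal subject variation) with the level-specific SD inflation
#' applied multiplicatively. Additive effects are applied in SD units of
#' the target variable. Missing cells are masked completely at random in
#' the phenotype columns (attributes stay complete). Every planted
#' quantity is recorded in the returned ground truth.
#'
#' @param spec a `synth_spec`
#' @return a `synth_study`: list with `table` (a `phenotype_table`),
#'   `dictionary`, `groups` (a `groups_config` with an `all` subset and a
#'   grouping per factor plus decade `Age` bins when an `Age` attribute
#'   exists), `truth` (planted block membership, effects, SD inflations,
#'   missing rate), and `spec`
#' @export
generate <- function(spec) {
  validate_synth_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_subjects

  ids <- sprintf("S%05d", seq_len(n))
  data <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  dict <- data.frame(name = "subject_id", label = "subject identifier",
                     kind = "identifier", units = "", source = "core",
                     stringsAsFactors = FALSE)
  add_var <- function(name, label, kind, units, source) {
    dict <<- rbind(dict, data.frame(name = name, label = label, kind = kind,
                                    units = units, source = source,
                                    stringsAsFactors = FALSE))
  }

  for (f in spec$factors) {
    data[[f$name]] <- sample(f$levels, n, replace = TRUE, prob = f$probs)
    add_var(f$name, f$name, "factor", "", "demographics")
  }
  binned <- list()   # <name>Bin views of binnable continuous attributes
  for (cv in spec$continuous) {
    data[[cv$name]] <- stats::runif(n, cv$min, cv$max)
    add_var(cv$name, cv$name, "numeric", "", "demographics")
    if (!is.null(cv$bin_edges))
      binned[[paste0(cv$name, "Bin")]] <-
        discretize(data[[cv$name]], cv$bin_edges, cv$bin_labels)
  }

  truth <- list(blocks = list(), effects = list(),
                pairs = list(), missing_rate = spec$missing_rate)

  phen_cols <- character(0)
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    common <- stats::rnorm(n)
    nms <- sprintf("B%02d_V%02d", bi, seq_len(b$m))
    for (j in seq_len(b$m)) {
      x <- sqrt(b$rho) * common + sqrt(1 - b$rho) * stats::rnorm(n)
      data[[nms[j]]] <- x
      add_var(nms[j], sprintf("block %d variable %d", bi, j), "numeric",
              "z", sprintf("block%02d", bi))
    }
    phen_cols <- c(phen_cols, nms)
    truth$blocks[[bi]] <- list(variables = nms, rho = b$rho)
  }

  for (pr in spec$pairs) {
    mean_base <- pr$mean_base %||% 500
    sd_base <- pr$sd_base %||% 100
    mv <- paste0(pr$stem, "_MEANRT")
    sv <- paste0(pr$stem, "_SDRT")
    mu <- mean_base + 0.1 * mean_base * stats::rnorm(n)
    sg <- sd_base * exp(0.25 * stats::rnorm(n))
    mult <- rep(1, n)
    if (!is.null(pr$sd_mult) && !is.null(spec$sd_mult_attribute)) {
      attr_col <- data[[spec$sd_mult_attribute]]
      hit <- attr_col %in% names(pr$sd_mult)
      mult[hit] <- as.numeric(unlist(pr$sd_mult))[
        match(attr_col[hit], names(pr$sd_mult))]
    }
    data[[mv]] <- mu
    data[[sv]] <- sg * mult
    add_var(mv, sprintf("%s mean reaction time", pr$stem), "numeric", "ms",
            pr$stem)
    add_var(sv, sprintf("%s reaction time SD", pr$stem), "numeric", "ms",
            pr$stem)
    phen_cols <- c(phen_cols, mv, sv)
    truth$pairs[[length(truth$pairs) + 1L]] <-
      list(stem = pr$stem, mean_var = mv, sd_var = sv,
           sd_mult = pr$sd_mult %||% list())
  }

  # additive effects in SD units of the target variable
  for (ef in spec$effects) {
    targets <- ef$variables
    if (length(targets) == 1L && grepl("*", targets, fixed = TRUE))
      targets <- dict$name[grepl(utils::glob2rx(targets), dict$name)]
    attr_col <- data[[ef$attribute]] %||% binned[[ef$attribute]]
    if (is.null(attr_col))
      stop_viva("config", sprintf("effect on unknown attribute %s",
                                  sQuote(ef$attribute)))
    ef$variables <- targets
    truth$effects[[length(truth$effects) + 1L]] <- ef
    for (v in targets) {
      sdv <- stats::sd(data[[v]])
      if (isTRUE(ef$monotone)) {
        for (k in seq_along(ef$levels)) {
          hit <- !is.na(attr_col) & attr_col == ef$levels[k]
          data[[v]][hit] <- data[[v]][hit] + k * ef$delta * sdv
        }
      } else {
        hit <- !is.na(attr_col) & attr_col %in% ef$levels
        data[[v]][hit] <- data[[v]][hit] + ef$delta * sdv
      }
    }
  }

  if (spec$missing_rate > 0 && length(phen_cols)) {
    for (v in phen_cols) {
      mask <- stats::runif(n) < spec$missing_rate
      data[[v]][mask] <- NA
    }
  }

  dictionary <- as_dictionary(dict)
  table <- new_phenotype_table(data, dictionary,
                               provenance = list(source = "synthetic",
                                                 cleaning_log = empty_log()))

  groups <- synth_groups_config(spec, dictionary)
  structure(list(table = table, dictionary = dictionary, groups = groups,
                 truth = truth, spec = spec),
            class = "synth_study")
}

empty_log <- function() {
  data.frame(subject = character(0), variable = character(0),
             original = character(0), action = character(0),
             stringsAsFactors = FALSE)
}

synth_groups_config <- function(spec, dictionary) {
  groupings <- list()
  for (f in spec$factors) {
    groupings[[f$name]] <- list(
      name = f$name, derivation = "factor",
      source_variable = f$name, levels = f$levels)
  }
  for (cv in spec$continuous) {
    if (!is.null(cv$bin_edges)) {
      groupings[[cv$name]] <- list(
        name = cv$name, derivation = "bins", source_variable = cv$name,
        edges = cv$bin_edges, labels = cv$bin_labels)
    }
  }
  subsets <- list(all = list(name = "all", predicate = list()))
  for (f in spec$factors) {
    for (l in f$levels) {
      nm <- paste0(f$name, "=", l)
      subsets[[nm]] <- list(name = nm, predicate = list(
        list(attribute = f$name, op = "=", value = l)))
    }
  }
  structure(list(subsets = subsets, groupings = groupings,
                 palettes = list()),
            class = "groups_config")
}

#' CNP-style synthetic study presets
#'
#' Ready-made [synth_spec()]s that emulate the statistical structure of a
#' neuropsychiatric phenomics database:
#' * an `Age` attribute (21-90, binned into 7 ordered decade ranges) with
#'   a planted monotone slowing of every mean reaction time with age;
#' * a `Diagnosis` attribute (`control` / `SZ`) with the schizophrenia
#'   group's reaction-time SDs inflated, so the planted coefficient of
#'   variation is higher in patients at every task;
#' * several blocks of correlated phenotype variables.
#'
#' `small` is 200 subjects and 20 phenotype variables (fast tests); `full`
#' is 1300 subjects and 150 phenotype variables.
#'
#' @param scale `"small"` or `"full"`
#' @param seed integer seed
#' @return a `synth_spec`
#' @export
cnp_like_preset <- function(scale = c("small", "full"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "full") {
    n <- 1300L
    blocks <- lapply(seq_len(13), function(i)
      list(m = 10L, rho = 0.6 + 0.02 * ((i - 1) %% 4)))
    stems <- c("SST", "CPT", "ANT", "SCWT", "DDT", "SR", "TS", "PRLT",
               "SMNM", "VMNM")
  } else {
    n <- 200L
    blocks <- list(list(m = 4L, rho = 0.7), list(m = 4L, rho = 0.7),
                   list(m = 4L, rho = 0.7))
    stems <- c("SST", "CPT", "ANT", "SCWT")
  }
  age_labels <- c("21-30", "31-40", "41-50", "51-60", "61-70", "71-80",
                  "81-90")
  pairs <- lapply(stems, function(s)
    list(stem = s, mean_base = 500, sd_base = 100,
         sd_mult = list(SZ = 1.5)))
  synth_spec(
    n_subjects = n,
    blocks = blocks,
    factors = list(
      list(name = "Diagnosis", levels = c("control", "SZ"),
           probs = c(0.8, 0.2)),
      list(name = "Gender", levels = c("Female", "Male"),
           probs = c(0.5, 0.5))),
    continuous = list(
      list(name = "Age", min = 21, max = 90,
           bin_edges = seq(20, 90, by = 10), bin_labels = age_labels)),
    effects = list(
      list(attribute = "AgeBin", levels = age_labels,
           variables = "*_MEANRT", delta = 0.5, monotone = TRUE),
      list(attribute = "Diagnosis", levels = "SZ",
           variables = "B01_V*", delta = 0.8, monotone = FALSE)),
    pairs = pairs,
    sd_mult_attribute = "Diagnosis",
    missing_rate = 0.05,
    seed = seed)
}

#' Write a synthetic study to disk as a drop-in CLI input
#'
#' Writes the data CSV, the dictionary TSV and the groups-config JSON so
#' the generated study can be fed straight back through [load_table()] and
#' the report commands.
#'
#' @param study a `synth_study` from [generate()]
#' @param dir output directory (created if needed)
#' @return (invisibly) named list of the three file paths
#' @export
write_synth_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(dir, "phenotypes.csv")
  dict_path <- file.path(dir, "dictionary.tsv")
  groups_path <- file.path(dir, "groups.json")
  write_table(study$table, data_path)
  write_dictionary(study$dictionary, dict_path)
  cfg <- study$groups
  jsonlite::write_json(
    list(subsets = cfg$subsets, groupings = cfg$groupings),
    groups_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(data = data_path, dictionary = dict_path,
                 groups = groups_path))
}
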