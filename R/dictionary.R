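#' Read a data dictionary
#'
#' The dictionary declares every column an input table may carry. Each
#' variable has a `name` (unique token), free-text `label`, a `kind`
#' (`numeric`, `factor` or `identifier`), free-text `units`, and a
#' `source` table name. JSON (array of objects) and TSV (one header row)
#' are accepted.
#'
#' @param path path to a `.json` or `.tsv` file, or a data.frame already in
#'   dictionary shape
#' @return a `data_dictionary`: a data.frame with columns
#'   `name`, `label`, `kind`, `units`, `source`
#' @export
read_dictionary <- function(path) {
  if (is.data.frame(path)) return(as_dictionary(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    d <- as.data.frame(d, stringsAsFactors = FALSE)
  } else {
    d <- utils::read.delim(path, colClasses = "character")
  }
  as_dictionary(d)
}

as_dictionary <- function(d) {
  if (inherits(d, "data_dictionary")) return(d)
  if (!is.data.frame(d))
    stop_viva("config", "dictionary must be a data.frame or a file path")
  for (col in c("label", "units", "source"))
    if (is.null(d[[col]])) d[[col]] <- ""
  need <- c("name", "label", "kind", "units", "source")
  miss <- setdiff(c("name", "kind"), names(d))
  if (length(miss))
    stop_viva("config", sprintf("dictionary lacks column(s): %s",
                                paste(miss, collapse = ", ")))
  d <- d[, need]
  if (anyDuplicated(d$name))
    stop_viva("config", sprintf("duplicate dictionary variable name %s",
                                sQuote(d$name[duplicated(d$name)][1])))
  bad <- setdiff(unique(d$kind), c("numeric", "factor", "identifier"))
  if (length(bad))
    stop_viva("config", sprintf("unknown dictionary kind(s): %s",
                                paste(bad, collapse = ", ")))
  if (sum(d$kind == "identifier") != 1L)
    stop_viva("config", "dictionary must declare exactly one identifier column")
  class(d) <- c("data_dictionary", "data.frame")
  d
}

dict_vars <- function(dictionary, kind) {
  dictionary$name[dictionary$kind %in% kind]
}

#' Write a data dictionary as TSV
#' @param dictionary a `data_dictionary`
#' @param path output file
#' @export
write_dictionary <- function(dictionary, path) {
  utils::write.table(as.data.frame(dictionary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a groups configuration
#'
#' The configuration names the population subsets (`S` in a formula) and
#' groupings (`G`). A subset is a conjunction of atomic conditions
#' `{attribute, op, value}` with `op` one of `=`, `!=`, `<`, `<=`, `>`,
#' `>=`, `in`; an empty condition list selects everyone. A grouping has a
#' `derivation`:
#' * `factor`: levels are the values of a factor attribute;
#' * `bins`: a continuous attribute cut at `edges` into ordered `labels`;
#' * `union`: each level is itself a subset predicate (levels must be
#'   disjoint on any table).
#'
#' @param path JSON file, or a list already in config shape
#' @return a `groups_config`: list with named lists `subsets`, `groupings`
#' @export
read_groups_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    path
  }
  subsets <- lapply(cfg$subsets %||% list(), validate_subset_def)
  groupings <- lapply(cfg$groupings %||% list(), validate_grouping)
  # propagate list names into the definitions
  for (nm in names(subsets)) subsets[[nm]]$name <- nm
  for (nm in names(groupings)) groupings[[nm]]$name <- nm
  structure(list(subsets = subsets, groupings = groupings,
                 palettes = cfg$palettes %||% list()),
            class = "groups_config")
}

validate_subset_def <- function(s) {
  preds <- lapply(s$predicate %||% list(), function(p) {
    if (is.null(p$attribute) || is.null(p$op))
      stop_viva("config", "subset condition needs 'attribute' and 'op'")
    if (!p$op %in% c("=", "!=", "<", "<=", ">", ">=", "in"))
      stop_viva("config", sprintf("unknown subset comparator %s", sQuote(p$op)))
    list(attribute = p$attribute, op = p$op, value = unlist(p$value))
  })
  list(name = s$name %||% "", predicate = preds)
}

validate_grouping <- function(g) {
  der <- g$derivation %||% "factor"
  if (!der %in% c("factor", "bins", "union"))
    stop_viva("config", sprintf("unknown grouping derivation %s", sQuote(der)))
  if (der == "bins") {
    edges <- as.numeric(unlist(g$edges))
    labels <- as.character(unlist(g$labels))
    if (any(diff(edges) <= 0))
      stop_viva("config", "grouping bin edges must be strictly increasing")
    if (length(labels) != length(edges) - 1L)
      stop_viva("config", "grouping needs one label per bin interval")
    g$edges <- edges; g$labels <- labels
  }
  if (der == "factor" && !is.null(g$levels))
    g$levels <- as.character(unlist(g$levels))
  if (der == "union") {
    if (is.null(g$levels) || !length(g$levels))
      stop_viva("config", "union grouping needs a named list of level predicates")
  }
  g$derivation <- der
  g
}

#' Color palettes for group levels
#'
#' `"default"` is a colorblind-safe ordered palette (Okabe-Ito); `"cnp"`
#' carries the diagnosis colors used in neuropsychiatric phenomics
#' displays (controls light orange, ADHD blue, bipolar red, schizophrenia
#' purple).
#'
#' @param name palette name
#' @param n number of colors (recycled if needed)
#' @export
viva_palette <- function(name = "default", n = NULL) {
  pal <- switch(name,
    default = c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
                "#0072B2", "#D55E00", "#CC79A7", "#000000"),
    cnp = c(control = "#FDB863", ADHD = "#4575B4",
            BP = "#D73027", SZ = "#7B3294"),
    stop_viva("config", sprintf("unknown palette %s", sQuote(name))))
  if (!is.null(n)) pal <- rep_len(pal, n)
  pal
}
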