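#' Variance-structure model formulas
#'
#' A variance-structure model is a five-part specification of a rough
#' hypothesis, written on one line as
#'
#' ```
#' M: Y ~ X | G : (S)
#' ```
#'
#' where `M` names the analysis or visualization method (e.g. `VISOVA`,
#' `PCA`, `Correlation`), `Y` is a (possibly empty) comma-separated list of
#' dependent variable patterns, `X` is a non-empty comma-separated list of
#' independent variable patterns, `G` names a grouping (a factor partition
#' of subjects), and `S` names a population subset. `M:`, `Y`, `| G` and
#' `: (S)` are each optional; the `~` separator is mandatory. Variable
#' names may contain spaces; commas are the only list separator; patterns
#' may use glob-style `*` wildcards. An empty `Y` means all listed
#' variables are treated as independent.
#'
#' @name variance_model
#' @examples
#' m <- parse_model("VISOVA: ~ ReactionTime | Age : (LA2K control)")
#' m$independents   # "ReactionTime"
#' format(m)
NULL

#' Methods a formula may dispatch to
#'
#' The method registry is open: unknown methods parse (formulas stay
#' forward-compatible) but fail at dispatch time in [run_explore()].
#' @return character vector of method names understood by the report layer
#' @export
registered_methods <- function() {
  c("VISOVA", "PCA", "Correlation", "Covariance")
}

#' Parse a variance-structure model string
#'
#' @param text a single-line model formula, grammar `[M :] [Y] ~ X [| G] [: ( S )]`.
#' @return an object of class `variance_model`: a list with fields
#'   `method`, `dependents`, `independents`, `grouping`, `subset`.
#'   Omitted parts are `character(0)` (lists) or `""` (names); an omitted
#'   method defaults to `"VISOVA"`.
#' @export
parse_model <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop_viva("parse", "model formula must be a single character string")
  if (grepl("[\r\n]", text))
    stop_viva("parse", "model formula must be a single line")

  if (!grepl("~", text, fixed = TRUE))
    stop_viva("parse", sprintf(
      "missing '~' separator in model formula: %s", sQuote(trimws(text))))
  # only one ~ permitted
  if (lengths(regmatches(text, gregexpr("~", text, fixed = TRUE))) > 1L)
    stop_viva("parse", "more than one '~' in model formula")

  parts <- strsplit(text, "~", fixed = TRUE)[[1]]
  lhs <- if (length(parts) >= 1L) parts[1] else ""
  rhs <- if (length(parts) >= 2L) parts[2] else ""

  # left of '~': optional "M :" prefix, then optional Y list
  lhs <- trimws(lhs)
  if (grepl(":", lhs, fixed = TRUE)) {
    i <- regexpr(":", lhs, fixed = TRUE)
    method <- trimws(substr(lhs, 1L, i - 1L))
    ytext  <- trimws(substr(lhs, i + 1L, nchar(lhs)))
  } else {
    method <- "VISOVA"
    ytext  <- lhs
  }
  if (method == "")
    stop_viva("parse", "empty method name before ':'")
  dependents <- split_varlist(ytext)

  # right of '~': X [| G] [: ( S )]
  rhs <- trimws(rhs)
  subset_name <- ""
  # subset clause: last ':' followed by a parenthesised name at end of line
  sm <- regexpr(":\\s*\\(", rhs)
  if (sm > 0L) {
    stext <- trimws(substr(rhs, sm + attr(sm, "match.length") - 1L, nchar(rhs)))
    rhs <- trimws(substr(rhs, 1L, sm - 1L))
    if (!grepl("^\\(", stext) || !grepl("\\)$", stext) ||
        nchar(gsub("[^(]", "", stext)) != nchar(gsub("[^)]", "", stext)))
      stop_viva("parse", "unbalanced parentheses in subset clause")
    subset_name <- trimws(substr(stext, 2L, nchar(stext) - 1L))
  } else if (grepl("[()]", rhs)) {
    stop_viva("parse", "unbalanced parentheses in subset clause")
  }

  grouping <- ""
  if (grepl("|", rhs, fixed = TRUE)) {
    gi <- regexpr("|", rhs, fixed = TRUE)
    grouping <- trimws(substr(rhs, gi + 1L, nchar(rhs)))
    rhs <- trimws(substr(rhs, 1L, gi - 1L))
    if (grouping == "")
      stop_viva("parse", "empty grouping name after '|'")
  }

  independents <- split_varlist(rhs)
  if (length(independents) == 0L)
    stop_viva("parse", "model formula has no independent variables (empty X)")

  structure(
    list(method = method, dependents = dependents,
         independents = independents, grouping = grouping,
         subset = subset_name),
    class = "variance_model")
}

split_varlist <- function(text) {
  if (is.na(text) || trimws(text) == "") return(character(0))
  out <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  if (any(out == ""))
    stop_viva("parse", "empty entry in comma-separated variable list")
  out
}

#' Serialize a variance model back to its formula string
#'
#' `parse_model(format(m))` always reproduces `m` exactly (round-trip).
#'
#' @param x a `variance_model`
#' @param ... ignored
#' @export
format.variance_model <- function(x, ...) {
  out <- paste0(x$method, ": ")
  if (length(x$dependents)) out <- paste0(out, paste(x$dependents, collapse = ", "), " ")
  out <- paste0(out, "~ ", paste(x$independents, collapse = ", "))
  if (nzchar(x$grouping)) out <- paste0(out, " | ", x$grouping)
  if (nzchar(x$subset))   out <- paste0(out, " : (", x$subset, ")")
  out
}

#' @export
print.variance_model <- function(x, ...) {
  cat("<variance_model> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Resolve a variance model against a data dictionary and groups config
#'
#' Expands `*` wildcard patterns to concrete variable names (dictionary
#' order is preserved within each pattern), and resolves grouping and
#' subset names against the configuration. Dependent and independent
#' variable sets must be disjoint after expansion.
#'
#' @param model a `variance_model`
#' @param dictionary a `data_dictionary` (see [read_dictionary()])
#' @param config a `groups_config` (see [read_groups_config()])
#' @return an object of class `resolved_model` with fields `model`,
#'   `dependent_vars`, `independent_vars`, `grouping_def`, `subset_def`.
#' @export
resolve_model <- function(model, dictionary, config) {
  stopifnot(inherits(model, "variance_model"))
  dictionary <- as_dictionary(dictionary)

  dep <- expand_patterns(model$dependents, dictionary)
  ind <- expand_patterns(model$independents, dictionary)
  both <- intersect(dep, ind)
  if (length(both))
    stop_viva("resolve", sprintf(
      "variables appear as both dependent and independent: %s",
      paste(both, collapse = ", ")))

  grouping_def <- NULL
  if (nzchar(model$grouping)) {
    grouping_def <- config$groupings[[model$grouping]]
    if (is.null(grouping_def))
      stop_viva("resolve", sprintf(
        "unknown grouping %s; known groupings: %s", sQuote(model$grouping),
        paste(names(config$groupings), collapse = ", ")))
  }
  subset_def <- NULL
  if (nzchar(model$subset)) {
    subset_def <- config$subsets[[model$subset]]
    if (is.null(subset_def))
      stop_viva("resolve", sprintf(
        "unknown subset %s; known subsets: %s", sQuote(model$subset),
        paste(names(config$subsets), collapse = ", ")))
  }

  structure(
    list(model = model, dependent_vars = dep, independent_vars = ind,
         grouping_def = grouping_def, subset_def = subset_def),
    class = "resolved_model")
}

# expand glob patterns against dictionary variable names, preserving
# dictionary order within each pattern; duplicates collapse to first use
expand_patterns <- function(patterns, dictionary) {
  vars <- dictionary$name
  out <- character(0)
  for (p in patterns) {
    if (grepl("*", p, fixed = TRUE)) {
      hits <- vars[grepl(utils::glob2rx(p), vars)]
    } else {
      hits <- vars[vars == p]
    }
    if (length(hits) == 0L)
      stop_viva("resolve", sprintf(
        "pattern %s matches no dictionary variable", sQuote(p)))
    out <- c(out, hits)
  }
  out[!duplicated(out)]
}

#' Read a hypothesis catalogue
#'
#' A catalogue is a JSON list of `{name, formula, notes}` entries used by
#' [run_atlas()]. Names must be unique and every formula must parse.
#'
#' @param path JSON file, or a list already in that shape
#' @return list of entries, each with `name`, `formula`, `notes`, and the
#'   parsed `model`
#' @export
read_catalogue <- function(path) {
  entries <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    path
  }
  nm <- vapply(entries, function(e) e$name %||% "", "")
  if (any(nm == "")) stop_viva("config", "catalogue entry without a name")
  if (anyDuplicated(nm))
    stop_viva("config", sprintf("duplicate catalogue entry name %s",
                                sQuote(nm[duplicated(nm)][1])))
  lapply(entries, function(e) {
    e$model <- parse_model(e$formula)
    e$notes <- e$notes %||% ""
    e
  })
}
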