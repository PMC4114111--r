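#' Cleaning policy for table loading
#'
#' Declarative rules applied by [load_table()]. Every altered cell is
#' recorded in the cleaning log, so the cleaned table is auditable.
#'
#' @param missing_codes strings treated as missing in any column
#' @param numeric_missing_codes numeric sentinel codes (e.g. `-999`)
#'   treated as missing in numeric columns
#' @param ranges named list of `c(min, max)` hard limits per numeric
#'   variable; values outside are set missing and logged
#' @export
cleaning_policy <- function(missing_codes = c("", "NA"),
                            numeric_missing_codes = numeric(0),
                            ranges = list()) {
  structure(list(missing_codes = missing_codes,
                 numeric_missing_codes = numeric_missing_codes,
                 ranges = ranges),
            class = "cleaning_policy")
}

#' Load a subjects-by-variables phenotype table
#'
#' Reads a CSV/TSV file with one header row and one row per subject,
#' validates every column against the data dictionary, parses numeric
#' columns with locale-independent rules, and applies the cleaning policy.
#' Missing values are represented by the single canonical sentinel `NA`.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension,
#'   override with `sep`)
#' @param dictionary a `data_dictionary`
#' @param cleaning a [cleaning_policy()]
#' @param permissive if `TRUE`, undeclared columns are skipped with a
#'   warning instead of aborting the load
#' @param sep field separator; default `","` for `.csv`, `"\t"` otherwise
#' @return a `phenotype_table`: list with `data` (data.frame, one row per
#'   subject), `subject_ids`, `dictionary`, and `provenance` (source path
#'   plus a cleaning log with one row per altered cell)
#' @export
load_table <- function(path, dictionary, cleaning = cleaning_policy(),
                       permissive = FALSE, sep = NULL) {
  dictionary <- as_dictionary(dictionary)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) != 1L)
    stop_viva("load", sprintf(
      "ragged file: rows have %s fields", paste(unique(nf), collapse = "/")))

  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "")
  undeclared <- setdiff(names(raw), dictionary$name)
  if (length(undeclared)) {
    if (!permissive)
      stop_viva("load", sprintf("undeclared column(s): %s",
                                paste(undeclared, collapse = ", ")))
    warn_viva("load", sprintf("skipping undeclared column(s): %s",
                              paste(undeclared, collapse = ", ")))
    raw <- raw[, setdiff(names(raw), undeclared), drop = FALSE]
  }

  id_col <- dict_vars(dictionary, "identifier")
  if (!id_col %in% names(raw))
    stop_viva("load", sprintf("identifier column %s not in file", sQuote(id_col)))
  ids <- raw[[id_col]]
  if (anyDuplicated(ids))
    stop_viva("load", sprintf("duplicate subject id %s",
                              sQuote(ids[duplicated(ids)][1])))

  log <- list()
  add_log <- function(subject, variable, original, action) {
    log[[length(log) + 1L]] <<- data.frame(
      subject = subject, variable = variable,
      original = as.character(original), action = action,
      stringsAsFactors = FALSE)
  }

  data <- data.frame(row.names = seq_along(ids))
  for (v in names(raw)) {
    kind <- dictionary$kind[dictionary$name == v]
    col <- raw[[v]]
    is_code <- col %in% cleaning$missing_codes
    if (any(is_code) && v != id_col) {
      for (i in which(is_code)) add_log(ids[i], v, col[i], "missing-code")
      col[is_code] <- NA_character_
    }
    if (kind == "numeric") {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      for (i in bad) add_log(ids[i], v, col[i], "unparseable")
      if (length(cleaning$numeric_missing_codes)) {
        code <- which(num %in% cleaning$numeric_missing_codes)
        for (i in code) add_log(ids[i], v, col[i], "numeric-missing-code")
        num[num %in% cleaning$numeric_missing_codes] <- NA_real_
      }
      rng <- cleaning$ranges[[v]]
      if (!is.null(rng)) {
        out <- which(!is.na(num) & (num < rng[1] | num > rng[2]))
        for (i in out) add_log(ids[i], v, col[i], "out-of-range")
        num[out] <- NA_real_
      }
      data[[v]] <- num
    } else {
      data[[v]] <- col
    }
  }

  log <- if (length(log)) do.call(rbind, log) else
    data.frame(subject = character(0), variable = character(0),
               original = character(0), action = character(0),
               stringsAsFactors = FALSE)

  new_phenotype_table(data, dictionary,
                      provenance = list(source = path, cleaning_log = log))
}

new_phenotype_table <- function(data, dictionary, provenance = NULL) {
  dictionary <- as_dictionary(dictionary)
  id_col <- dict_vars(dictionary, "identifier")
  if (!id_col %in% names(data))
    stop_viva("load", sprintf("table lacks identifier column %s", sQuote(id_col)))
  if (anyDuplicated(data[[id_col]]))
    stop_viva("load", "duplicate subject ids")
  undeclared <- setdiff(names(data), dictionary$name)
  if (length(undeclared))
    stop_viva("load", sprintf("undeclared column(s): %s",
                              paste(undeclared, collapse = ", ")))
  structure(
    list(data = data,
         subject_ids = as.character(data[[id_col]]),
         dictionary = dictionary,
         provenance = provenance %||%
           list(source = "<memory>",
                cleaning_log = data.frame(subject = character(0),
                                          variable = character(0),
                                          original = character(0),
                                          action = character(0),
                                          stringsAsFactors = FALSE))),
    class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> %d subjects x %d variables (%d cleaning log entries)\n",
              nrow(x$data), ncol(x$data) - 1L, nrow(x$provenance$cleaning_log)))
  invisible(x)
}

#' @export
dim.phenotype_table <- function(x) dim(x$data)

#' Number of subjects in a table
#' @param table a `phenotype_table`
#' @export
n_subjects <- function(table) length(table$subject_ids)

#' Numeric phenotype variables of a table
#' @param table a `phenotype_table`
#' @param source restrict to variables from one source table
#' @export
numeric_vars <- function(table, source = NULL) {
  d <- table$dictionary
  keep <- d$kind == "numeric" & d$name %in% names(table$data)
  if (!is.null(source)) keep <- keep & d$source == source
  d$name[keep]
}

# numeric matrix over the given variables, rows aligned to subjects
table_matrix <- function(table, variables) {
  miss <- setdiff(variables, names(table$data))
  if (length(miss))
    stop_viva("resolve", sprintf("variable(s) not in table: %s",
                                 paste(miss, collapse = ", ")))
  kinds <- table$dictionary$kind[match(variables, table$dictionary$name)]
  if (any(kinds != "numeric"))
    stop_viva("resolve", sprintf("non-numeric variable(s): %s",
              paste(variables[kinds != "numeric"], collapse = ", ")))
  m <- as.matrix(table$data[, variables, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$subject_ids
  m
}

#' Write a phenotype table as CSV
#'
#' The written file reloads (with the same dictionary) to an identical
#' table: numbers are printed at full precision.
#'
#' @param table a `phenotype_table`
#' @param path output CSV file
#' @export
write_table <- function(table, path) {
  out <- table$data
  for (v in names(out))
    if (is.numeric(out[[v]]))
      out[[v]] <- ifelse(is.na(out[[v]]), NA,
                         sprintf("%.17g", out[[v]]))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Restrict a table to a population subset
#'
#' Keeps exactly the subjects that satisfy every atomic condition of the
#' subset predicate; subjects with a missing value in any predicate
#' attribute are excluded. Subject order is preserved. Applying the same
#' subset twice equals applying it once (idempotent).
#'
#' @param table a `phenotype_table`
#' @param subset a subset definition (see [read_groups_config()]); an
#'   empty predicate returns the table unchanged
#' @export
apply_subset <- function(table, subset) {
  keep <- rep(TRUE, n_subjects(table))
  for (p in subset$predicate %||% list()) {
    col <- table$data[[p$attribute]]
    if (is.null(col))
      stop_viva("resolve", sprintf("subset condition on unknown attribute %s",
                                   sQuote(p$attribute)))
    val <- p$value
    if (is.numeric(col)) val <- as.numeric(val)
    ok <- switch(p$op,
                 "="  = col == val,
                 "!=" = col != val,
                 "<"  = col <  val,
                 "<=" = col <= val,
                 ">"  = col >  val,
                 ">=" = col >= val,
                 "in" = col %in% val)
    ok[is.na(ok)] <- FALSE
    # %in% maps NA to FALSE already; make missingness exclusion uniform
    ok[is.na(col)] <- FALSE
    keep <- keep & ok
  }
  sub <- table
  sub$data <- table$data[keep, , drop = FALSE]
  rownames(sub$data) <- NULL
  sub$subject_ids <- table$subject_ids[keep]
  sub
}

#' Cut a continuous variable into ordered labelled intervals
#'
#' Intervals follow the convention behind labels like `"21-30"` /
#' `"41-50"`: each interval is left-open/right-closed `(edge_i,
#' edge_(i+1)]`, with the first interval additionally closed at its left
#' edge. Values outside all intervals map to `NA` (unassigned).
#'
#' @param values numeric vector
#' @param edges strictly increasing cut points (length = intervals + 1)
#' @param labels one label per interval, in order
#' @return character vector of labels, `NA` where unassigned
#' @export
discretize <- function(values, edges, labels) {
  if (any(diff(edges) <= 0))
    stop_viva("config", "discretize edges must be strictly increasing")
  if (length(labels) != length(edges) - 1L)
    stop_viva("config", "discretize needs one label per interval")
  as.character(cut(values, breaks = edges, labels = labels,
                   right = TRUE, include.lowest = TRUE))
}

#' Assign subjects to grouping levels
#'
#' Each subject maps to exactly one level or to unassigned (`NA`).
#' Unassigned subjects are excluded from profile computation but stay in
#' the table. For a `union` grouping, overlapping level predicates are a
#' configuration error detected here.
#'
#' @param table a `phenotype_table`
#' @param grouping a grouping definition (see [read_groups_config()]), or
#'   `NULL` for a single all-subjects level
#' @return a `group_assignment`: list with `levels` (ordered labels),
#'   `colors`, `assignment` (character per subject, `NA` = unassigned) and
#'   `counts`
#' @export
assign_groups <- function(table, grouping = NULL) {
  n <- n_subjects(table)
  if (is.null(grouping)) {
    return(new_group_assignment("all subjects",
                                rep("all subjects", n), table, NULL))
  }
  der <- grouping$derivation %||% "factor"
  if (der == "factor") {
    col <- table$data[[grouping$source_variable]]
    if (is.null(col))
      stop_viva("resolve", sprintf("grouping source variable %s not in table",
                                   sQuote(grouping$source_variable)))
    levels <- grouping$levels %||% sort(unique(col[!is.na(col)]))
    assignment <- ifelse(col %in% levels, as.character(col), NA_character_)
  } else if (der == "bins") {
    col <- table$data[[grouping$source_variable]]
    if (is.null(col))
      stop_viva("resolve", sprintf("grouping source variable %s not in table",
                                   sQuote(grouping$source_variable)))
    levels <- grouping$labels
    assignment <- discretize(as.numeric(col), grouping$edges, grouping$labels)
  } else { # union of subset predicates
    levels <- names(grouping$levels)
    member <- vapply(grouping$levels, function(pred) {
      sub <- apply_subset(table, list(predicate = pred))
      table$subject_ids %in% sub$subject_ids
    }, logical(n))
    member <- matrix(member, nrow = n)
    overlap <- rowSums(member) > 1L
    if (any(overlap))
      stop_viva("config", sprintf(
        "union grouping %s: %d subject(s) match more than one level",
        sQuote(grouping$name %||% "?"), sum(overlap)))
    assignment <- rep(NA_character_, n)
    for (j in seq_along(levels))
      assignment[member[, j]] <- levels[j]
  }
  new_group_assignment(levels, assignment, table, grouping)
}

new_group_assignment <- function(levels, assignment, table, grouping) {
  counts <- vapply(levels, function(l) sum(assignment == l, na.rm = TRUE), 0L)
  colors <- grouping$colors %||% NULL
  if (is.null(colors)) {
    pal <- viva_palette("default", length(levels))
    colors <- stats::setNames(pal, levels)
  } else {
    colors <- stats::setNames(as.character(unlist(colors)), levels)
  }
  structure(list(levels = levels, colors = colors,
                 assignment = assignment,
                 subject_ids = table$subject_ids,
                 counts = counts,
                 grouping_name = grouping$name %||% "all"),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> %s: %s (unassigned: %d)\n",
              x$grouping_name,
              paste(sprintf("%s=%d", x$levels, x$counts), collapse = ", "),
              sum(is.na(x$assignment))))
  invisible(x)
}
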