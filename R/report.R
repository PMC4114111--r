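#' Run one variance-structure model and write a report directory
#'
#' The exploration entry point: loads the inputs (paths or in-memory
#' objects), parses and resolves the formula, applies the subset and
#' grouping, detects mean/SD pairs and augments the table with CV/SNR/FF
#' measures, and dispatches on the formula's method:
#' * `VISOVA`: correlation clustering for the column order, group
#'   profiles, and a parallel-coordinates figure;
#' * `Correlation` / `Covariance`: a clustered correlation heatmap;
#' * `PCA`: pairwise projection panels plus a 3D view and an
#'   explained-variance table.
#'
#' Numeric tables (`profiles.tsv`, `correlation.tsv`, `explained.tsv` as
#' applicable) are always written beside the figures, plus a
#' `manifest.json` recording the resolved model, figure hashes, subject
#' counts per level and every warning raised by lower modules. Inputs are
#' fully validated before anything is written, so a failing run leaves no
#' partial output directory. No p-values are computed anywhere: standard
#' errors and counts are the only inferential quantities shown.
#'
#' @param data a `phenotype_table` or CSV/TSV path
#' @param dictionary a `data_dictionary` or path (ignored if `data` is a
#'   table)
#' @param groups_config a `groups_config` or JSON path
#' @param formula a model formula string or `variance_model`
#' @param outdir output directory (created)
#' @param options list: `axis_scaling`, `linkage_method`, `distance`,
#'   `corr_method`, `format` (`"svg"`/`"png"`), `se_mult`, `max_subjects`,
#'   `augment` (default `TRUE`), `pair_overrides`
#' @return (invisibly) the manifest as a list
#' @export
run_explore <- function(data, dictionary, groups_config, formula,
                        outdir, options = list()) {
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  cfg <- if (inherits(groups_config, "groups_config")) groups_config else
    read_groups_config(groups_config)
  dict <- if (inherits(data, "phenotype_table")) data$dictionary else
    read_dictionary(dictionary)
  table <- if (inherits(data, "phenotype_table")) data else
    collect(load_table(data, dict, options$cleaning %||% cleaning_policy()))

  model <- if (inherits(formula, "variance_model")) formula else
    parse_model(formula)
  if (!model$method %in% registered_methods())
    stop_viva("dispatch", sprintf(
      "unknown method %s; registered methods: %s", sQuote(model$method),
      paste(registered_methods(), collapse = ", ")))

  if (isTRUE(options$augment %||% TRUE)) {
    pairs <- detect_pairs(table$dictionary,
                          overrides = options$pair_overrides)
    new <- setdiff(
      as.vector(outer(pairs$stem, c("CV", "SNR", "FF"), paste, sep = "_")),
      names(table$data))
    if (nrow(pairs) && length(new) ==
          nrow(pairs) * 3L)   # skip if already augmented
      table <- collect(augment_variability(table, pairs))
  }

  resolved <- resolve_model(model, table$dictionary, cfg)

  sub <- if (!is.null(resolved$subset_def))
    apply_subset(table, resolved$subset_def) else table
  if (n_subjects(sub) == 0L)
    stop_viva("empty_subset", sprintf(
      "subset %s leaves no subjects", sQuote(model$subset)))
  assignment <- collect(assign_groups(sub, resolved$grouping_def))

  variables <- c(resolved$dependent_vars, resolved$independent_vars)
  kinds <- sub$dictionary$kind[match(variables, sub$dictionary$name)]
  variables <- variables[kinds == "numeric"]
  if (length(variables) == 0L)
    stop_viva("resolve", "model selects no numeric variables")

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fmt <- options$format %||% "svg"
  figures <- list()
  tables <- character(0)

  profiles <- collect(group_profiles(sub, assignment, variables))
  write_profile(profiles, file.path(outdir, "profiles.tsv"))
  tables <- c(tables, "profiles.tsv")

  corr <- NULL; ordering <- NULL
  if (length(variables) >= 2L) {
    corr <- collect(correlation_matrix(
      sub, variables, options$corr_method %||% "pearson"))
    write_corr(corr, file.path(outdir, "correlation.tsv"))
    tables <- c(tables, "correlation.tsv")
    ordering <- collect(cluster_variables(
      corr, options$linkage_method %||% "average",
      options$distance %||% "1-r"))
  } else {
    ordering <- structure(
      list(variables = variables, leaf_order = variables, leaf_index = 1L,
           merge = matrix(integer(0), 0, 2), height = numeric(0),
           linkage_method = "average", distance = "1-r"),
      class = "variable_ordering")
    warnings_seen <- c(warnings_seen,
                       "single-variable model: degenerate ordering")
  }

  if (model$method == "VISOVA") {
    spec <- collect(build_visova(sub, assignment, profiles, ordering,
                                 options))
    figures <- c(figures, list(collect(render_figure(
      spec, file.path(outdir, paste0("visova.", fmt)), fmt))))
    if (!is.null(corr)) {
      hm <- build_corr_heatmap(corr, ordering)
      figures <- c(figures, list(collect(render_figure(
        hm, file.path(outdir, paste0("correlation.", fmt)), fmt))))
    }
  } else if (model$method %in% c("Correlation", "Covariance")) {
    if (is.null(corr))
      stop_viva("resolve", "correlation heatmap needs >= 2 variables")
    hm <- build_corr_heatmap(corr, ordering)
    figures <- c(figures, list(collect(render_figure(
      hm, file.path(outdir, paste0("correlation.", fmt)), fmt))))
  } else if (model$method == "PCA") {
    pca <- collect(pca_projection(sub, variables,
                                  scaling = options$pca_scaling %||%
                                    "correlation"))
    dims <- min(3L, ncol(pca$scores))
    views <- collect(build_pca_views(pca, assignment, dims))
    figures <- c(figures, list(collect(render_figure(
      views, file.path(outdir, paste0("pca.", fmt)), fmt))))
    expl <- data.frame(component = seq_along(pca$explained_all),
                       explained = fmt_num(pca$explained_all, 10))
    utils::write.table(expl, file.path(outdir, "explained.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tables <- c(tables, "explained.tsv")
    if (pca$n_dropped > 0)
      warnings_seen <- c(warnings_seen, sprintf(
        "PCA dropped %d incomplete subject(s)", pca$n_dropped))
  }

  manifest <- list(
    formula = format(model),
    method = model$method,
    variables = variables,
    grouping = model$grouping,
    subset = model$subset,
    levels = assignment$levels,
    counts = as.list(stats::setNames(as.integer(assignment$counts),
                                     assignment$levels)),
    unassigned = sum(is.na(assignment$assignment)),
    n_subjects = n_subjects(sub),
    cleaning_log_entries = nrow(sub$provenance$cleaning_log),
    missing_policy = list(
      profiles = "per-cell (each mean uses all non-missing values)",
      correlation = "pairwise-complete",
      pca = "complete-case"),
    tables = tables,
    figures = figures,
    warnings = warnings_seen)
  write_manifest(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rapid whole-table exploration
#'
#' Equivalent to [run_explore()] with the formula
#' `VISOVA: ~ <all numeric variables of the source table> | <grouping> : (all)`.
#' With no grouping, a single all-subjects level gives one profile line.
#'
#' @param data,dictionary,groups_config as in [run_explore()]
#' @param table_name source-table name from the dictionary (`NULL` = all
#'   numeric variables)
#' @param grouping grouping name, or `NULL` for a single level
#' @param outdir output directory
#' @param options as in [run_explore()]
#' @export
run_viewer <- function(data, dictionary, groups_config, table_name = NULL,
                       grouping = NULL, outdir, options = list()) {
  dict <- if (inherits(data, "phenotype_table")) data$dictionary else
    read_dictionary(dictionary)
  keep <- dict$kind == "numeric"
  if (!is.null(table_name)) keep <- keep & dict$source == table_name
  vars <- dict$name[keep]
  if (length(vars) == 0L)
    stop_viva("resolve", sprintf("no numeric variables in table %s",
                                 sQuote(table_name %||% "<all>")))
  if (length(vars) == 1L)
    warn_viva("render", "single-variable table: degenerate one-axis display")
  cfg <- if (inherits(groups_config, "groups_config")) groups_config else
    read_groups_config(groups_config)
  if (!"all" %in% names(cfg$subsets))
    cfg$subsets$all <- list(name = "all", predicate = list())
  formula <- sprintf("VISOVA: ~ %s%s : (all)",
                     paste(vars, collapse = ", "),
                     if (is.null(grouping)) "" else paste0(" | ", grouping))
  run_explore(data, dictionary, cfg, formula, outdir,
              c(options, list(augment = FALSE)))
}

#' Build an atlas: a static report site over a hypothesis catalogue
#'
#' The catalogue (all formulas are parsed up front) is run entry by entry
#' into `outdir/<entry name>/`; an individual entry's failure is recorded
#' in the site manifest and never aborts the batch or alters other
#' entries. An `index.html` links every section. Reruns on identical
#' inputs produce byte-identical figures and manifest hashes.
#'
#' @param data,dictionary,groups_config as in [run_explore()]
#' @param catalogue a catalogue list or JSON path (see [read_catalogue()])
#' @param outdir output directory
#' @param options as in [run_explore()]
#' @return (invisibly) the site manifest
#' @export
run_atlas <- function(data, dictionary, groups_config, catalogue, outdir,
                      options = list()) {
  entries <- read_catalogue(catalogue)
  if (!dir.exists(dirname(outdir)) && dirname(outdir) != ".")
    stop_viva("io", sprintf("parent of output directory does not exist: %s",
                            dirname(outdir)))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  sections <- list()
  for (e in entries) {
    entry_dir <- file.path(outdir, gsub("[^A-Za-z0-9_.-]", "_", e$name))
    res <- tryCatch(
      list(ok = TRUE,
           manifest = run_explore(data, dictionary, groups_config,
                                  e$formula, entry_dir, options)),
      error = function(err)
        list(ok = FALSE, error = conditionMessage(err)))
    sections[[e$name]] <- c(list(name = e$name, formula = e$formula,
                                 notes = e$notes, dir = basename(entry_dir)),
                            res)
  }

  site <- list(entries = sections,
               n_ok = sum(vapply(sections, function(s) isTRUE(s$ok), TRUE)),
               n_failed = sum(vapply(sections,
                                     function(s) !isTRUE(s$ok), TRUE)))
  write_manifest(site, file.path(outdir, "manifest.json"))
  write_atlas_index(site, file.path(outdir, "index.html"))
  invisible(site)
}

write_atlas_index <- function(site, path) {
  esc <- function(s) svg_escape(s)
  lines <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>Atlas</title>",
    "<style>body{font-family:sans-serif;max-width:70em;margin:2em auto}",
    "img,object{max-width:100%}code{background:#eee;padding:1px 4px}",
    ".fail{color:#A50026}</style></head><body>",
    "<h1>Hypothesis atlas</h1>",
    sprintf("<p>%d section(s), %d failed.</p>", length(site$entries),
            site$n_failed))
  for (s in site$entries) {
    lines <- c(lines, sprintf("<h2>%s</h2>", esc(s$name)),
               sprintf("<p><code>%s</code> %s</p>", esc(s$formula),
                       esc(s$notes %||% "")))
    if (isTRUE(s$ok)) {
      m <- s$manifest
      cnt <- paste(sprintf("%s=%d", names(m$counts), unlist(m$counts)),
                   collapse = ", ")
      lines <- c(lines,
        sprintf("<p>%d subjects; groups: %s; unassigned: %d</p>",
                m$n_subjects, esc(cnt), m$unassigned))
      for (f in m$figures)
        lines <- c(lines, sprintf(
          "<p><object data=\"%s/%s\" type=\"image/svg+xml\"></object></p>",
          esc(s$dir), esc(f$file)))
      for (t in m$tables)
        lines <- c(lines, sprintf("<p><a href=\"%s/%s\">%s</a></p>",
                                  esc(s$dir), esc(t), esc(t)))
      if (length(m$warnings))
        lines <- c(lines, "<ul>",
                   sprintf("<li>%s</li>", vapply(m$warnings, esc, "")),
                   "</ul>")
    } else {
      lines <- c(lines, sprintf("<p class=\"fail\">failed: %s</p>",
                                esc(s$error)))
    }
  }
  lines <- c(lines, "</body></html>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' The default hypothesis catalogue shipped with the package
#'
#' Four worked scenarios over the synthetic presets: reaction-time slowing
#' across age groups, elevated reaction-time CV in the schizophrenia
#' group, whole-battery profiles by gender, and a PCA projection colored
#' by diagnosis.
#'
#' @export
default_catalogue <- function() {
  list(
    list(name = "age-slowing",
         formula = "VISOVA: ~ *_MEANRT | Age : (all)",
         notes = "mean reaction time by age decade across every task"),
    list(name = "sz-rt-variability",
         formula = "VISOVA: ~ *_CV | Diagnosis : (all)",
         notes = "reaction-time coefficient of variation, control vs SZ"),
    list(name = "gender-profiles",
         formula = "VISOVA: ~ B*_V* | Gender : (all)",
         notes = "phenotype battery profiles by gender"),
    list(name = "diagnosis-pca",
         formula = "PCA: ~ B*_V* | Diagnosis : (all)",
         notes = "principal-component projections colored by diagnosis"))
}
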