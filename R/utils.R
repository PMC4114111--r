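`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so the CLI can map error classes to exit codes
stop_viva <- function(class, message, call. = FALSE) {
  stop(structure(
    class = c(paste0("viva_", class, "_error"), "viva_error",
              "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)))
}

warn_viva <- function(class, message) {
  warning(structure(
    class = c(paste0("viva_", class, "_warning"), "viva_warning",
              "warning", "condition"),
    list(message = message, call = NULL)))
}

# fixed-format number for deterministic text output (SVG, TSV, manifests)
fmt_num <- function(x, digits = 4) {
  out <- formatC(x, format = "f", digits = digits)
  out[!is.finite(x)] <- "NA"
  out
}
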