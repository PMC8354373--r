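#' @keywords internal
"_PACKAGE"

# Stage-prefixed, timestamped log line. All pipeline functions funnel
# informational output through here so drivers can silence it uniformly.
dn_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
  invisible(NULL)
}

dn_stop <- function(...) stop(..., call. = FALSE)

# upper-case, trimmed, unique-preserving-order symbol normalization
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
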