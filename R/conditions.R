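#' @keywords internal
"_PACKAGE"

# Classed conditions: every error carries both its bare schema name
# (e.g. "BundleIncomplete") and "dyadscope_error", so callers can catch
# either. `...` are stored as condition fields.
abort_dyadscope <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "dyadscope_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

warn_dyadscope <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "dyadscope_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}
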