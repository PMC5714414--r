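# Internal helpers shared across modules.

# Classed conditions so callers (and the shell wrapper) can map
# validation vs. infeasibility onto distinct exit codes.
abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "planrad_validation_error")
}

abort_infeasible <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "planrad_infeasible_error")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_number <- function(x, what) {
  if (!is_scalar_number(x)) {
    abort_validation("`%s` must be a single finite number.", what)
  }
  invisible(x)
}

# Shortest decimal representation that still reparses to exactly the same
# double, for text outputs that must round-trip (DVH files, manifests).
format_full <- function(x) {
  vapply(x, function(xi) {
    for (d in c(1, 6, 15, 16, 17)) {
      s <- trimws(formatC(xi, digits = d, format = "g"))
      if (as.numeric(s) == xi) return(s)
    }
    s
  }, character(1))
}
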