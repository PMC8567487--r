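#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching the convention
#' used in clinical histomorphometry reports (R's `round()` rounds half to
#' even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards against 0.5 landing just below itself in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# internal: stop with a classed condition so callers can test error classes
bm_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "bonematrix_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# internal: consistent assertion for scalar numerics
assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    bm_stop("bm_domain_error", sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
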