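#' Z-score set
#'
#' Standardized deviations of measured parameters from normative reference
#' values. One row per parameter; `z = (value - ref_mean) / ref_sd`, reported
#' to two decimals (half away from zero), with parameters whose absolute
#' deviation exceeds `flag_threshold` standard deviations flagged -- the
#' conventional presentation in clinical bone histomorphometry, where
#' deviations beyond 2 SD are typeset in bold.
#'
#' @param parameter character vector of parameter names.
#' @param value measured values.
#' @param ref_mean,ref_sd reference means and standard deviations
#'   (`ref_sd > 0`).
#' @param flag_threshold absolute z beyond which a parameter is flagged
#'   (default 2).
#' @return a `zscore_set`: a data.frame with columns `parameter`, `value`,
#'   `ref_mean`, `ref_sd`, `z` (2 decimals) and `flag`.
#' @export
zscore_set <- function(parameter, value, ref_mean, ref_sd, flag_threshold = 2) {
  stopifnot(length(parameter) == length(value),
            length(value) == length(ref_mean),
            length(ref_mean) == length(ref_sd))
  if (any(!is.na(ref_sd) & ref_sd <= 0))
    bm_stop("bm_domain_error", "reference SDs must be > 0")
  z <- round_half_away((value - ref_mean) / ref_sd, 2)
  out <- data.frame(
    parameter = as.character(parameter),
    value = value,
    ref_mean = ref_mean,
    ref_sd = ref_sd,
    z = z,
    flag = !is.na(z) & abs(z) > flag_threshold,
    stringsAsFactors = FALSE
  )
  class(out) <- c("zscore_set", "data.frame")
  out
}

#' @export
print.zscore_set <- function(x, ...) {
  y <- as.data.frame(x)
  y$z <- sprintf("%+.2f%s", y$z, ifelse(y$flag, " *", ""))
  y$flag <- NULL
  print(y, row.names = FALSE)
  cat("* |z| exceeds the flag threshold\n")
  invisible(x)
}
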