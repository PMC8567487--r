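#' Two-point gray-level / calcium calibration
#'
#' qBEI gray levels are, over the relevant range, an affine function of the
#' local calcium weight-percent of the polished bone surface: the detector is
#' calibrated against carbon and aluminium standards and the resulting map is
#' linear in the backscattered signal. `calibration_fit` determines the map
#' from two anchor points (gray level, wt% Ca).
#'
#' The package default anchors place the organic (osteoid) phase at gray
#' level 25 with 0 wt% Ca and gray level 55 at 5.2 wt% Ca, the conventional
#' bone/void discrimination level in OLS analysis. Both anchors are
#' overridable for instruments calibrated differently.
#'
#' @param gl_a,gl_b gray levels of the two anchors, in `[0, 255]`.
#' @param ca_a,ca_b calcium content (wt% Ca, >= 0) at the two anchors.
#' @return an object of class `calibration_map` with elements `slope`
#'   (wt% Ca per gray level), `intercept` (wt% Ca at gray level 0) and
#'   `anchors` (2 x 2 matrix of the fitted points).
#' @examples
#' cal <- calibration_fit(25, 0.0, 55, 5.2)
#' gl_to_ca(cal, 55)  # 5.2
#' @export
calibration_fit <- function(gl_a = 25, ca_a = 0.0, gl_b = 55, ca_b = 5.2) {
  for (v in c("gl_a", "gl_b", "ca_a", "ca_b"))
    assert_scalar_num(get(v), v)
  if (gl_a < 0 || gl_a > 255 || gl_b < 0 || gl_b > 255)
    bm_stop("bm_domain_error", "anchor gray levels must lie in [0, 255]")
  if (ca_a < 0 || ca_b < 0)
    bm_stop("bm_domain_error", "calcium contents must be >= 0")
  if (gl_a == gl_b)
    bm_stop("bm_degenerate_calibration",
            "anchor gray levels are equal: calibration is degenerate")
  slope <- (ca_b - ca_a) / (gl_b - gl_a)
  if (slope <= 0)
    bm_stop("bm_degenerate_calibration",
            "calibration slope must be positive (brighter = more mineralized)")
  structure(
    list(
      slope = slope,
      intercept = ca_a - slope * gl_a,
      anchors = matrix(c(gl_a, ca_a, gl_b, ca_b), nrow = 2, byrow = TRUE,
                       dimnames = list(NULL, c("gl", "ca")))
    ),
    class = "calibration_map"
  )
}

#' @export
print.calibration_map <- function(x, ...) {
  cat("qBEI calibration map: Ca[wt%] =",
      format(x$slope, digits = 6), "* GL",
      ifelse(x$intercept < 0, "-", "+"),
      format(abs(x$intercept), digits = 6), "\n")
  cat("anchors: GL", x$anchors[1, 1], "<->", x$anchors[1, 2], "wt% Ca;",
      "GL", x$anchors[2, 1], "<->", x$anchors[2, 2], "wt% Ca\n")
  invisible(x)
}

#' Convert gray levels to calcium content
#'
#' @param map a [calibration_fit()] result.
#' @param gl numeric vector of gray levels in `[0, 255]`.
#' @param clip logical; clip negative calcium values to 0 for reporting
#'   (default `TRUE`). Anchor arithmetic (e.g. round trips) should use
#'   `clip = FALSE`.
#' @return calcium content in wt% Ca.
#' @export
gl_to_ca <- function(map, gl, clip = TRUE) {
  stopifnot(inherits(map, "calibration_map"))
  if (any(!is.finite(gl)) || any(gl < 0) || any(gl > 255))
    bm_stop("bm_domain_error", "gray levels must be finite and in [0, 255]")
  ca <- map$slope * gl + map$intercept
  if (clip) ca <- pmax(ca, 0)
  ca
}

#' Convert calcium content to (real-valued) gray levels
#'
#' Inverse of [gl_to_ca()]. Quantization to 8 bits is the caller's
#' responsibility; values mapping outside `[0, 255]` raise a warning and are
#' clipped, with the clipping recorded in the `"clipped"` attribute.
#'
#' @param map a [calibration_fit()] result.
#' @param ca numeric vector of calcium contents (wt% Ca).
#' @return real-valued gray levels with attribute `clipped` (logical vector).
#' @export
ca_to_gl <- function(map, ca) {
  stopifnot(inherits(map, "calibration_map"))
  if (any(!is.finite(ca)))
    bm_stop("bm_domain_error", "calcium contents must be finite")
  gl <- (ca - map$intercept) / map$slope
  clipped <- gl < 0 | gl > 255
  if (any(clipped)) {
    warning("calcium values map outside gray-level range [0, 255]; clipping",
            call. = FALSE)
    gl <- pmin(pmax(gl, 0), 255)
  }
  attr(gl, "clipped") <- clipped
  gl
}

#' Serialize / restore a calibration map as JSON
#'
#' @param map a `calibration_map`.
#' @param path file path of the JSON file.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a `calibration_map`.
#' @export
write_calibration <- function(map, path) {
  stopifnot(inherits(map, "calibration_map"))
  jsonlite::write_json(
    list(slope = map$slope, intercept = map$intercept,
         anchors = list(unname(map$anchors[1, ]), unname(map$anchors[2, ]))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- if (is.matrix(x$anchors)) x$anchors else do.call(rbind, x$anchors)
  calibration_fit(a[1, 1], a[1, 2], a[2, 1], a[2, 2])
}
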