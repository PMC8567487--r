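#' Calcium histogram (BMDD) of a calibrated qBEI raster
#'
#' Converts the gray-level frequency distribution of the mineralized bone
#' pixels to a frequency distribution of calcium concentration -- the bone
#' mineralization density distribution (BMDD). Pixels below the bone
#' gray-level threshold (void, marrow, osteoid) and pixels outside the mask
#' are excluded; frequencies are normalized to percent of contributing
#' pixels, so they sum to 100.
#'
#' Bins are uniform in wt% Ca, anchored at 0, with a default width of
#' 0.17 wt% Ca (about one 8-bit gray level under the default calibration).
#' A pixel with calcium content `ca` falls in bin `floor(ca / bin_width)`.
#'
#' @param image integer matrix of gray levels 0..255.
#' @param map a [calibration_fit()] calibration.
#' @param mask optional inclusion mask (matrix, nonzero = include) congruent
#'   with `image`.
#' @param bone_gl_threshold gray level at or above which a pixel counts as
#'   mineralized bone (default 55, the OLS bone/void discrimination level).
#' @param bin_width histogram bin width in wt% Ca (default 0.17).
#' @return a `ca_histogram`: list with `bin_centers`, `bin_edges`,
#'   `frequencies` (percent of bone area per bin, summing to 100),
#'   `bin_width`, `n_pixels`, and `meta` (threshold and calibration used).
#' @export
ca_histogram <- function(image, map, mask = NULL, bone_gl_threshold = 55,
                         bin_width = 0.17) {
  stopifnot(is.matrix(image), inherits(map, "calibration_map"))
  if (bone_gl_threshold <= 0 || bone_gl_threshold >= 255)
    bm_stop("bm_domain_error", "bone_gl_threshold must lie in (0, 255)")
  if (bin_width <= 0)
    bm_stop("bm_domain_error", "bin_width must be > 0")
  keep <- check_mask(image, mask) & image >= bone_gl_threshold
  n <- sum(keep)
  if (n == 0L)
    bm_stop("bm_empty_region", "no bone pixels at or above the threshold inside the mask")
  ca <- gl_to_ca(map, image[keep])
  # the small offset keeps values that land on a bin edge up to floating-
  # point error in the upper bin, independent of how `ca` was computed
  idx <- pmax(floor(ca / bin_width + 1e-9), 0) + 1L
  nbin <- max(idx, ceiling(gl_to_ca(map, 255) / bin_width))
  counts <- tabulate(idx, nbins = nbin)
  structure(
    list(
      bin_centers = (seq_len(nbin) - 0.5) * bin_width,
      bin_edges = (0:nbin) * bin_width,
      frequencies = 100 * counts / n,
      bin_width = bin_width,
      n_pixels = n,
      meta = list(bone_gl_threshold = bone_gl_threshold,
                  calibration = map[c("slope", "intercept")])
    ),
    class = "ca_histogram"
  )
}

#' @export
print.ca_histogram <- function(x, ...) {
  nz <- which(x$frequencies > 0)
  cat("BMDD histogram:", x$n_pixels, "bone pixels,",
      length(x$bin_centers), "bins of", x$bin_width, "wt% Ca\n")
  if (length(nz))
    cat("support:", format(x$bin_centers[min(nz)], digits = 4), "-",
        format(x$bin_centers[max(nz)], digits = 4), "wt% Ca\n")
  invisible(x)
}

# internal: centered boxcar smoothing, zero-padded at the edges
boxcar <- function(f, window) {
  if (window <= 1L) return(f)
  if (window %% 2L == 0L)
    bm_stop("bm_domain_error", "smoothing window must be odd")
  k <- rep(1 / window, window)
  as.numeric(stats::filter(c(rep(0, window %/% 2), f, rep(0, window %/% 2)),
                           k, sides = 2))[(window %/% 2 + 1):(window %/% 2 + length(f))]
}

#' BMDD summary parameters
#'
#' Derives the five canonical BMDD parameters from a calcium histogram:
#' \describe{
#'   \item{CaMean}{weighted mean calcium content (wt% Ca).}
#'   \item{CaPeak}{most frequently measured calcium content: the bin center
#'     maximizing the (optionally boxcar-smoothed) frequency (wt% Ca).}
#'   \item{CaWidth}{full width at half maximum of the smoothed distribution,
#'     with the half-height crossings located by linear interpolation between
#'     bin centers (delta wt% Ca); indexes mineralization heterogeneity.}
#'   \item{CaLow}{percent of bone area mineralized below `low_cut` (default
#'     17.68 wt% Ca, the 5th percentile of the adult trabecular reference
#'     BMDD).}
#'   \item{CaHigh}{percent of bone area mineralized above `high_cut` (default
#'     25.30 wt% Ca, the 95th percentile of the reference BMDD).}
#' }
#' Cut comparisons are strict (`<` / `>`) on bin centers, so CaLow, CaHigh
#' and the mass between the cuts always partition exactly 100% of the bone
#' area. CaMean, CaLow and CaHigh are computed from the raw histogram;
#' smoothing affects only the mode and width estimates.
#'
#' @param hist a [ca_histogram()].
#' @param low_cut,high_cut tail cut points in wt% Ca.
#' @param smooth_window odd boxcar window (in bins) applied before locating
#'   the peak and FWHM; default 3, use 1 to disable.
#' @return a `bmdd_result`: list with `CaMean`, `CaPeak`, `CaWidth`, `CaLow`,
#'   `CaHigh`, `flags` (character vector; e.g. `"peak_tie"` when several bins
#'   share the maximum and the lowest-Ca one was chosen, `"width_truncated"`
#'   when a half-height crossing fell outside the histogram support), and
#'   `meta` (cuts and smoothing actually used).
#' @export
bmdd_parameters <- function(hist, low_cut = 17.68, high_cut = 25.30,
                            smooth_window = 3L) {
  stopifnot(inherits(hist, "ca_histogram"))
  f <- hist$frequencies
  cc <- hist$bin_centers
  if (all(f == 0))
    bm_stop("bm_empty_region", "histogram has no mass")
  flags <- character(0)

  ca_mean <- sum(f * cc) / sum(f)

  s <- boxcar(f, smooth_window)
  pk <- max(s)
  peak_idx <- which(s == pk)
  if (length(peak_idx) > 1L) flags <- c(flags, "peak_tie")
  peak_idx <- peak_idx[1L]   # tie-break to lowest Ca
  ca_peak <- cc[peak_idx]

  half <- pk / 2
  # left crossing: last bin below half-height left of the peak
  left <- which(s[seq_len(peak_idx)] < half)
  if (length(left)) {
    i <- max(left)
    x_left <- cc[i] + (half - s[i]) / (s[i + 1] - s[i]) * hist$bin_width
  } else {
    x_left <- hist$bin_edges[1L]
    flags <- c(flags, "width_truncated")
  }
  right <- which(s[peak_idx:length(s)] < half)
  if (length(right)) {
    j <- peak_idx + min(right) - 1L
    x_right <- cc[j - 1] + (s[j - 1] - half) / (s[j - 1] - s[j]) * hist$bin_width
  } else {
    x_right <- hist$bin_edges[length(hist$bin_edges)]
    flags <- c(flags, "width_truncated")
  }
  ca_width <- x_right - x_left

  structure(
    list(
      CaMean = ca_mean,
      CaPeak = ca_peak,
      CaWidth = ca_width,
      CaLow = sum(f[cc < low_cut]),
      CaHigh = sum(f[cc > high_cut]),
      flags = flags,
      meta = list(low_cut = low_cut, high_cut = high_cut,
                  smooth_window = smooth_window, bin_width = hist$bin_width,
                  pore_border_exclusion = "none")
    ),
    class = "bmdd_result"
  )
}

#' @export
print.bmdd_result <- function(x, ...) {
  cat(sprintf(
    "BMDD: CaMean %.2f | CaPeak %.2f | CaWidth %.2f wt%% Ca | CaLow %.2f%% | CaHigh %.2f%%\n",
    x$CaMean, x$CaPeak, x$CaWidth, x$CaLow, x$CaHigh))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

bmdd_par_names <- c("CaMean", "CaPeak", "CaWidth", "CaLow", "CaHigh")

# internal: accept a bmdd_result or a named numeric vector
as_bmdd_values <- function(x) {
  if (inherits(x, "bmdd_result")) unlist(x[bmdd_par_names])
  else {
    stopifnot(all(bmdd_par_names %in% names(x)))
    unlist(x)[bmdd_par_names]
  }
}

#' Compare cortical and trabecular BMDD
#'
#' Per-parameter relative difference of the cortical compartment from the
#' trabecular compartment, `100 * (cortical - trabecular) / trabecular`,
#' reported to one decimal. A zero trabecular value yields `NA` with an
#' `undefined_ratio` flag rather than an error.
#'
#' @param cortical,trabecular [bmdd_parameters()] results (or named numeric
#'   vectors with the five BMDD parameters) measured under the same
#'   calibration.
#' @return data.frame with columns `parameter`, `cortical`, `trabecular`,
#'   `pct_diff`, `flag`.
#' @export
compare_compartments <- function(cortical, trabecular) {
  co <- as_bmdd_values(cortical)
  tr <- as_bmdd_values(trabecular)
  pct <- ifelse(tr == 0, NA_real_,
                round_half_away(100 * (co - tr) / tr, 1))
  data.frame(
    parameter = bmdd_par_names,
    cortical = unname(co),
    trabecular = unname(tr),
    pct_diff = unname(pct),
    flag = ifelse(tr == 0, "undefined_ratio", ""),
    stringsAsFactors = FALSE
  )
}

#' Standardize BMDD parameters against a trabecular reference
#'
#' @param result a [bmdd_parameters()] result (or named numeric vector).
#' @param reference data.frame with columns `parameter`, `mean`, `sd` (see
#'   [read_reference_table()]); must contain one row per BMDD parameter.
#' @return a [zscore_set()].
#' @export
bmdd_zscores <- function(result, reference) {
  vals <- as_bmdd_values(result)
  m <- match(bmdd_par_names, reference$parameter)
  if (anyNA(m))
    bm_stop("bm_missing_reference",
            paste("missing reference rows for:",
                  paste(bmdd_par_names[is.na(m)], collapse = ", ")))
  zscore_set(bmdd_par_names, unname(vals),
             reference$mean[m], reference$sd[m])
}

#' Read a normative reference table
#'
#' Reads a CSV of normative statistics. For BMDD references the expected
#' columns are `parameter,mean,sd,source`; for histomorphometry references
#' `parameter,sex,age_lo,age_hi,mean,sd,source`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_reference_table <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("parameter", "mean", "sd") %in% names(ref)))
    bm_stop("bm_input_error",
            "reference table must have columns parameter, mean, sd")
  if (any(ref$sd <= 0))
    bm_stop("bm_domain_error", "reference SDs must be > 0")
  ref
}

#' Export a BMDD histogram as CSV
#'
#' @param hist a [ca_histogram()].
#' @param path output CSV path (columns `bin_center`, `percent`).
#' @return `path`, invisibly.
#' @export
write_bmdd_csv <- function(hist, path) {
  stopifnot(inherits(hist, "ca_histogram"))
  utils::write.csv(
    data.frame(bin_center = hist$bin_centers, percent = hist$frequencies),
    path, row.names = FALSE)
  invisible(path)
}

#' Plot a BMDD curve
#'
#' Draws the BMDD as a frequency curve over calcium content, optionally
#' overlaying a reference band (mean curve plus/minus one SD), the standard
#' presentation of mineralization density distributions.
#'
#' @param hist a [ca_histogram()] (or a list of them, named by compartment).
#' @param reference optional data.frame with columns `bin_center`, `mean`,
#'   `sd` describing a reference BMDD curve.
#' @return a ggplot object.
#' @export
plot_bmdd <- function(hist, reference = NULL) {
  hh <- if (inherits(hist, "ca_histogram")) list(BMDD = hist) else hist
  df <- do.call(rbind, lapply(names(hh), function(nm) {
    data.frame(compartment = nm, ca = hh[[nm]]$bin_centers,
               percent = hh[[nm]]$frequencies)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ca, y = .data$percent,
                                        color = .data$compartment))
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_ribbon(
      data = reference,
      ggplot2::aes(x = .data$bin_center, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      inherit.aes = FALSE, fill = "grey80") +
      ggplot2::geom_line(
        data = reference,
        ggplot2::aes(x = .data$bin_center, y = .data$mean),
        inherit.aes = FALSE, linetype = "dotted")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Calcium content (wt% Ca)",
                  y = "Bone area (%)", color = NULL) +
    ggplot2::theme_classic()
}
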