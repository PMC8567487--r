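#' Segment pores (osteocyte lacunae sections and larger voids)
#'
#' Pores are maximal connected components of pixels strictly below the
#' bone/void gray-level threshold (default 55, i.e. below 5.2 wt% Ca under
#' the default calibration). With this convention the pore and bone
#' definitions partition the raster exhaustively: every masked pixel is
#' either bone (`gl >= threshold`) or pore (`gl < threshold`).
#'
#' Components are labeled with 8-connectivity by default (4-connectivity for
#' the background), so thin or diagonal lacuna sections are not fragmented.
#' Region geometry comes from second-order moments of the pixel centers:
#' the equivalent-ellipse major/minor axis lengths are `4 * sqrt(lambda)`
#' for the two eigenvalues `lambda` of the pixel covariance matrix, and the
#' aspect ratio is their quotient (rotation invariant, >= 1). The perimeter
#' is the city-block boundary length (count of exposed pixel edges times the
#' pixel size), an upper-bound estimate for smooth shapes.
#'
#' @param image integer matrix of gray levels 0..255.
#' @param map optional [calibration_fit()]; recorded in the output metadata
#'   (the threshold itself is specified in gray levels).
#' @param gl_threshold pore/bone discrimination gray level (default 55).
#' @param pixel_size pixel edge length in micrometers (default 0.88, the
#'   resolution of high-magnification qBEI scans used for OLS analysis).
#' @param connectivity 8 (default) or 4.
#' @param mask optional inclusion mask; pixels outside it belong to neither
#'   phase, and regions touching the mask boundary are flagged as censored.
#' @return a `pore_regions` data.frame, one row per component, with columns
#'   `id`, `n_pixels`, `area_um2`, `perimeter_um`, `x_um`, `y_um`,
#'   `major_um`, `minor_um`, `aspect_ratio`, `touches_border`. The label
#'   matrix is attached as attribute `labels`; `pixel_size` and
#'   `gl_threshold` as attributes of the same names.
#' @export
segment_pores <- function(image, map = NULL, gl_threshold = 55,
                          pixel_size = 0.88, connectivity = 8, mask = NULL) {
  stopifnot(is.matrix(image))
  if (pixel_size <= 0) bm_stop("bm_domain_error", "pixel_size must be > 0")
  if (!connectivity %in% c(4, 8))
    bm_stop("bm_domain_error", "connectivity must be 4 or 8")
  inc <- check_mask(image, mask)
  if (!any(inc)) bm_stop("bm_empty_region", "mask excludes every pixel")
  pore <- (image < gl_threshold) & inc
  lab <- label_components(pore, connectivity)
  nlab <- max(lab)
  if (nlab == 0L) {
    out <- empty_pore_df()
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    nr <- nrow(image)
    row <- ((idx - 1L) %% nr) + 1L
    col <- ((idx - 1L) %/% nr) + 1L
    # pixel-center coordinates in micrometers
    x <- (col - 0.5) * pixel_size
    y <- (row - 0.5) * pixel_size
    n <- tabulate(l, nlab)
    sx <- rowsum_vec(x, l, nlab);  sy <- rowsum_vec(y, l, nlab)
    sxx <- rowsum_vec(x * x, l, nlab); syy <- rowsum_vec(y * y, l, nlab)
    sxy <- rowsum_vec(x * y, l, nlab)
    cx <- sx / n; cy <- sy / n
    vxx <- sxx / n - cx^2; vyy <- syy / n - cy^2; vxy <- sxy / n - cx * cy
    tr <- vxx + vyy
    det <- vxx * vyy - vxy^2
    disc <- sqrt(pmax(tr^2 / 4 - det, 0))
    l1 <- pmax(tr / 2 + disc, 0); l2 <- pmax(tr / 2 - disc, 0)
    major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
    ar <- ifelse(minor > 0, major / minor, 1)  # degenerate (single px / line)
    # exposed 4-neighbor edges -> city-block perimeter
    per <- boundary_edges(lab, nlab) * pixel_size
    tb <- border_labels(lab, nlab, inc)
    out <- data.frame(
      id = seq_len(nlab), n_pixels = n,
      area_um2 = n * pixel_size^2, perimeter_um = per,
      x_um = cx, y_um = cy, major_um = major, minor_um = minor,
      aspect_ratio = ar, touches_border = tb,
      stringsAsFactors = FALSE
    )
  }
  attr(out, "labels") <- lab
  attr(out, "pixel_size") <- pixel_size
  attr(out, "gl_threshold") <- gl_threshold
  class(out) <- c("pore_regions", "data.frame")
  out
}

empty_pore_df <- function() {
  data.frame(id = integer(0), n_pixels = integer(0), area_um2 = numeric(0),
             perimeter_um = numeric(0), x_um = numeric(0), y_um = numeric(0),
             major_um = numeric(0), minor_um = numeric(0),
             aspect_ratio = numeric(0), touches_border = logical(0),
             stringsAsFactors = FALSE)
}

rowsum_vec <- function(v, group, n) {
  out <- numeric(n)
  s <- rowsum(v, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# internal: connected-component labeling. EBImage::bwlabel labels with
# 4-connectivity; for 8-connectivity, labels that touch diagonally are
# merged with a union-find pass over the (few) diagonal label adjacencies.
label_components <- function(bw, connectivity = 8) {
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow(bw)))
  lab <- matrix(as.integer(lab), nrow(bw))
  nlab <- max(lab)
  if (connectivity == 4 || nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(relabel_consecutive(lab))
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  map <- match(root, sort(unique(root)))
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L || identical(u, seq_along(u))) return(lab)
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# internal: per-label count of exposed 4-neighbor pixel edges
boundary_edges <- function(lab, nlab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  edges <- numeric(nlab)
  for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[2:(nr + 1) + sh[1], 2:(nc + 1) + sh[2]]
    exposed <- ctr > 0L & nb != ctr
    if (any(exposed)) {
      cnt <- tabulate(ctr[exposed], nlab)
      edges <- edges + cnt
    }
  }
  edges
}

# internal: labels touching the image border or a masked-out pixel
border_labels <- function(lab, nlab, inc) {
  tb <- logical(nlab)
  edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  tb[edge[edge > 0L]] <- TRUE
  if (!all(inc)) {
    nr <- nrow(lab); nc <- ncol(lab)
    pad <- matrix(TRUE, nr + 2L, nc + 2L)
    pad[2:(nr + 1), 2:(nc + 1)] <- inc
    ctr <- lab
    for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nb <- pad[2:(nr + 1) + sh[1], 2:(nc + 1) + sh[2]]
      hit <- ctr > 0L & !nb
      tb[unique(ctr[hit])] <- TRUE
    }
  }
  tb
}

#' Separate osteocyte lacunae from larger pores
#'
#' Applies the size cutoff that discriminates osteocyte lacunae sections
#' from larger voids (vascular channels, Haversian canals, cracks, marrow
#' space): regions with area up to `max_area` (inclusive) are retained as
#' lacunae. Border-touching regions have censored geometry and are excluded
#' by default; an optional minimum area (default 0, i.e. none) suppresses
#' single-pixel noise when needed.
#'
#' @param regions a [segment_pores()] result.
#' @param max_area size cutoff in square micrometers (default 200).
#' @param exclude_border exclude regions touching the image/mask border
#'   (default `TRUE`).
#' @param min_area minimum retained area in square micrometers (default 0).
#' @return list with elements `lacunae` (retained rows) and `excluded`
#'   (rows with an extra `reason` column: `"large"`, `"border"` or
#'   `"small"`).
#' @export
filter_lacunae <- function(regions, max_area = 200, exclude_border = TRUE,
                           min_area = 0) {
  stopifnot(inherits(regions, "pore_regions") || is.data.frame(regions))
  reason <- rep(NA_character_, nrow(regions))
  reason[regions$area_um2 > max_area] <- "large"
  if (exclude_border)
    reason[is.na(reason) & regions$touches_border] <- "border"
  reason[is.na(reason) & regions$area_um2 < min_area] <- "small"
  keep <- is.na(reason)
  excluded <- as.data.frame(regions)[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(lacunae = as.data.frame(regions)[keep, , drop = FALSE],
       excluded = excluded)
}

#' Summarize osteocyte lacunae morphometry
#'
#' @param lacunae data.frame of retained lacunae (from [filter_lacunae()]).
#' @param bone_area_mm2 bone area in square millimeters: masked pixels at or
#'   above the bone threshold plus the retained lacuna pixels (lacunae are
#'   part of the bone tissue; larger voids are not).
#' @param excluded optional `excluded` data.frame from [filter_lacunae()],
#'   used for the exclusion counts.
#' @return an `ols_summary` list: `n_lacunae`, `ols_density` (1/mm^2 of bone
#'   area), `mean_area` (um^2), `mean_perimeter` (um), `mean_aspect_ratio`,
#'   `lacunar_porosity` (% of bone area), `n_excluded_large`,
#'   `n_excluded_border`, `bone_area_mm2`. With zero lacunae the means are
#'   `NA` and the summary carries a `"no_lacunae"` flag.
#' @export
ols_summary <- function(lacunae, bone_area_mm2, excluded = NULL) {
  if (!is.numeric(bone_area_mm2) || bone_area_mm2 <= 0)
    bm_stop("bm_domain_error", "bone_area_mm2 must be > 0")
  n <- nrow(lacunae)
  flags <- character(0)
  if (n == 0L) flags <- "no_lacunae"
  structure(
    list(
      n_lacunae = n,
      ols_density = n / bone_area_mm2,
      mean_area = if (n) mean(lacunae$area_um2) else NA_real_,
      mean_perimeter = if (n) mean(lacunae$perimeter_um) else NA_real_,
      mean_aspect_ratio = if (n) mean(lacunae$aspect_ratio) else NA_real_,
      lacunar_porosity = if (n) 100 * sum(lacunae$area_um2) / (bone_area_mm2 * 1e6) else 0,
      n_excluded_large = if (is.null(excluded)) NA_integer_ else sum(excluded$reason == "large"),
      n_excluded_border = if (is.null(excluded)) NA_integer_ else sum(excluded$reason == "border"),
      bone_area_mm2 = bone_area_mm2,
      flags = flags
    ),
    class = "ols_summary"
  )
}

#' @export
print.ols_summary <- function(x, ...) {
  cat(sprintf(
    "OLS: %d lacunae | density %.1f /mm2 | mean area %.1f um2 | mean AR %.2f | porosity %.2f%%\n",
    x$n_lacunae, x$ols_density, x$mean_area, x$mean_aspect_ratio,
    x$lacunar_porosity))
  if (!is.na(x$n_excluded_large))
    cat("excluded:", x$n_excluded_large, "large,",
        x$n_excluded_border, "border-touching\n")
  invisible(x)
}

#' Full OLS analysis of a qBEI raster
#'
#' Convenience wrapper: segments pores, separates lacunae from larger voids,
#' and summarizes the lacunar morphometry. The bone area denominator is the
#' area of masked pixels at or above the threshold plus the retained lacuna
#' pixels.
#'
#' @inheritParams segment_pores
#' @inheritParams filter_lacunae
#' @return list with `summary` ([ols_summary()]), `lacunae`, `excluded` and
#'   `regions`.
#' @export
ols_analysis <- function(image, map = NULL, gl_threshold = 55,
                         pixel_size = 0.88, max_area = 200,
                         exclude_border = TRUE, min_area = 0,
                         connectivity = 8, mask = NULL) {
  regions <- segment_pores(image, map, gl_threshold, pixel_size,
                           connectivity, mask)
  parts <- filter_lacunae(regions, max_area, exclude_border, min_area)
  inc <- check_mask(image, mask)
  bone_px <- sum(image >= gl_threshold & inc) + sum(parts$lacunae$n_pixels)
  bone_area <- bone_px * (pixel_size / 1000)^2
  if (bone_area <= 0) bm_stop("bm_empty_region", "no bone area in the image")
  list(
    summary = ols_summary(parts$lacunae, bone_area, parts$excluded),
    lacunae = parts$lacunae,
    excluded = parts$excluded,
    regions = regions
  )
}

#' Export per-lacuna morphometry as CSV
#'
#' @param parts result of [filter_lacunae()] (or [ols_analysis()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lacunae_csv <- function(parts, path) {
  lac <- parts$lacunae
  lac$excluded_reason <- ""
  exc <- parts$excluded
  if (nrow(exc)) {
    exc$excluded_reason <- exc$reason
    exc$reason <- NULL
  }
  cols <- c("id", "area_um2", "perimeter_um", "major_um", "minor_um",
            "aspect_ratio", "x_um", "y_um", "excluded_reason")
  out <- rbind(lac[, cols], if (nrow(exc)) exc[, cols])
  utils::write.csv(out[order(out$id), ], path, row.names = FALSE)
  invisible(path)
}
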