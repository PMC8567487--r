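#' Specification of a synthetic bone scene
#'
#' Bundles every knob of the synthetic generators with defaults chosen to
#' emulate the study conditions the package is designed for: an adult
#' transiliac biopsy cross-section with a mildly mineralized, heterogeneous
#' matrix (trabecular CaMean near 20.7 wt% Ca with a broad distribution,
#' cortical bone more mineralized than trabecular), a high lacunar density
#' with enlarged, moderately elongated lacunae, extended osteoid surface
#' with thin seams, and sparse tetracycline double labels.
#'
#' Geometry, lacuna placement, mineralization and sensor noise each draw
#' from their own pseudo-random sub-stream derived from `seed`, so changing
#' e.g. the noise level does not reshuffle the geometry.
#'
#' @param seed integer master seed; identical seeds give bit-identical
#'   scenes.
#' @param width_px,height_px canvas size in pixels.
#' @param pixel_size_um pixel edge length (default 0.88, the OLS imaging
#'   scale; use 3.6 for overview BMDD-scale scans).
#' @param cortical_frac fraction of the canvas width occupied by the solid
#'   cortical band on the left (0 for a trabecular-only field, 1 for pure
#'   cortex).
#' @param bvtv trabecular bone area fraction of the non-cortical region.
#' @param strut_scale_px Gaussian smoothing length of the thresholded noise
#'   field that shapes the trabecular struts.
#' @param mineralization per-compartment normal mixtures of calcium content:
#'   a list with elements `cortical` and `trabecular`, each a list of
#'   `weights`, `means` (wt% Ca) and `sds` (wt% Ca); weights must sum to 1.
#' @param lacunae lacuna model: `density_per_mm2` (of bone area),
#'   `area_meanlog`/`area_sdlog` (lognormal section area in um^2, resampled
#'   above `area_cap_um2` so planted lacunae stay below the lacuna/pore size
#'   cutoff), `ar_mean`/`ar_sd` (lognormal aspect ratio, truncated at 1),
#'   `min_separation_px`, `gl` (gray level the lacunae are stamped at).
#' @param sensor sensor model: `calibration` ([calibration_fit()]),
#'   `noise_gl_sd` (additive Gaussian gray-level noise before 8-bit
#'   quantization), `background_gl` (marrow/embedding level).
#' @param histo histomorphometry scene model: canvas (`width_px`,
#'   `height_px`, `pixel_size_um`), `n_struts` and `strut_th_um` (straight
#'   trabecular plates), surface state fractions (`os_fraction` includes the
#'   osteoblast-covered part, `ob_fraction`; `eroded_fraction` includes
#'   `oc_fraction`), `o_th_um` seam width, label extents (`dl_fraction`,
#'   `sl_fraction` of bone surface), `mar_um_day` and `label_interval_days`
#'   (the planted inter-label distance is their product), `n_osteoclasts`.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    seed = 1L,
    width_px = 640L, height_px = 640L, pixel_size_um = 0.88,
    cortical_frac = 0.3, bvtv = 0.35, strut_scale_px = 14,
    mineralization = list(
      cortical = list(weights = 1, means = 22.4, sds = 1.8),
      trabecular = list(weights = 1, means = 20.7, sds = 2.1)
    ),
    lacunae = list(
      density_per_mm2 = 220, area_meanlog = log(45) - 0.35^2 / 2,
      area_sdlog = 0.35, area_cap_um2 = 180, ar_mean = 2.0, ar_sd = 0.3,
      min_separation_px = 2, gl = 25
    ),
    sensor = list(
      calibration = calibration_fit(), noise_gl_sd = 2, background_gl = 10
    ),
    histo = list(
      width_px = 800L, height_px = 1200L, pixel_size_um = 1,
      n_struts = 2L, strut_th_um = 140,
      os_fraction = 0.35, ob_fraction = 0.06,
      eroded_fraction = 0.08, oc_fraction = 0.005,
      o_th_um = 5, dl_fraction = 0.05, sl_fraction = 0.02,
      mar_um_day = 0.7, label_interval_days = 15, n_osteoclasts = 4L
    )) {
  spec <- list(seed = as.integer(seed), width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               pixel_size_um = pixel_size_um, cortical_frac = cortical_frac,
               bvtv = bvtv, strut_scale_px = strut_scale_px,
               mineralization = mineralization, lacunae = lacunae,
               sensor = sensor, histo = histo)
  for (comp in spec$mineralization) {
    if (abs(sum(comp$weights) - 1) > 1e-9)
      bm_stop("bm_domain_error", "mixture weights must sum to 1")
    if (any(comp$sds <= 0))
      bm_stop("bm_domain_error", "mixture SDs must be > 0")
  }
  if (spec$lacunae$density_per_mm2 < 0 || spec$bvtv <= 0 || spec$bvtv > 1)
    bm_stop("bm_domain_error", "densities and fractions must be valid")
  class(spec) <- "synthetic_spec"
  spec
}

#' Read a synthetic spec from YAML
#'
#' Fields present in the YAML override the [synthetic_spec()] defaults;
#' nested blocks (`mineralization`, `lacunae`, `sensor`, `histo`) are merged
#' element-wise.
#'
#' @param path YAML path.
#' @return a `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  base <- synthetic_spec()
  for (nm in names(y)) {
    if (is.list(base[[nm]]) && is.list(y[[nm]]) && nm != "mineralization") {
      base[[nm]][names(y[[nm]])] <- y[[nm]]
    } else if (nm == "mineralization") {
      for (comp in names(y[[nm]])) base[[nm]][[comp]] <- y[[nm]][[comp]]
    } else base[[nm]] <- y[[nm]]
  }
  if (!is.null(y$sensor$calibration)) {
    a <- y$sensor$calibration$anchors
    base$sensor$calibration <- calibration_fit(a[[1]][1], a[[1]][2],
                                               a[[2]][1], a[[2]][2])
  } else base$sensor$calibration <- calibration_fit()
  do.call(synthetic_spec, base)
}

# internal: derive independent sub-seeds from the master seed
sub_seeds <- function(seed, n = 4L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# internal: separable Gaussian blur with edge renormalization
gauss_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (d in -r:r) {
      src <- pmin(pmax(seq_len(n) + d, 1L), n)  # replicate edges
      out <- out + k[d + r + 1L] * m[src, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(x))))
}

# internal: count of TRUE cells in a (2r+1) square window around each cell
box_count <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[(r + 1L):(nr + r), (r + 1L):(nc + r)] <- m
  out <- matrix(0, nr, nc)
  for (dr in -r:r) for (dc in -r:r)
    out <- out + pad[(r + 1L + dr):(nr + r + dr), (r + 1L + dc):(nc + r + dc)]
  out
}

# internal: pixel indices of a rotated ellipse (semi-axes in px)
ellipse_pixels <- function(nr, nc, cx, cy, a, b, theta) {
  r <- ceiling(a) + 1L
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  dx <- outer(rep(1, length(rows)), cols - 0.5 - cx)
  dy <- outer(rows - 0.5 - cy, rep(1, length(cols)))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

#' True BMDD parameters of a normal mixture
#'
#' Computes the five BMDD parameters of a continuous normal-mixture calcium
#' distribution (the generator's ground truth): mean analytically, tail
#' fractions from the mixture CDF, and mode/FWHM numerically on a fine grid
#' with linear interpolation at the half-maximum crossings.
#'
#' @param weights,means,sds mixture components (wt% Ca).
#' @param low_cut,high_cut tail cuts (wt% Ca).
#' @param grid_step numeric grid step for mode/FWHM (default 0.002).
#' @return named vector `CaMean`, `CaPeak`, `CaWidth`, `CaLow`, `CaHigh`.
#' @export
mixture_bmdd_truth <- function(weights, means, sds,
                               low_cut = 17.68, high_cut = 25.30,
                               grid_step = 0.002) {
  lo <- max(0, min(means - 6 * sds))
  hi <- max(means + 6 * sds)
  x <- seq(lo, hi, by = grid_step)
  dens <- rowSums(vapply(seq_along(weights), function(i)
    weights[i] * stats::dnorm(x, means[i], sds[i]), numeric(length(x))))
  pk <- which.max(dens)
  half <- dens[pk] / 2
  li <- max(which(dens[1:pk] < half))
  xl <- x[li] + (half - dens[li]) / (dens[li + 1] - dens[li]) * grid_step
  ri <- pk + min(which(dens[pk:length(x)] < half)) - 1L
  xr <- x[ri - 1] + (dens[ri - 1] - half) / (dens[ri - 1] - dens[ri]) * grid_step
  cdf <- function(q) sum(weights * stats::pnorm(q, means, sds))
  c(CaMean = sum(weights * means),
    CaPeak = x[pk],
    CaWidth = xr - xl,
    CaLow = 100 * cdf(low_cut),
    CaHigh = 100 * (1 - cdf(high_cut)))
}

#' Generate a synthetic qBEI raster with known ground truth
#'
#' Builds a two-compartment bone field (solid cortical band, trabecular
#' struts from a thresholded smoothed-noise field), draws every bone pixel's
#' calcium content from its compartment's normal mixture, stamps elliptical
#' osteocyte lacunae into the bone at a low gray level, and pushes the scene
#' through the sensor model (calibration, additive Gaussian gray-level
#' noise, 8-bit quantization).
#'
#' Lacunae are placed by rejection sampling: each lacuna must lie entirely
#' in bone, at least `min_separation_px` pixels from marrow, from the image
#' border and from every other lacuna, so planted lacunae are recoverable as
#' distinct connected components.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `image` (integer gray-level matrix), `compartments`
#'   (0 = none, 1 = cortical, 2 = trabecular region), `bone_mask` (logical,
#'   bone tissue including lacunae), and `truth`: per-compartment mixture
#'   parameters and their [mixture_bmdd_truth()], the planted lacuna table
#'   (center, semi-axes, orientation, analytic and rasterized areas, aspect
#'   ratio), lacuna counts and density, and the bone area in mm^2.
#' @export
generate_qbei <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  # leave the caller's RNG stream untouched
  old_rng <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  nr <- spec$height_px; nc <- spec$width_px
  ps <- spec$pixel_size_um
  ss <- sub_seeds(spec$seed, 4L)

  ## --- geometry -------------------------------------------------------
  set.seed(ss[1])
  n_cort <- round(spec$cortical_frac * nc)
  comp <- matrix(0L, nr, nc)
  if (n_cort > 0) comp[, seq_len(n_cort)] <- 1L
  if (n_cort < nc) comp[, (n_cort + 1L):nc] <- 2L
  bone <- comp == 1L
  if (n_cort < nc) {
    field <- gauss_blur(matrix(stats::rnorm(nr * (nc - n_cort)), nr),
                        spec$strut_scale_px)
    thr <- stats::quantile(field, 1 - spec$bvtv)
    bone[, (n_cort + 1L):nc] <- field >= thr
  }
  bone_px <- sum(bone)
  bone_area_mm2 <- bone_px * (ps / 1000)^2

  ## --- lacunae --------------------------------------------------------
  set.seed(ss[2])
  lac <- spec$lacunae
  sep <- lac$min_separation_px
  n_target <- round(lac$density_per_mm2 * bone_area_mm2)
  allowed <- box_count(!bone, sep) == 0
  allowed[c(seq_len(sep + 1L), (nr - sep):nr), ] <- FALSE
  allowed[, c(seq_len(sep + 1L), (nc - sep):nc)] <- FALSE
  cand_idx <- which(allowed)
  lacuna_mask <- matrix(FALSE, nr, nc)
  forbidden <- matrix(FALSE, nr, nc)
  planted <- vector("list", n_target)
  n_placed <- 0L
  tries <- 0L
  max_tries <- 200L * max(n_target, 1L)
  while (n_placed < n_target && tries < max_tries) {
    tries <- tries + 1L
    area <- stats::rlnorm(1, lac$area_meanlog, lac$area_sdlog)
    if (area > lac$area_cap_um2) next
    ar <- max(1, stats::rlnorm(1, log(lac$ar_mean) - 0.5 * (lac$ar_sd / lac$ar_mean)^2,
                               lac$ar_sd / lac$ar_mean))
    b <- sqrt(area / (pi * ar)) / ps     # semi-minor in px
    a <- ar * b
    theta <- stats::runif(1, 0, pi)
    ctr <- cand_idx[sample.int(length(cand_idx), 1L)]
    cy <- ((ctr - 1L) %% nr) + 0.5
    cx <- ((ctr - 1L) %/% nr) + 0.5
    px <- ellipse_pixels(nr, nc, cx, cy, a, b, theta)
    if (nrow(px) == 0L) next
    ok <- all(allowed[px]) && !any(forbidden[px])
    if (!ok) next
    n_placed <- n_placed + 1L
    lacuna_mask[px] <- TRUE
    # forbid a sep-dilated halo around the new lacuna
    for (dr in -sep:sep) for (dc in -sep:sep) {
      rr <- px[, 1] + dr; cc2 <- px[, 2] + dc
      keep <- rr >= 1 & rr <= nr & cc2 >= 1 & cc2 <= nc
      forbidden[cbind(rr[keep], cc2[keep])] <- TRUE
    }
    planted[[n_placed]] <- data.frame(
      id = n_placed, x_um = cx * ps, y_um = cy * ps,
      semi_major_um = a * ps, semi_minor_um = b * ps, theta = theta,
      area_um2 = area, area_px_um2 = nrow(px) * ps^2,
      aspect_ratio = ar, compartment = comp[px[1, 1], px[1, 2]])
  }
  if (n_placed < n_target)
    bm_stop("bm_packing_error",
            sprintf("placed only %d of %d lacunae; lower the lacunar density or enlarge the canvas",
                    n_placed, n_target))
  planted <- if (n_target > 0) do.call(rbind, planted) else
    data.frame(id = integer(0))

  ## --- mineralization -------------------------------------------------
  set.seed(ss[3])
  cal <- spec$sensor$calibration
  gl <- matrix(spec$sensor$background_gl, nr, nc)
  for (ci in 1:2) {
    mix <- spec$mineralization[[c("cortical", "trabecular")[ci]]]
    sel <- bone & comp == ci & !lacuna_mask
    n <- sum(sel)
    if (n == 0L) next
    k <- sample.int(length(mix$weights), n, replace = TRUE, prob = mix$weights)
    ca <- stats::rnorm(n, mix$means[k], mix$sds[k])
    gl[sel] <- suppressWarnings(ca_to_gl(cal, pmax(ca, 0)))
  }
  gl[lacuna_mask] <- lac$gl

  ## --- sensor noise and quantization ----------------------------------
  set.seed(ss[4])
  if (spec$sensor$noise_gl_sd > 0)
    gl <- gl + stats::rnorm(nr * nc, 0, spec$sensor$noise_gl_sd)
  img <- matrix(as.integer(pmin(pmax(round(gl), 0), 255)), nr, nc)

  truth_bmdd <- lapply(spec$mineralization, function(mix)
    mixture_bmdd_truth(mix$weights, mix$means, mix$sds))

  list(
    image = img,
    compartments = comp,
    bone_mask = bone,
    truth = list(
      mineralization = spec$mineralization,
      bmdd = truth_bmdd,
      lacunae = planted,
      n_lacunae = n_placed,
      lacuna_density_per_mm2 = if (bone_area_mm2 > 0) n_placed / bone_area_mm2 else NA,
      bone_area_mm2 = bone_area_mm2,
      pixel_size_um = ps
    )
  )
}

#' Generate a synthetic histomorphometry scene with known ground truth
#'
#' Lays out straight trabecular plates, partitions their top and bottom
#' surfaces into remodeling states at the specified fractions, rasterizes
#' osteoid seams of the specified width along the osteoid-covered extent,
#' and plants tetracycline label polylines whose inter-label distance
#' encodes the target mineral apposition rate. The returned ground truth
#' carries the exact planted primitives, so every derived ASBMR parameter
#' has a closed-form expected value.
#'
#' @param spec a [synthetic_spec()]; only the `histo` block and `seed` are
#'   used.
#' @return list with `raster` ([class_raster()]), `annotation`
#'   ([surface_annotation()]) and `truth` (a [histo_primitives()] of the
#'   planted values plus the derived [histo_parameters()]).
#' @export
generate_histo_scene <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$histo
  ps <- h$pixel_size_um
  nr <- h$height_px; nc <- h$width_px
  t_px <- round(h$strut_th_um / ps)
  w_px <- round(h$o_th_um / ps)
  if (w_px >= t_px)
    bm_stop("bm_geometry_error",
            "osteoid seam width must be smaller than the strut thickness")
  if (h$os_fraction < h$ob_fraction || h$eroded_fraction < h$oc_fraction)
    bm_stop("bm_domain_error",
            "osteoblast/osteoclast fractions are subsets of the osteoid/eroded fractions")
  margin <- round(0.05 * nc)
  L_px <- nc - 2L * margin
  gap <- (nr - h$n_struts * t_px) %/% (h$n_struts + 1L)
  if (gap < 2L) bm_stop("bm_geometry_error", "struts do not fit the canvas")

  cls <- matrix(CLASS_VOID, nr, nc)
  surfaces <- list(); labels <- list()
  x0 <- margin * ps; x1 <- (margin + L_px) * ps

  # split one edge into state segments at the global fractions
  state_cuts <- function() {
    fr <- c(OSTEOID = h$os_fraction - h$ob_fraction,
            OSTEOBLAST = h$ob_fraction,
            ERODED = h$eroded_fraction - h$oc_fraction,
            OSTEOCLAST = h$oc_fraction)
    fr <- c(fr, QUIESCENT = 1 - sum(fr))
    cum <- cumsum(c(0, fr))
    lapply(seq_along(fr), function(i)
      list(state = names(fr)[i],
           from = x0 + cum[i] * (x1 - x0), to = x0 + cum[i + 1] * (x1 - x0)))
  }

  for (s in seq_len(h$n_struts)) {
    top <- gap * s + t_px * (s - 1L) + 1L       # first bone row
    rows <- top:(top + t_px - 1L)
    cols <- (margin + 1L):(margin + L_px)
    cls[rows, cols] <- CLASS_MINERALIZED
    y_top <- (top - 1L) * ps                    # top bone boundary
    y_bot <- (top + t_px - 1L) * ps             # bottom bone boundary
    for (edge in c("top", "bottom")) {
      y <- if (edge == "top") y_top else y_bot
      for (seg in state_cuts()) {
        if (seg$to - seg$from < 1e-9) next
        surfaces[[length(surfaces) + 1L]] <- list(
          coords = matrix(c(seg$from, y, seg$to, y), 2, byrow = TRUE),
          state = seg$state)
        if (seg$state %in% c("OSTEOID", "OSTEOBLAST")) {
          c0 <- floor(seg$from / ps) + 1L
          c1 <- ceiling(seg$to / ps)
          seam_rows <- if (edge == "top") rows[seq_len(w_px)]
                       else rows[(t_px - w_px + 1L):t_px]
          cls[seam_rows, c0:c1] <- CLASS_OSTEOID
        }
      }
    }
    # tetracycline labels along the quiescent part of the top edge
    lab_len_d <- h$dl_fraction * 2 * (x1 - x0)  # per strut, both edges pooled
    lab_len_s <- h$sl_fraction * 2 * (x1 - x0)
    xq <- x0 + (h$os_fraction + h$eroded_fraction) * (x1 - x0)
    if (lab_len_d > 0)
      labels[[length(labels) + 1L]] <- list(
        coords = matrix(c(xq, y_top, xq + lab_len_d, y_top), 2, byrow = TRUE),
        type = "double",
        inter_label_um = h$mar_um_day * h$label_interval_days)
    if (lab_len_s > 0)
      labels[[length(labels) + 1L]] <- list(
        coords = matrix(c(xq, y_bot, xq + lab_len_s, y_bot), 2, byrow = TRUE),
        type = "single", inter_label_um = NULL)
  }

  ann <- surface_annotation(surfaces, labels,
                            label_interval_days = h$label_interval_days,
                            n_osteoclasts = h$n_osteoclasts)
  raster <- class_raster(cls, ps)

  L_mm <- L_px * ps / 1000
  bs <- h$n_struts * 2 * L_mm
  ov <- sum(cls == CLASS_OSTEOID) * (ps / 1000)^2  # exact by construction
  truth_prim <- histo_primitives(
    tv = nr * nc * (ps / 1000)^2,
    bv = h$n_struts * L_px * t_px * (ps / 1000)^2,
    bs = bs,
    ov = ov,
    os = h$os_fraction * bs,
    o_th_direct = h$o_th_um,
    ob_s = h$ob_fraction * bs,
    es = h$eroded_fraction * bs,
    oc_s = h$oc_fraction * bs,
    n_oc = h$n_osteoclasts,
    dl_pm = h$dl_fraction * bs,
    sl_pm = h$sl_fraction * bs,
    ir_l_wi = if (h$dl_fraction > 0) h$mar_um_day * h$label_interval_days else NA_real_,
    label_interval = h$label_interval_days)

  list(raster = raster, annotation = ann,
       truth = list(primitives = truth_prim,
                    params = histo_parameters(truth_prim)))
}
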