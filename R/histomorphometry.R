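#' Class-coded section raster
#'
#' Container for a histological section raster in which every pixel carries
#' a tissue class: 0 = void/marrow, 1 = mineralized bone, 2 = osteoid. An
#' optional parallel raster labels compartments (0 = outside, 1 = cortical,
#' 2 = trabecular); compartment extent includes intracompartmental voids,
#' so cortical porosity is computable from it.
#'
#' @param classes integer matrix with values in \{0, 1, 2\}.
#' @param pixel_size pixel edge length in micrometers.
#' @param compartments optional integer matrix, congruent with `classes`,
#'   with values in \{0, 1, 2\}.
#' @return a `class_raster` object.
#' @export
class_raster <- function(classes, pixel_size, compartments = NULL) {
  stopifnot(is.matrix(classes))
  if (pixel_size <= 0) bm_stop("bm_domain_error", "pixel_size must be > 0")
  if (!all(classes %in% 0:2))
    bm_stop("bm_domain_error", "classes must be 0 (void), 1 (mineralized) or 2 (osteoid)")
  if (!is.null(compartments) && !all(dim(compartments) == dim(classes)))
    bm_stop("bm_shape_error", "compartment raster does not match class raster")
  structure(list(classes = classes, pixel_size = pixel_size,
                 compartments = compartments),
            class = "class_raster")
}

CLASS_VOID <- 0L; CLASS_MINERALIZED <- 1L; CLASS_OSTEOID <- 2L

SURFACE_STATES <- c("QUIESCENT", "OSTEOID", "OSTEOBLAST", "ERODED", "OSTEOCLAST")

#' Bone-surface and tetracycline-label annotation
#'
#' Surface polylines partition the bone perimeter into remodeling states;
#' tetracycline labels are polylines marking the mineralization front, as
#' double-label pairs (with a mean inter-label distance) or single labels.
#'
#' @param surfaces list of polylines; each element is a list with `coords`
#'   (n x 2 matrix of x,y in micrometers) and `state` (one of `"QUIESCENT"`,
#'   `"OSTEOID"`, `"OSTEOBLAST"`, `"ERODED"`, `"OSTEOCLAST"`). Osteoid
#'   surface (OS) is the union of the OSTEOID and OSTEOBLAST states; eroded
#'   surface (ES) the union of ERODED and OSTEOCLAST.
#' @param labels list of label polylines; each a list with `coords`, `type`
#'   (`"double"` or `"single"`) and, for double labels, `inter_label_um`
#'   (mean distance between the two labels of the pair, > 0).
#' @param label_interval_days time between the midpoints of the two
#'   tetracycline courses (default 15: two 3-day courses separated by a
#'   12-day interval).
#' @param n_osteoclasts optional osteoclast count for N.Oc/BS.
#' @param osteoid_widths_um optional vector of directly measured osteoid
#'   seam widths; when supplied their mean is used as O.Th instead of the
#'   OV/OS quotient.
#' @return a `surface_annotation` object.
#' @export
surface_annotation <- function(surfaces = list(), labels = list(),
                               label_interval_days = 15,
                               n_osteoclasts = NA_integer_,
                               osteoid_widths_um = NULL) {
  for (s in surfaces) {
    if (!s$state %in% SURFACE_STATES)
      bm_stop("bm_input_error",
              sprintf("unknown surface state '%s'", s$state))
    stopifnot(is.matrix(s$coords), ncol(s$coords) == 2)
  }
  for (l in labels) {
    if (!l$type %in% c("double", "single"))
      bm_stop("bm_input_error", "label type must be 'double' or 'single'")
    if (l$type == "double" &&
        (is.null(l$inter_label_um) || l$inter_label_um <= 0))
      bm_stop("bm_domain_error",
              "double labels require inter_label_um > 0")
  }
  if (label_interval_days <= 0)
    bm_stop("bm_domain_error", "label_interval_days must be > 0")
  structure(list(surfaces = surfaces, labels = labels,
                 label_interval_days = label_interval_days,
                 n_osteoclasts = n_osteoclasts,
                 osteoid_widths_um = osteoid_widths_um),
            class = "surface_annotation")
}

polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

#' Raw histomorphometric primitives
#'
#' The measured quantities from which all ASBMR parameters derive. Areas in
#' square millimeters, surface (perimeter) lengths in millimeters, widths in
#' micrometers. Primitives can be constructed directly (e.g. from values
#' measured in another program) or via [measure_primitives()].
#'
#' @param tv total (tissue) area, mm^2.
#' @param bv bone area (mineralized + osteoid), mm^2.
#' @param bs bone surface (perimeter) length, mm.
#' @param ov osteoid area, mm^2.
#' @param os osteoid surface length, mm.
#' @param o_th_direct directly measured mean osteoid seam width, um
#'   (`NA` to fall back on `1000 * ov / os`).
#' @param ob_s osteoblast-covered surface length, mm.
#' @param es eroded surface length, mm.
#' @param oc_s osteoclast-covered surface length, mm.
#' @param n_oc osteoclast count.
#' @param dl_pm double-labeled perimeter, mm.
#' @param sl_pm single-labeled perimeter, mm.
#' @param ir_l_wi mean inter-label width of double labels, um.
#' @param label_interval label interval, days.
#' @param ct_wi cortical width, mm.
#' @param ct_po cortical porosity, %.
#' @return a `histo_primitives` object.
#' @export
histo_primitives <- function(tv, bv, bs, ov = 0, os = 0,
                             o_th_direct = NA_real_, ob_s = 0, es = 0,
                             oc_s = 0, n_oc = NA_real_, dl_pm = 0, sl_pm = 0,
                             ir_l_wi = NA_real_, label_interval = 15,
                             ct_wi = NA_real_, ct_po = NA_real_) {
  p <- list(tv = tv, bv = bv, bs = bs, ov = ov, os = os,
            o_th_direct = o_th_direct, ob_s = ob_s, es = es, oc_s = oc_s,
            n_oc = n_oc, dl_pm = dl_pm, sl_pm = sl_pm, ir_l_wi = ir_l_wi,
            label_interval = label_interval, ct_wi = ct_wi, ct_po = ct_po)
  nonneg <- c("tv", "bv", "bs", "ov", "os", "ob_s", "es", "oc_s",
              "dl_pm", "sl_pm")
  for (nm in nonneg)
    if (!is.na(p[[nm]]) && p[[nm]] < 0)
      bm_stop("bm_domain_error", sprintf("'%s' must be >= 0", nm))
  if (p$os > p$bs + 1e-9)
    bm_stop("bm_domain_error", "osteoid surface cannot exceed bone surface")
  if (p$dl_pm + p$sl_pm > p$bs + 1e-9)
    bm_stop("bm_domain_error", "labeled perimeter cannot exceed bone surface")
  structure(p, class = "histo_primitives")
}

#' Measure histomorphometric primitives from a section
#'
#' Areas are measured by pixel counting on the class raster; surface lengths
#' by polyline arc length over the annotation. When a compartment raster is
#' present, the areal primitives (TV, BV, OV) are restricted to the
#' trabecular compartment and cortical width/porosity are measured on the
#' cortical compartment (porosity = void area within the compartment /
#' compartment area; width = compartment area / its row-wise extent,
#' assuming a band running along the section).
#'
#' Surface polylines are checked against the rasterized bone boundary: a
#' vertex farther than `align_tol_px` pixels from any bone-boundary pixel
#' raises an alignment error.
#'
#' @param raster a [class_raster()].
#' @param ann a [surface_annotation()].
#' @param check_alignment verify polylines lie on the bone boundary
#'   (default `TRUE`).
#' @param align_tol_px alignment tolerance in pixels (default 2).
#' @return a [histo_primitives()] object.
#' @export
measure_primitives <- function(raster, ann, check_alignment = TRUE,
                               align_tol_px = 2) {
  stopifnot(inherits(raster, "class_raster"),
            inherits(ann, "surface_annotation"))
  ps <- raster$pixel_size
  px_mm2 <- (ps / 1000)^2
  cls <- raster$classes
  comp <- raster$compartments
  trab <- if (is.null(comp)) matrix(TRUE, nrow(cls), ncol(cls)) else comp == 2L

  tv <- sum(trab) * px_mm2
  bv <- sum(trab & cls != CLASS_VOID) * px_mm2
  ov <- sum(trab & cls == CLASS_OSTEOID) * px_mm2

  if (check_alignment && length(ann$surfaces))
    check_surface_alignment(cls, ann, ps, align_tol_px)

  state_len <- function(states) {
    sum(vapply(ann$surfaces, function(s)
      if (s$state %in% states) polyline_length(s$coords) else 0,
      numeric(1))) / 1000  # um -> mm
  }
  bs <- state_len(SURFACE_STATES)
  os <- state_len(c("OSTEOID", "OSTEOBLAST"))
  ob_s <- state_len("OSTEOBLAST")
  es <- state_len(c("ERODED", "OSTEOCLAST"))
  oc_s <- state_len("OSTEOCLAST")

  lab_len <- function(type) {
    sum(vapply(ann$labels, function(l)
      if (l$type == type) polyline_length(l$coords) else 0,
      numeric(1))) / 1000
  }
  dl_pm <- lab_len("double")
  sl_pm <- lab_len("single")
  dbl <- Filter(function(l) l$type == "double", ann$labels)
  ir_l_wi <- if (length(dbl)) {
    w <- vapply(dbl, function(l) l$inter_label_um, numeric(1))
    len <- vapply(dbl, function(l) polyline_length(l$coords), numeric(1))
    sum(w * len) / sum(len)
  } else NA_real_

  o_th_direct <- if (!is.null(ann$osteoid_widths_um))
    mean(ann$osteoid_widths_um) else NA_real_

  ct_wi <- NA_real_; ct_po <- NA_real_
  if (!is.null(comp) && any(comp == 1L)) {
    cort <- comp == 1L
    ct_area <- sum(cort) * px_mm2
    ct_po <- 100 * sum(cort & cls == CLASS_VOID) / sum(cort)
    rows_with_cortex <- sum(rowSums(cort) > 0)
    ct_wi <- ct_area / (rows_with_cortex * ps / 1000)
  }

  histo_primitives(tv = tv, bv = bv, bs = bs, ov = ov, os = os,
                   o_th_direct = o_th_direct, ob_s = ob_s, es = es,
                   oc_s = oc_s, n_oc = ann$n_osteoclasts, dl_pm = dl_pm,
                   sl_pm = sl_pm, ir_l_wi = ir_l_wi,
                   label_interval = ann$label_interval_days,
                   ct_wi = ct_wi, ct_po = ct_po)
}

# internal: every polyline vertex must sit within tol pixels of a pixel on
# the bone/void boundary
check_surface_alignment <- function(cls, ann, ps, tol) {
  bone <- cls != CLASS_VOID
  nr <- nrow(bone); nc <- ncol(bone)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- bone
  boundary <- bone & !(pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
                       pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)])
  bidx <- which(boundary, arr.ind = TRUE)
  if (nrow(bidx) == 0L)
    bm_stop("bm_alignment_error", "raster has no bone boundary")
  for (s in ann$surfaces) {
    v <- s$coords / ps   # um -> px coordinates (x = col, y = row)
    for (k in seq_len(nrow(v))) {
      col <- v[k, 1] + 0.5; row <- v[k, 2] + 0.5
      d <- pmax(abs(bidx[, 1] - row), abs(bidx[, 2] - col))
      if (min(d) > tol + 0.5 + 1e-9)
        bm_stop("bm_alignment_error",
                sprintf("surface vertex (%.1f, %.1f) um lies > %g px off the bone boundary",
                        s$coords[k, 1], s$coords[k, 2], tol))
    }
  }
  invisible(TRUE)
}

#' Static ASBMR parameters
#'
#' Derives the static structural and formation/resorption parameters from
#' measured primitives. Trabecular thickness uses the plate model,
#' `Tb.Th = 2000 * BV / BS` (um, with BV in mm^2 and BS in mm), and
#' `Tb.N = (BV/TV) / Tb.Th * 1000` (1/mm, with BV/TV as a fraction). O.Th is
#' the directly measured seam width when available, otherwise `OV/OS`.
#'
#' @param prim a [histo_primitives()] object.
#' @return a named numeric vector of class `histo_params` with attribute
#'   `flags` naming parameters undefined because of a zero denominator.
#' @export
static_parameters <- function(prim) {
  stopifnot(inherits(prim, "histo_primitives"))
  flags <- character(0)
  sdiv <- function(num, den, name) {
    if (is.na(den) || den == 0) { flags <<- c(flags, name); NA_real_ }
    else num / den
  }
  bvtv <- 100 * sdiv(prim$bv, prim$tv, "BV/TV")
  tbth <- 2000 * sdiv(prim$bv, prim$bs, "Tb.Th")
  tbn <- sdiv(bvtv / 100, tbth, "Tb.N") * 1000
  o_th <- if (!is.na(prim$o_th_direct)) prim$o_th_direct
          else 1000 * sdiv(prim$ov, prim$os, "O.Th")
  out <- c(
    "BV/TV"   = bvtv,
    "Tb.Th"   = tbth,
    "Tb.N"    = tbn,
    "Ct.Wi"   = prim$ct_wi,
    "Ct.Po"   = prim$ct_po,
    "OV/BV"   = 100 * sdiv(prim$ov, prim$bv, "OV/BV"),
    "O.Th"    = o_th,
    "OS/BS"   = 100 * sdiv(prim$os, prim$bs, "OS/BS"),
    "Ob.S/BS" = 100 * sdiv(prim$ob_s, prim$bs, "Ob.S/BS"),
    "ES/BS"   = 100 * sdiv(prim$es, prim$bs, "ES/BS"),
    "Oc.S/BS" = 100 * sdiv(prim$oc_s, prim$bs, "Oc.S/BS"),
    "N.Oc/BS" = sdiv(prim$n_oc, prim$bs, "N.Oc/BS")
  )
  structure(out, flags = unique(flags), class = "histo_params")
}

#' Dynamic (tetracycline-derived) ASBMR parameters
#'
#' The dynamic chain:
#' \deqn{MS/BS = 100 (dL.Pm + sL.Pm/2) / BS}
#' \deqn{MAR = Ir.L.Wi / label\ interval}
#' \deqn{Aj.Ar = MAR \cdot (MS/BS) / (OS/BS)}
#' \deqn{Mlt = O.Th / Aj.Ar}
#' \deqn{BFR/BS = MAR \cdot (MS/BS)/100 \cdot 365}
#' \deqn{BFR/BV = (BFR/BS) \cdot (BS/BV) / 10}
#' Single labels count half in the mineralizing surface. The identities
#' `Mlt * Aj.Ar = O.Th` and `BFR/BS = MAR * (MS/BS)/100 * 365` hold exactly
#' before any rounding.
#'
#' @param prim a [histo_primitives()] object.
#' @param o_th osteoid thickness in micrometers used for Mlt; defaults to
#'   the direct measurement in `prim`, falling back on `OV/OS`.
#' @return a named numeric vector of class `histo_params` (`MS/BS`, `MAR`,
#'   `Aj.Ar`, `BFR/BS`, `BFR/BV`, `Mlt`) with attribute `flags`.
#' @export
dynamic_parameters <- function(prim, o_th = NULL) {
  stopifnot(inherits(prim, "histo_primitives"))
  if (prim$label_interval <= 0)
    bm_stop("bm_domain_error", "label interval must be > 0")
  if (prim$bs <= 0) bm_stop("bm_domain_error", "bone surface must be > 0")
  flags <- character(0)
  ms_bs <- 100 * (prim$dl_pm + prim$sl_pm / 2) / prim$bs
  os_bs <- 100 * prim$os / prim$bs
  if (os_bs == 0 && ms_bs > 0)
    bm_stop("bm_inconsistency",
            "mineralizing surface without osteoid surface is inconsistent")
  mar <- if (is.na(prim$ir_l_wi)) {
    if (ms_bs > 0) flags <- c(flags, "MAR")
    NA_real_
  } else prim$ir_l_wi / prim$label_interval
  aj_ar <- if (os_bs > 0 && !is.na(mar)) mar * ms_bs / os_bs else {
    flags <- c(flags, "Aj.Ar"); NA_real_
  }
  if (is.null(o_th)) {
    o_th <- if (!is.na(prim$o_th_direct)) prim$o_th_direct
            else if (prim$os > 0) 1000 * prim$ov / prim$os else NA_real_
  }
  mlt <- if (!is.na(aj_ar) && aj_ar > 0 && !is.na(o_th)) o_th / aj_ar else {
    flags <- c(flags, "Mlt"); NA_real_
  }
  # a fully quiescent surface forms no bone regardless of the (then
  # unmeasurable) apposition rate
  bfr_bs <- if (ms_bs == 0) 0 else if (!is.na(mar))
    mar * (ms_bs / 100) * 365 else NA_real_
  bfr_bv <- if (!is.na(bfr_bs) && prim$bv > 0)
    bfr_bs * (prim$bs / prim$bv) / 10 else {
      flags <- c(flags, "BFR/BV"); NA_real_
    }
  structure(
    c("MS/BS" = ms_bs, "MAR" = mar, "Aj.Ar" = aj_ar,
      "BFR/BS" = bfr_bs, "BFR/BV" = bfr_bv, "Mlt" = mlt),
    flags = unique(flags), class = "histo_params")
}

#' Full ASBMR parameter set
#'
#' Combines [static_parameters()] and [dynamic_parameters()].
#'
#' @inheritParams dynamic_parameters
#' @return a `histo_params` named vector.
#' @export
histo_parameters <- function(prim, o_th = NULL) {
  s <- static_parameters(prim)
  d <- dynamic_parameters(prim, o_th = o_th)
  structure(c(unclass(s), unclass(d)),
            flags = unique(c(attr(s, "flags"), attr(d, "flags"))),
            class = "histo_params")
}

#' @export
print.histo_params <- function(x, ...) {
  df <- data.frame(parameter = names(x), value = signif(unclass(x), 5))
  print(df, row.names = FALSE)
  fl <- attr(x, "flags")
  if (length(fl)) cat("undefined:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Standardize histomorphometric parameters against normative references
#'
#' Looks up the age- and sex-matched rows of a normative reference table and
#' standardizes every parameter that has a matching row; parameters without
#' a reference row (e.g. cortical porosity in most normative series) are
#' skipped and listed in the `"skipped"` attribute. Deviations beyond 2 SD
#' are flagged.
#'
#' @param params a `histo_params` vector (or named numeric vector).
#' @param ref reference table with columns
#'   `parameter,sex,age_lo,age_hi,mean,sd`.
#' @param sex `"M"` or `"F"`.
#' @param age age in years; matched against `[age_lo, age_hi]`.
#' @return a [zscore_set()] with attribute `skipped`.
#' @export
zscore_table <- function(params, ref, sex, age) {
  stopifnot(is.numeric(params), !is.null(names(params)))
  band <- ref[ref$sex == sex & age >= ref$age_lo & age <= ref$age_hi, ]
  if (nrow(band) == 0L) {
    bands <- unique(sprintf("%s %d-%d", ref$sex, ref$age_lo, ref$age_hi))
    bm_stop("bm_missing_reference",
            paste0("no reference rows for ", sex, " age ", age,
                   "; available bands: ", paste(bands, collapse = ", ")))
  }
  m <- match(names(params), band$parameter)
  have <- !is.na(m) & !is.na(unclass(params))
  zs <- zscore_set(names(params)[have], unname(unclass(params)[have]),
                   band$mean[m[have]], band$sd[m[have]])
  attr(zs, "skipped") <- names(params)[!have]
  zs
}

#' Import histomorphometric primitives from CSV
#'
#' Reads a one-row wide CSV whose column names are the arguments of
#' [histo_primitives()] (e.g. `tv,bv,bs,ov,os,...`), so the parameter
#' calculus is usable without image measurement.
#'
#' @param path CSV path.
#' @return a [histo_primitives()] object.
#' @export
read_primitives_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) != 1L)
    bm_stop("bm_input_error", "primitives CSV must contain exactly one row")
  do.call(histo_primitives, as.list(df))
}
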