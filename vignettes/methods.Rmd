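---
title: "Methods: quantitative bone-matrix analysis with bonematrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative bone-matrix analysis with bonematrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonematrix)
```

This vignette documents the scientific model behind `bonematrix`, the
meaning and defaults of every tunable parameter, what the synthetic
generator does and does not emulate, the numerical conventions the
implementation commits to, and the limitations of the approach. It is a
methods description, not a results paper: every quantitative statement
here is either a definition or something the package's test suite
actually computes.

## 1. The measurement model

The package analyses undecalcified transiliac bone biopsies through
three complementary channels:

1. **qBEI mineralization imaging.** In quantitative backscattered
   electron imaging, the gray level of a polished bone surface is, over
   the relevant range, an affine function of the local calcium
   weight-percent. Calibrated gray-level histograms of the mineralized
   bone area give the *bone mineralization density distribution* (BMDD).
2. **Osteocyte lacunae sections (OLS).** At higher magnification the
   same rasters resolve osteocyte lacunae as small unmineralized
   (dark) islands inside bone. Their number, size and shape per bone
   area are morphometric indicators of osteocyte recruitment and
   perilacunar remodeling.
3. **Histomorphometry.** Class-coded section rasters (void /
   mineralized / osteoid) plus surface-state and tetracycline-label
   annotations yield the static and dynamic parameters of the ASBMR
   nomenclature, standardized against age- and sex-matched normative
   references.

### 1.1 Calibration

`calibration_fit(gl_a, ca_a, gl_b, ca_b)` solves the two-anchor affine
system `ca = slope * gl + intercept` exactly. The package defaults place
the organic (0 wt% Ca) phase at gray level 25 and 5.2 wt% Ca at gray
level 55. The second anchor doubles as the conventional bone/void
discrimination level in OLS work, which makes the two channels
consistent: a pixel below gray level 55 is "not mineralized bone" for
both the BMDD mask and the pore segmentation. Both anchors are plain
arguments, so instruments calibrated differently (carbon/aluminium
standards map to other gray levels) are supported without code changes.
Degenerate anchor pairs (equal gray levels, or a non-positive slope) are
rejected with a classed condition rather than producing a silently
useless map.

### 1.2 BMDD

`ca_histogram()` bins the calibrated calcium values of all pixels at or
above the bone threshold into bins that are uniform in wt% Ca, anchored
at 0, with default width 0.17 wt% Ca — about one 8-bit gray level under
the default calibration, so default binning loses essentially no
information relative to the sensor. Frequencies are normalized to
percent of contributing pixels and always sum to 100.

`bmdd_parameters()` derives the five canonical summary parameters:

* **CaMean** — the frequency-weighted mean, computed on the *raw*
  histogram (smoothing would not change it in exact arithmetic, so the
  raw value is used).
* **CaPeak** — the mode, located on a boxcar-smoothed copy of the
  histogram (default window: 3 bins) to suppress single-bin noise. Exact
  ties resolve to the lowest-calcium candidate and set a `peak_tie`
  flag.
* **CaWidth** — the full width at half maximum of the smoothed
  histogram, with linear interpolation at the two half-maximum
  crossings, so the value is not quantized to whole bins. For a Gaussian
  this equals `2*sqrt(2*log(2)) * sigma ≈ 2.3548 sigma`, which the test
  suite verifies to ±0.02 wt% Ca on finely binned Gaussians.
* **CaLow / CaHigh** — the percent of bone area below 17.68 and above
  25.30 wt% Ca respectively, evaluated as strict inequalities on bin
  centers. The cuts are the conventional ±5th/95th percentile bounds of
  the adult trabecular reference BMDD and are arguments, not constants.

Compartment contrasts (`compare_compartments()`) are reported as
`100 * (cortical - trabecular) / trabecular`, rounded to one decimal;
standardized differences (`bmdd_zscores()`, `zscore_table()`) as
`(value - mean) / sd`, rounded to two decimals. All clinical rounding
uses *round half away from zero* (`round_half_away()`), matching how
printed clinical tables are typically rounded, rather than R's default
round-half-to-even.

### 1.3 OLS morphometry

`segment_pores()` thresholds strictly below the bone gray level
(default 55) and labels connected components, by default with
8-connectivity (4-connectivity is available). Per region it reports:

* area as `pixel count * pixel_size^2` (exact for the discrete image);
* perimeter as the city-block exposed-edge count times the pixel size;
* an equivalent ellipse from the second central moments of the pixel
  centers, with axes `4 * sqrt(eigenvalues)` of the covariance matrix —
  the same convention as common image-analysis toolkits, so a rasterized
  ellipse with semi-axes `a >= b` recovers `major ≈ 2a`, `minor ≈ 2b`
  and aspect ratio `a/b`.

`filter_lacunae()` splits regions into osteocyte lacunae and larger
pores at an *inclusive* 200 µm² cutoff and, by default, censors
border-touching regions (their area and shape are right-censored by the
field of view). `ols_summary()` then reports density (per mm² of bone
area, where bone area counts the mineralized pixels plus the retained
lacuna pixels), mean area/perimeter/aspect ratio, and lacunar porosity.

### 1.4 Histomorphometry

`measure_primitives()` reduces a class raster plus annotation to the
primitive quantities of the ASBMR calculus — areas (TV, BV including
osteoid, OV), boundary lengths (BS, OS, Ob.S, ES, Oc.S), label extents
(dL.Pm, sL.Pm) and the mean inter-label distance. Annotation polylines
must hug the rasterized bone boundary (within 2 px by default) or a
`bm_alignment_error` is raised; this catches mismatched raster/annotation
pairs early. Derived parameters follow the standard definitions, with a
plate model for trabecular architecture:

* `Tb.Th = 2000 * BV / BS` (µm), `Tb.N = (BV/TV) / Tb.Th` (/mm);
* `O.Th` direct where measured, else `1000 * OV / OS`;
* `MS/BS = 100 * (dL.Pm + sL.Pm/2) / BS` (single labels count half);
* `MAR = Ir.L.Wi / label interval` (default interval 15 days — set it to
  the actual labeling schedule of the biopsy);
* `Aj.Ar = MAR * (MS/BS) / (OS/BS)`;
* `Mlt = O.Th / Aj.Ar`, so `Mlt * Aj.Ar = O.Th` holds as an exact
  identity before rounding (the suite asserts it at 1e-12);
* `BFR/BS = MAR * (MS/BS)/100 * 365`, `BFR/BV = BFR/BS * (BS/BV) / 10`.

A fully quiescent surface (`MS/BS = 0`) reports `BFR = 0` and flags MAR
and Mlt as undefined rather than erroring; labeled surface with zero
osteoid surface is rejected as inconsistent input.

Z-scores use a long-format reference table (parameter, sex, age band,
mean, SD). Parameters without a reference row are skipped and listed in
a `skipped` attribute; an age outside every band is an error that names
the available bands. The shipped reference covers males in the 21–30 and
61–70 year bands; cortical width in that table has a much tighter SD
than most parameters, so cortical thinning shows up strongly in
standardized units.

## 2. The synthetic generator

Because no public image data exist for this kind of study, the package
ships a generator whose **defaults are the study conditions**: a
moderately under-mineralized, unusually heterogeneous matrix (trabecular
mean 20.7 wt% Ca, SD 2.1; cortical 22.4, SD 1.8), dense lacunae
(220/mm², lognormal areas with mean 45 µm² capped at 180 µm², aspect
ratio ~2), extended osteoid surface (35% of BS) with thin (5 µm) seams,
sparse double labels (5% of BS) and MAR 0.7 µm/day with a 15-day
interval.

`generate_qbei()` builds the mineralization channel: a solid cortical
band plus trabecular struts obtained by thresholding a
Gaussian-smoothed white-noise field at the exact quantile that yields
the requested area fraction; per-compartment normal-mixture calcium
values; elliptical lacunae placed by rejection sampling so that each
lies entirely in bone, off the image border, and at least 2 px from
marrow and from every other lacuna (so planted lacunae are recoverable
as distinct components); then the sensor model — calibration, additive
Gaussian gray-level noise (SD 2), 8-bit quantization. Geometry, lacuna
placement, mineralization and noise each use a sub-seed derived from the
master seed, so the noise level can be changed without reshuffling the
geometry, and the caller's RNG stream is left untouched.
`mixture_bmdd_truth()` computes the exact BMDD parameters of the
continuous mixture (mean analytically, tails from the CDF, mode/FWHM on
a 0.002 wt% Ca grid), giving every recovery test a closed-form target.

`generate_histo_scene()` builds the histomorphometry channel from
straight horizontal plates whose surfaces are partitioned into states at
specified fractions, with rasterized osteoid seams and label polylines
whose inter-label distance encodes the target MAR. Because the scene is
piecewise-rectangular, every planted primitive — and therefore every
derived parameter — has an exact expected value, and the suite asserts
exact (1e-9) recovery.

**Scope.** The generator emulates what the analysis consumes, not bone
biology: struts are a thresholded random field (qBEI channel) or
straight plates (histo channel), not remodeling-shaped trabeculae;
lacunae are perfect ellipses; mineralization has no spatial
autocorrelation (no osteonal banding, no lamellae); labels are ideal
line pairs. Quantities the analysis derives purely from geometry it
cannot "teach" the analysis to get right by construction — e.g. the
measured lacunar density differs from the nominal one by discretization
and packing effects, which is exactly what the tolerance-based recovery
tests quantify.

## 3. Numerical choices worth knowing about

* **Bin-edge stability.** With the default calibration, integer gray
  levels land exactly on bin edges when the bin width equals one gray
  level. Binning therefore uses `floor(ca/width + 1e-9)`, so values
  within floating-point error of an edge consistently fall in the upper
  bin regardless of how `ca` was computed. This is what makes
  CaMean/CaPeak exactly shift-equivariant under integer gray-level
  shifts (a property the acceptance suite checks).
* **Rounding.** All clinically reported numbers round half away from
  zero with an epsilon guard against binary representation of `x.xx5`.
  Internal values are never rounded; rounding happens in the reporting
  and Z-score layer only.
* **Connectivity.** The 8-connectivity default is implemented as
  4-connected labeling plus a union–find merge of diagonal adjacencies,
  and tested against a hand-built diagonal pair under both conventions.
* **Determinism.** Identical seeds give bit-identical scenes; reports
  are byte-identical across runs given identical inputs and config. A
  serialized `run_config()` (anchors, thresholds, cuts, bin width,
  smoothing window, label interval, seed, package version) is embedded
  in every report.

## 4. Limitations

* The BMDD mode and width are computed on a smoothed histogram; with the
  default 3-bin window on 0.17-bins this is a ~0.5 wt% Ca kernel.
  For delta-like or very narrow distributions pass `smooth_window = 1`.
* `Tb.Th`/`Tb.N` use the plate model; rod-like architectures violate its
  assumptions, and thickness from BV/BS is not comparable to direct
  measurement methods.
* The perimeter is a city-block (exposed pixel edge) measure; it
  systematically overestimates smooth-boundary perimeters. It is
  reported for comparability within the package, not as an unbiased
  estimate.
* Lacuna recovery is provably exact only on pure-bone fields; on mixed
  cortical/trabecular canvases small marrow pockets below the size
  cutoff can appear as false positives, which is a genuine property of
  threshold-based OLS segmentation, not a bug the generator hides.
* Normative references are sparse (two male age bands shipped);
  parameters without a reference row are skipped, not extrapolated.
* The package analyses 2D sections; no 3D lacuno-canalicular or
  stereological inference is attempted.
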