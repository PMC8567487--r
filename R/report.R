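#' Run configuration
#'
#' Collects the tunable constants of a pipeline run so that a serialized
#' copy can be embedded in every output for provenance.
#'
#' @param calibration a [calibration_fit()] map.
#' @param bone_gl_threshold bone/void gray-level threshold.
#' @param ols_max_area lacuna/pore size cutoff, um^2.
#' @param low_cut,high_cut BMDD tail cuts, wt% Ca.
#' @param bin_width BMDD bin width, wt% Ca.
#' @param smooth_window BMDD mode/FWHM smoothing window, bins.
#' @param label_interval tetracycline label interval, days.
#' @param flag_threshold |z| beyond which parameters are flagged.
#' @param unicode_minus use the typographic minus sign in Markdown reports
#'   (machine CSV output always uses ASCII hyphen-minus).
#' @param seed integer seed recorded for provenance.
#' @return a `run_config` list.
#' @export
run_config <- function(calibration = calibration_fit(),
                       bone_gl_threshold = 55, ols_max_area = 200,
                       low_cut = 17.68, high_cut = 25.30,
                       bin_width = 0.17, smooth_window = 3,
                       label_interval = 15, flag_threshold = 2,
                       unicode_minus = FALSE, seed = NA_integer_) {
  structure(
    list(calibration = calibration[c("slope", "intercept", "anchors")],
         bone_gl_threshold = bone_gl_threshold, ols_max_area = ols_max_area,
         low_cut = low_cut, high_cut = high_cut, bin_width = bin_width,
         smooth_window = smooth_window, label_interval = label_interval,
         flag_threshold = flag_threshold, unicode_minus = unicode_minus,
         seed = seed,
         package_version = as.character(utils::packageVersion("bonematrix"))),
    class = "run_config")
}

#' Serialize a run configuration to JSON
#'
#' @param config a [run_config()].
#' @return a JSON string (as produced by [jsonlite::toJSON()]).
#' @export
config_json <- function(config) {
  cfg <- unclass(config)
  cfg$calibration$anchors <- unname(split(cfg$calibration$anchors,
                                          row(cfg$calibration$anchors)))
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
}

fmt_num <- function(x, digits = 2, minus = "-") {
  out <- ifelse(is.na(x), "",
                formatC(round_half_away(x, digits), format = "f",
                        digits = digits))
  gsub("-", minus, out, fixed = TRUE)
}

#' Render a standardized report
#'
#' Writes the analysis results as machine-readable CSV plus a Markdown
#' report laid out like a clinical histomorphometry table: one row per
#' parameter with the measured value, the reference mean (SD) and the
#' standardized difference, parameters beyond the flag threshold set in
#' bold. When both cortical and trabecular BMDD results are present, a
#' compartment percent-difference block is appended; the report layer does
#' no arithmetic beyond rounding and those percent differences.
#'
#' @param zsets named list of [zscore_set()] objects (e.g.
#'   `list(histomorphometry = ..., bmdd_trabecular = ...)`); may be empty.
#' @param bmdd optional named list of [bmdd_parameters()] results by
#'   compartment (`cortical`, `trabecular`).
#' @param ols optional [ols_summary()].
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the paths written.
#' @export
render_report <- function(zsets = list(), bmdd = NULL, ols = NULL,
                          config = run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  minus <- if (isTRUE(config$unicode_minus)) "−" else "-"
  md <- c("# Bone tissue analysis report", "")

  if (length(zsets) == 0 && is.null(bmdd) && is.null(ols))
    md <- c(md, "_No analysis results supplied._", "")

  for (nm in names(zsets)) {
    zs <- zsets[[nm]]
    p <- file.path(out_dir, paste0("zscores_", nm, ".csv"))
    utils::write.csv(as.data.frame(zs), p, row.names = FALSE)
    paths <- c(paths, p)
    md <- c(md, paste0("## ", nm), "",
            "| Parameter | Value | Reference (SD) | Difference (SD) |",
            "|---|---|---|---|")
    for (i in seq_len(nrow(zs))) {
      z <- fmt_num(zs$z[i], 2, minus)
      if (zs$z[i] > 0) z <- paste0("+", z)
      if (zs$flag[i]) z <- paste0("**", z, "**")
      md <- c(md, sprintf("| %s | %s | %s (%s) | %s |",
                          zs$parameter[i], fmt_num(zs$value[i], 2, minus),
                          fmt_num(zs$ref_mean[i], 2, minus),
                          fmt_num(zs$ref_sd[i], 2, minus), z))
    }
    md <- c(md, "")
  }

  if (!is.null(bmdd)) {
    bt <- do.call(rbind, lapply(names(bmdd), function(nm)
      data.frame(compartment = nm, parameter = bmdd_par_names,
                 value = unname(as_bmdd_values(bmdd[[nm]])))))
    p <- file.path(out_dir, "bmdd_parameters.csv")
    utils::write.csv(bt, p, row.names = FALSE)
    paths <- c(paths, p)
    if (all(c("cortical", "trabecular") %in% names(bmdd))) {
      cmp <- compare_compartments(bmdd$cortical, bmdd$trabecular)
      p <- file.path(out_dir, "bmdd_compartment_differences.csv")
      utils::write.csv(cmp, p, row.names = FALSE)
      paths <- c(paths, p)
      md <- c(md, "## BMDD: cortical vs trabecular", "",
              "| Parameter | Cortical | Trabecular | Difference (%) |",
              "|---|---|---|---|",
              sprintf("| %s | %s | %s | %s%s |", cmp$parameter,
                      fmt_num(cmp$cortical, 2, minus),
                      fmt_num(cmp$trabecular, 2, minus),
                      ifelse(!is.na(cmp$pct_diff) & cmp$pct_diff > 0, "+", ""),
                      fmt_num(cmp$pct_diff, 1, minus)),
              "")
    }
  }

  if (!is.null(ols)) {
    os <- ols[c("n_lacunae", "ols_density", "mean_area", "mean_perimeter",
                "mean_aspect_ratio", "lacunar_porosity",
                "n_excluded_large", "n_excluded_border", "bone_area_mm2")]
    p <- file.path(out_dir, "ols_summary.csv")
    utils::write.csv(as.data.frame(os), p, row.names = FALSE)
    paths <- c(paths, p)
    md <- c(md, "## Osteocyte lacunae sections", "",
            sprintf("- lacunae: %d (density %s /mm^2 of bone area)",
                    os$n_lacunae, fmt_num(os$ols_density, 1, minus)),
            sprintf("- mean area %s um^2, mean aspect ratio %s",
                    fmt_num(os$mean_area, 1, minus),
                    fmt_num(os$mean_aspect_ratio, 2, minus)),
            sprintf("- lacunar porosity %s %% of bone area",
                    fmt_num(os$lacunar_porosity, 2, minus)),
            "")
  }

  md <- c(md, "## Run configuration", "", "```json",
          as.character(config_json(config)), "```", "")
  p <- file.path(out_dir, "report.md")
  writeLines(md, p)
  invisible(c(paths, p))
}
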