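test_that("identical seeds give bit-identical scenes, different seeds differ", {
  spec <- synthetic_spec(seed = 4, width_px = 200L, height_px = 200L)
  a <- generate_qbei(spec)
  b <- generate_qbei(spec)
  expect_identical(a, b)
  c <- generate_qbei(synthetic_spec(seed = 5, width_px = 200L,
                                    height_px = 200L))
  expect_false(identical(a$image, c$image))

  h1 <- generate_histo_scene(spec)
  h2 <- generate_histo_scene(spec)
  expect_identical(h1, h2)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_qbei(synthetic_spec(seed = 3, width_px = 120L,
                                         height_px = 120L)))
  expect_identical(.Random.seed, before)
})

test_that("a noiseless single-component field reproduces its mean calcium", {
  spec <- synthetic_spec(
    seed = 8, width_px = 400L, height_px = 400L, cortical_frac = 1,
    mineralization = list(cortical = list(weights = 1, means = 22.0, sds = 1.2),
                          trabecular = list(weights = 1, means = 20.7, sds = 2.1)),
    sensor = list(calibration = calibration_fit(), noise_gl_sd = 0,
                  background_gl = 10))
  sc <- generate_qbei(spec)
  p <- bmdd_parameters(ca_histogram(sc$image, spec$sensor$calibration))
  expect_equal(p$CaMean, 22.0, tolerance = 0.17 / 2 / 22)
  expect_equal(p$CaPeak, 22.0, tolerance = 0.2 / 22)
})

test_that("cortical bone measures more mineralized than trabecular", {
  spec <- synthetic_spec(seed = 6, width_px = 400L, height_px = 400L,
                         cortical_frac = 0.5)
  sc <- generate_qbei(spec)
  cal <- spec$sensor$calibration
  p_c <- bmdd_parameters(ca_histogram(sc$image, cal,
                                      mask = sc$compartments == 1L))
  p_t <- bmdd_parameters(ca_histogram(sc$image, cal,
                                      mask = sc$compartments == 2L))
  cmp <- compare_compartments(p_c, p_t)
  expect_gt(cmp$pct_diff[cmp$parameter == "CaMean"], 0)
})

test_that("mixture ground truth matches the single-Gaussian closed forms", {
  mu <- 20.63; sigma <- 2.06
  tr <- mixture_bmdd_truth(1, mu, sigma)
  expect_equal(unname(tr["CaMean"]), mu, tolerance = 1e-12)
  expect_equal(unname(tr["CaPeak"]), mu, tolerance = 0.003)
  expect_equal(unname(tr["CaWidth"]), 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.005 / 4.85)
  expect_equal(unname(tr["CaLow"]), 100 * pnorm(17.68, mu, sigma),
               tolerance = 1e-9)
  expect_equal(unname(tr["CaHigh"]), 100 * (1 - pnorm(25.30, mu, sigma)),
               tolerance = 1e-9)
})

test_that("measured CaWidth grows with the sensor noise level", {
  widths <- vapply(c(0, 2, 5), function(ns) {
    spec <- synthetic_spec(
      seed = 10, width_px = 300L, height_px = 300L, cortical_frac = 1,
      sensor = list(calibration = calibration_fit(), noise_gl_sd = ns,
                    background_gl = 10))
    sc <- generate_qbei(spec)
    bmdd_parameters(ca_histogram(sc$image, spec$sensor$calibration))$CaWidth
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("gray images and class rasters round-trip bit-exactly", {
  spec <- synthetic_spec(seed = 2, width_px = 96L, height_px = 80L)
  sc <- generate_qbei(spec)
  for (ext in c(".tif", ".png")) {
    path <- withr::local_tempfile(fileext = ext)
    write_gray_image(sc$image, path)
    expect_identical(read_gray_image(path), sc$image)
  }

  hs <- generate_histo_scene(spec)
  rp <- withr::local_tempfile(fileext = ".png")
  write_class_raster(hs$raster, rp)
  back <- read_class_raster(rp)
  expect_identical(back$classes, hs$raster$classes)
  expect_equal(back$pixel_size, hs$raster$pixel_size)

  ap <- withr::local_tempfile(fileext = ".json")
  write_annotation(hs$annotation, ap)
  ann2 <- read_annotation(ap)
  prim1 <- measure_primitives(hs$raster, hs$annotation)
  prim2 <- measure_primitives(back, ann2)
  expect_equal(unclass(prim2), unclass(prim1), tolerance = 1e-9)
})

test_that("the histo scene's planted primitives are recovered exactly", {
  sc <- generate_histo_scene(synthetic_spec(seed = 7))
  prim <- measure_primitives(sc$raster, sc$annotation)
  tr <- sc$truth$primitives
  for (f in c("tv", "bv", "bs", "ov", "os", "ob_s", "es", "oc_s",
              "dl_pm", "sl_pm", "ir_l_wi"))
    expect_equal(prim[[f]], tr[[f]], tolerance = 1e-9, label = f)
  p <- histo_parameters(prim, o_th = tr$o_th_direct)
  expect_equal(unclass(p), unclass(sc$truth$params), tolerance = 1e-9)
})

test_that("an all-quiescent scene yields zero turnover and flagged Mlt", {
  spec <- synthetic_spec(seed = 9)
  spec$histo$os_fraction <- 0; spec$histo$ob_fraction <- 0
  spec$histo$eroded_fraction <- 0; spec$histo$oc_fraction <- 0
  spec$histo$dl_fraction <- 0; spec$histo$sl_fraction <- 0
  sc <- generate_histo_scene(spec)
  d <- dynamic_parameters(sc$truth$primitives)
  expect_equal(d[["MS/BS"]], 0)
  expect_equal(d[["BFR/BS"]], 0)
  expect_true(is.na(d[["Mlt"]]))
  expect_true("Mlt" %in% attr(d, "flags"))
})

test_that("the planted mineral apposition rate is measured back", {
  spec <- synthetic_spec(seed = 12)
  sc <- generate_histo_scene(spec)
  prim <- measure_primitives(sc$raster, sc$annotation)
  d <- dynamic_parameters(prim)
  expect_equal(d[["MAR"]], spec$histo$mar_um_day, tolerance = 1e-9)
})

test_that("impossible packings and geometries fail loudly", {
  dense <- synthetic_spec(seed = 1, width_px = 100L, height_px = 100L,
                          cortical_frac = 1)
  dense$lacunae$density_per_mm2 <- 2e5
  expect_error(generate_qbei(dense), class = "bm_packing_error")

  bad <- synthetic_spec(seed = 1)
  bad$histo$o_th_um <- bad$histo$strut_th_um
  expect_error(generate_histo_scene(bad), class = "bm_geometry_error")

  expect_error(synthetic_spec(bvtv = 0), class = "bm_domain_error")
  expect_error(
    synthetic_spec(mineralization = list(
      cortical = list(weights = c(0.5, 0.4), means = c(20, 23), sds = c(1, 1)),
      trabecular = list(weights = 1, means = 20.7, sds = 2.1))),
    class = "bm_domain_error")
})

test_that("YAML specs override defaults field by field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 77",
               "width_px: 128",
               "lacunae:",
               "  density_per_mm2: 90",
               "histo:",
               "  mar_um_day: 0.9"), path)
  spec <- read_synthetic_spec(path)
  expect_equal(spec$seed, 77L)
  expect_equal(spec$width_px, 128L)
  expect_equal(spec$lacunae$density_per_mm2, 90)
  expect_equal(spec$lacunae$area_cap_um2, 180)      # untouched default
  expect_equal(spec$histo$mar_um_day, 0.9)
  expect_equal(spec$histo$strut_th_um, 140)         # untouched default
})
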