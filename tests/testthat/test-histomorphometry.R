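make_strut_scene <- function(nr = 100, nc = 100, ps = 10, top = 41,
                             th = 20, seam_px = 0) {
  cls <- matrix(0L, nr, nc)
  cls[top:(top + th - 1L), ] <- 1L
  if (seam_px > 0) cls[top:(top + seam_px - 1L), ] <- 2L
  y_top <- (top - 1L) * ps
  y_bot <- (top + th - 1L) * ps
  list(cls = cls, y_top = y_top, y_bot = y_bot, width_um = nc * ps)
}

test_that("areas come from pixel counting, surfaces from arc length", {
  sc <- make_strut_scene(th = 40)  # 100x100 px at 10 um/px, 40 rows bone
  ann <- surface_annotation(list(
    list(coords = matrix(c(0, sc$y_top, sc$width_um, sc$y_top), 2, byrow = TRUE),
         state = "QUIESCENT"),
    list(coords = matrix(c(0, sc$y_bot, sc$width_um, sc$y_bot), 2, byrow = TRUE),
         state = "QUIESCENT")))
  prim <- measure_primitives(class_raster(sc$cls, 10), ann)
  expect_equal(prim$bv, 0.4 * prim$tv)          # 40% mineralized
  expect_equal(prim$tv, 1)                      # 1 mm x 1 mm field
  expect_equal(prim$bs, 2)                      # two 1-mm edges
})

test_that("osteoid seam width is recovered via OV/OS", {
  sc <- make_strut_scene(seam_px = 5)           # 5 px seam at 10 um/px
  ann <- surface_annotation(list(
    list(coords = matrix(c(0, sc$y_top, sc$width_um, sc$y_top), 2, byrow = TRUE),
         state = "OSTEOID"),
    list(coords = matrix(c(0, sc$y_bot, sc$width_um, sc$y_bot), 2, byrow = TRUE),
         state = "QUIESCENT")))
  prim <- measure_primitives(class_raster(sc$cls, 10), ann)
  o_th <- 1000 * prim$ov / prim$os
  expect_equal(o_th, 50, tolerance = 10 / 50)   # within one pixel
  p <- static_parameters(prim)
  expect_equal(p[["OS/BS"]], 50)                # one of two edges osteoid
})

test_that("surface polylines far from the bone boundary are rejected", {
  sc <- make_strut_scene()
  off <- sc$y_top - 50                          # 5 px off the boundary
  ann <- surface_annotation(list(
    list(coords = matrix(c(0, off, sc$width_um, off), 2, byrow = TRUE),
         state = "QUIESCENT")))
  expect_error(measure_primitives(class_raster(sc$cls, 10), ann),
               class = "bm_alignment_error")
})

test_that("static parameters follow the ASBMR definitions", {
  prim <- histo_primitives(tv = 2.5, bv = 0.2219 * 2.5, bs = 6,
                           ov = 0.01, os = 3)
  p <- static_parameters(prim)
  expect_equal(p[["BV/TV"]], 22.19)
  expect_equal(p[["OS/BS"]], 50)
  expect_equal(p[["Tb.Th"]], 2000 * prim$bv / prim$bs)
  expect_equal(p[["Tb.N"]], (p[["BV/TV"]] / 100) / p[["Tb.Th"]] * 1000)
  # OS = BS saturates the ratio at 100%
  p2 <- static_parameters(histo_primitives(tv = 1, bv = 0.3, bs = 4, os = 4))
  expect_equal(p2[["OS/BS"]], 100)
  # zero denominators flag rather than error
  p3 <- static_parameters(histo_primitives(tv = 0, bv = 0, bs = 0))
  expect_true(all(c("BV/TV", "OS/BS") %in% attr(p3, "flags")))
})

test_that("plate-model thickness recovers a planted plate phantom", {
  spec <- synthetic_spec(seed = 2)
  sc <- generate_histo_scene(spec)
  prim <- measure_primitives(sc$raster, sc$annotation)
  p <- static_parameters(prim)
  expect_equal(p[["Tb.Th"]], 140, tolerance = 0.05)
  # planted osteoid surface fraction is recovered closely
  expect_equal(p[["OS/BS"]], 100 * spec$histo$os_fraction, tolerance = 1.5 / 35)
})

test_that("the dynamic chain reproduces the worked-example arithmetic", {
  # patient 1: MAR 0.7 um/day, MS/BS 3.8%, OS/BS 50.33% -> Aj.Ar 0.053
  prim <- histo_primitives(tv = 1, bv = 0.25, bs = 100, os = 50.33,
                           o_th_direct = 4.1, dl_pm = 3.8, sl_pm = 0,
                           ir_l_wi = 0.7 * 15, label_interval = 15)
  d <- dynamic_parameters(prim)
  expect_equal(d[["MAR"]], 0.7)
  expect_equal(d[["MS/BS"]], 3.8)
  expect_equal(round_half_away(d[["Aj.Ar"]], 3), 0.053)
  expect_equal(round_half_away(d[["BFR/BS"]], 2), 9.71)  # 0.7*0.038*365
  # patient 2: O.Th 4.22, Aj.Ar 0.0865 -> Mlt 48.8
  expect_equal(round_half_away(4.22 / 0.0865, 1), 48.8)
})

test_that("lag time and formation rate identities hold exactly pre-rounding", {
  set.seed(31)
  for (i in 1:20) {
    bs <- runif(1, 50, 150)
    os <- runif(1, 1, bs)
    dl <- runif(1, 0, bs / 2); sl <- runif(1, 0, bs / 2)
    prim <- histo_primitives(tv = 1, bv = runif(1, 0.1, 0.5), bs = bs,
                             os = os, o_th_direct = runif(1, 2, 12),
                             dl_pm = dl, sl_pm = sl,
                             ir_l_wi = runif(1, 5, 20),
                             label_interval = 15)
    d <- dynamic_parameters(prim)
    expect_equal(d[["Mlt"]] * d[["Aj.Ar"]], prim$o_th_direct,
                 tolerance = 1e-12)
    expect_equal(d[["BFR/BS"]], d[["MAR"]] * (d[["MS/BS"]] / 100) * 365,
                 tolerance = 1e-12)
  }
})

test_that("single labels count half in the mineralizing surface", {
  base <- list(tv = 1, bv = 0.3, bs = 10, os = 5, o_th_direct = 6,
               ir_l_wi = 10.5, label_interval = 15)
  all_double <- dynamic_parameters(do.call(histo_primitives,
    c(base, list(dl_pm = 2, sl_pm = 0))))
  all_single <- dynamic_parameters(do.call(histo_primitives,
    c(base, list(dl_pm = 0, sl_pm = 2))))
  expect_equal(all_double[["MS/BS"]], 100 * 2 / 10)
  expect_equal(all_single[["MS/BS"]], all_double[["MS/BS"]] / 2)
})

test_that("inconsistent or degenerate dynamic inputs are handled", {
  expect_error(
    dynamic_parameters(histo_primitives(tv = 1, bv = 0.3, bs = 10, os = 0,
                                        dl_pm = 2, ir_l_wi = 10)),
    class = "bm_inconsistency")
  # quiescent surface: MS/BS = 0 and Mlt undefined, flagged
  d <- dynamic_parameters(histo_primitives(tv = 1, bv = 0.3, bs = 10,
                                           os = 2, ov = 0.01))
  expect_equal(d[["MS/BS"]], 0)
  expect_true(is.na(d[["Mlt"]]))
  expect_true("Mlt" %in% attr(d, "flags"))
})

test_that("Z-score table matches age- and sex-specific references", {
  ref <- bonematrix_data("histo_reference")
  zs <- zscore_table(c("OS/BS" = 50.33), ref, sex = "M", age = 61)
  expect_equal(zs$z, 9.03)
  expect_true(zs$flag)
  zs2 <- zscore_table(c("ES/BS" = 16.25), ref, sex = "M", age = 29)
  expect_equal(zs2$z, 10.46)
  # value at the reference mean scores 0 and is unflagged
  zs0 <- zscore_table(c("BV/TV" = 19.2), ref, sex = "M", age = 65)
  expect_equal(zs0$z, 0)
  expect_false(zs0$flag)
  # parameters without a reference row are skipped, not errors
  zsk <- zscore_table(c("Ct.Po" = 4.46, "BV/TV" = 22.19), ref, "M", 61)
  expect_equal(zsk$parameter, "BV/TV")
  expect_true("Ct.Po" %in% attr(zsk, "skipped"))
  err <- tryCatch(zscore_table(c("BV/TV" = 22), ref, "M", 45),
                  error = function(e) e)
  expect_s3_class(err, "bm_missing_reference")
  expect_match(conditionMessage(err), "61-70")
})

test_that("standardization is affine-equivariant", {
  set.seed(12)
  x <- runif(1); mu <- runif(1); sd <- runif(1, 0.5, 2); a <- 7.3
  z1 <- zscore_set("p", x, mu, sd)$z
  z2 <- zscore_set("p", a * x, a * mu, a * sd)$z
  expect_equal(z1, z2)
})

test_that("primitives import from CSV bypasses image measurement", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(tv = 1, bv = 0.25, bs = 100, os = 50.33, ov = 0.02,
                       o_th_direct = 4.1, dl_pm = 3.8, sl_pm = 0,
                       ir_l_wi = 10.5, label_interval = 15),
            path, row.names = FALSE)
  prim <- read_primitives_csv(path)
  expect_s3_class(prim, "histo_primitives")
  expect_equal(round_half_away(dynamic_parameters(prim)[["Aj.Ar"]], 3), 0.053)
})
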