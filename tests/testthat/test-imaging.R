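# Radiometric calibration, ExG masking, ROI extraction, GSD geometry.

test_that("panel calibration implements the gain definition", {
  raw <- array(1000, c(3, 3, 5))
  pan <- panel_observation(mean_dn = rep(1000, 5))
  sc <- calibrate_reflectance(raw, pan)
  expect_true(all(sc$bands == 0.5))
  sc2 <- calibrate_reflectance(raw * 2, pan)
  expect_true(all(sc2$bands == 1.0))
  # identity panel leaves an already-calibrated scene unchanged
  refl <- array(runif(3 * 3 * 5, 0, 1), c(3, 3, 5))
  ident <- panel_observation(mean_dn = rep(1, 5), nominal = rep(1, 5))
  expect_equal(calibrate_reflectance(refl, ident)$bands, refl,
               ignore_attr = TRUE)
  expect_error(panel_observation(mean_dn = c(0, 1, 1, 1, 1)), "positive")
})

test_that("calibration is scale-equivariant and clips with a record", {
  raw <- array(runif(4 * 4 * 5, 100, 4000), c(4, 4, 5))
  pan <- panel_observation(mean_dn = c(2000, 2100, 1900, 2050, 1980))
  a <- calibrate_reflectance(raw, pan)
  b <- calibrate_reflectance(
    raw * 3.7, panel_observation(mean_dn = pan$mean_dn * 3.7))
  expect_equal(a$bands, b$bands, ignore_attr = TRUE, tolerance = 1e-12)
  hot <- calibrate_reflectance(array(1e6, c(2, 2, 5)), pan)
  expect_true(all(hot$bands == 1.5))
  expect_gt(attr(hot$bands, "clipped"), 0)
})

test_that("ExG matches its band-math definition", {
  grey <- scene_raster(array(0.3, c(2, 2, 5)))
  expect_true(all(compute_exg(grey) == 0))
  bands <- array(0, c(1, 1, 5), dimnames = list(NULL, NULL, c("B", "G", "R", "RE", "NIR")))
  bands[1, 1, "G"] <- 0.5
  expect_equal(compute_exg(scene_raster(bands))[1, 1], 1.0)
})

test_that("ExG thresholding recovers the generator's vegetation mask", {
  sc <- default_scene()
  m <- vegetation_mask(compute_exg(sc), threshold = 0.07)
  expect_gte(mask_f1(m, sc$mask_vegetation), 0.95)
  expect_identical(attr(m, "provenance"), "exg_refined")
  # degenerate threshold keeps every valid pixel
  all_m <- vegetation_mask(compute_exg(sc), threshold = -Inf)
  expect_true(all(all_m))
  # soil-only scene gives an empty mask, with a warning not an error
  soil <- render_scene(soil_layout(), data.frame(), seed = 2)
  expect_warning(m0 <- vegetation_mask(compute_exg(soil)), "empty")
  expect_false(any(m0))
  # manual ROI intersection flips provenance
  roi <- matrix(FALSE, nrow(m), ncol(m))
  roi[1:50, 1:50] <- TRUE
  mm <- vegetation_mask(compute_exg(sc), roi = roi)
  expect_identical(attr(mm, "provenance"), "manual_polygon")
  expect_true(all(which(mm) %in% which(roi)))
})

test_that("ROI extraction averages bands and ignores layout order", {
  const <- scene_raster(array(0.42, c(4, 4, 5)))
  mask <- matrix(TRUE, 4, 4)
  expect_true(all(extract_reflectance(const, mask) == 0.42))
  bands <- array(0, c(2, 1, 5))
  bands[1, 1, ] <- 0.2
  bands[2, 1, ] <- 0.4
  sc <- scene_raster(bands)
  expect_equal(unname(extract_reflectance(sc, matrix(TRUE, 2, 1))),
               rep(0.3, 5))
  expect_error(extract_reflectance(sc, matrix(FALSE, 2, 1)), "no valid")
  # permutation invariance: shuffling pixels leaves ROI means unchanged
  big <- default_scene()
  H <- dim(big)[1]
  W <- dim(big)[2]
  perm <- local({
    set.seed(4)
    sample(H * W)
  })
  shuffled <- big$bands
  for (b in 1:5) shuffled[, , b] <- matrix(big$bands[, , b][perm], H, W)
  pmask <- matrix(big$mask_vegetation[perm], H, W)
  expect_equal(extract_reflectance(scene_raster(shuffled), pmask),
               extract_reflectance(big, big$mask_vegetation))
})

test_that("shadow-free ROI means track the generator's canopy spectrum", {
  truth <- default_truth()
  lay <- default_layout()
  sc0 <- render_scene(lay, truth, seed = 7,
                      params = scene_params(shadow_fraction = 0))
  i <- 1
  roi <- sc0$labels == i
  mu <- extract_reflectance(sc0, roi)
  expected <- canopy_reflectance(truth$cab[i], truth$lai[i])[1, ]
  expect_true(all(abs(mu / expected - 1) <= 0.05))
})

test_that("band-neutral shadow leaves ROI band ratios unchanged", {
  sc <- default_scene()
  sunlit <- extract_reflectance(sc, sc$mask_vegetation)
  withsh <- extract_reflectance(sc, sc$mask_canopy)
  for (pair in list(c("G", "R"), c("NIR", "RE"), c("NIR", "R"))) {
    expect_equal(withsh[[pair[1]]] / withsh[[pair[2]]],
                 sunlit[[pair[1]]] / sunlit[[pair[2]]],
                 tolerance = 0.02)
  }
})

test_that("GSD follows the pinhole geometry", {
  gsd <- gsd_from_geometry(30, 3.75e-6, 5.4e-3)
  expect_equal(round(gsd * 100), 2)           # 2 cm at the survey altitude
  expect_equal(gsd, 30 * 3.75e-6 / 5.4e-3)
  expect_equal(gsd_from_geometry(60, 3.75e-6, 5.4e-3), 2 * gsd)
  expect_equal(gsd_from_geometry(30, 1e-3, 1e-3), 30)
  expect_error(gsd_from_geometry(-30, 3.75e-6, 5.4e-3), "positive")
})

test_that("scene TIFF round trip preserves reflectance and gsd", {
  skip_if_not_installed("tiff")
  sc <- default_scene()
  tf <- tempfile(fileext = ".tif")
  write_scene_tiff(sc, tf)
  back <- read_scene_tiff(tf)
  expect_equal(back$gsd, sc$gsd)
  expect_equal(back$bands, sc$bands, ignore_attr = TRUE, tolerance = 1e-6)
})
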