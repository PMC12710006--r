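# Per-pixel trait mapping and per-plot summaries.

uniform_veg_scene <- function(h = 6, w = 6,
                              bands = c(B = 0.05, G = 0.15, R = 0.06,
                                        RE = 0.25, NIR = 0.40)) {
  arr <- array(rep(bands, each = h * w), c(h, w, 5),
               dimnames = list(NULL, NULL, names(bands)))
  scene_raster(arr)
}

test_that("a constant-reflectance canopy maps to the scalar prediction", {
  sc <- uniform_veg_scene()
  m <- univariate_fit(c(0.1, 0.2, 0.3, 0.4), c(40, 60, 80, 100),
                      index_name = "NDRE")
  tmap <- map_traits(sc, m, trait = "vcmax25")
  bands <- sc$bands[1, 1, ]
  expected <- predict(m, compute_index("NDRE", bands))
  vals <- tmap$values[!tmap$nodata]
  expect_gt(length(vals), 0)
  expect_true(all(abs(vals - expected) < 1e-12))
  expect_equal(tmap$stats$mean, expected)
})

test_that("an all-soil scene yields a fully masked map", {
  soil <- render_scene(soil_layout(), data.frame(), seed = 2)
  m <- univariate_fit(c(0.1, 0.2, 0.3), c(1, 2, 3), index_name = "NDVI")
  tmap <- map_traits(soil, m)
  expect_true(all(tmap$nodata))
  expect_identical(tmap$stats$n_valid, 0L)
})

test_that("mapping a model needing an unregistered index is rejected", {
  sc <- uniform_veg_scene()
  m <- univariate_fit(c(0.1, 0.2, 0.3), c(1, 2, 3), index_name = "WI")
  expect_error(map_traits(sc, m), "unregistered")
})

test_that("the map mask is a superset of the scene nodata mask", {
  sc <- default_scene()
  sc$nodata[1:10, 1:10] <- TRUE
  m <- univariate_fit(c(0.1, 0.2, 0.3, 0.5), c(30, 50, 70, 110),
                      index_name = "CI_RE")
  tmap <- map_traits(sc, m)
  expect_gte(sum(tmap$nodata), sum(sc$nodata))
  expect_true(all(tmap$nodata[sc$nodata]))
})

test_that("pixel-level and tabular predictions coincide on a uniform ROI", {
  sc <- uniform_veg_scene()
  mask <- matrix(TRUE, dim(sc)[1], dim(sc)[2])
  mu <- extract_reflectance(sc, mask)
  X <- compute_indices(mu)[, c("NDRE", "CVI"), drop = FALSE]
  pm <- fit_plsr(rbind(X + 0.01, X - 0.01, X + 0.02, X - 0.02),
                 c(51, 49, 52, 48), ncomp = 1, trait = "vcmax25")
  tabular <- unname(predict(pm, X))
  tmap <- map_traits(sc, pm)
  expect_equal(unname(tmap$stats$mean), tabular, tolerance = 1e-10)
})

test_that("plot summaries report each rectangle and keep empty plots", {
  lay <- soil_layout()
  lay$plots <- data.frame(plot_id = c("p1", "p2"), treatment = c("N0", "N4"),
                          r0 = c(1, 1), c0 = c(1, 21), r1 = c(10, 10),
                          c1 = c(10, 30))
  vals <- matrix(NA_real_, 40, 40)
  vals[1:10, 1:10] <- 55
  vals[1:10, 21:30] <- 80
  tmap <- structure(list(values = vals, nodata = is.na(vals),
                         trait = "vcmax25"), class = "trait_map")
  ps <- plot_summary(tmap, lay)
  expect_equal(ps$mean, c(55, 80))
  expect_equal(ps$min, c(55, 80))
  lay$plots <- rbind(lay$plots,
                     data.frame(plot_id = "empty", treatment = "N2",
                                r0 = 31, c0 = 31, r1 = 40, c1 = 40))
  ps2 <- plot_summary(tmap, lay)
  expect_true(is.na(ps2$mean[3]))
  expect_identical(ps2$n_valid[3], 0L)
})

test_that("mapped plot means rank with the underlying nitrogen truth", {
  truth <- default_truth()
  lay <- default_layout()
  sc <- default_scene()
  cfg <- pipeline_config()
  # train on tabular samples, then check the spatial product
  samples <- fixture("samples",
                     extract_trait_samples(truth, lay, sc, cfg))
  idx <- intersect(index_registry(include_stubs = FALSE)$name,
                   colnames(samples))
  tm <- fit_trait_model(samples[, idx], samples$vcmax25, seed = 1,
                        trait = "vcmax25")
  tmap <- map_traits(sc, tm)
  ps <- plot_summary(tmap, lay)
  truth_means <- tapply(truth$vcmax25, truth$plot_id, mean)
  rho <- cor(ps$mean, truth_means[as.character(ps$plot_id)],
             method = "spearman")
  expect_gte(rho, 0.8)
  # higher-nitrogen plots map to higher Vcmax on average
  hi <- mean(ps$mean[ps$treatment == "N4"])
  lo <- mean(ps$mean[ps$treatment == "N0"])
  expect_gt(hi, lo)
})

test_that("trait maps survive the TIFF encoding round trip", {
  skip_if_not_installed("tiff")
  sc <- uniform_veg_scene(4, 4)
  m <- univariate_fit(c(0.1, 0.2, 0.3), c(20, 60, 100), index_name = "NDRE")
  tmap <- map_traits(sc, m, trait = "vcmax25")
  tf <- tempfile(fileext = ".tif")
  write_trait_map(tmap, tf)
  expect_true(file.exists(tf))
  expect_true(file.exists(sub("\\.tif$", ".json", tf)))
  enc <- tiff::readTIFF(tf)
  meta <- jsonlite::fromJSON(sub("\\.tif$", ".json", tf))
  back <- meta$offset + (enc - 0.5) / 0.5 * meta$span
  vals <- tmap$values[!tmap$nodata]
  expect_equal(unique(round(back[enc > 0], 4)),
               unique(round(vals, 4)))
})
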