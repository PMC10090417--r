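test_that("calibration fit recovers a two-point line and flags degeneracy", {
  m <- fit_calibration(c(20, 850), c(0.02, 0.85))
  expect_equal(m$slope, 0.001)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_error(fit_calibration(c(0, 100), c(0.05, 0.05)), "slope")
  expect_error(fit_calibration(c(100, 100), c(0.05, 0.9)), "identical DN")
  # exactly collinear panels give r2 = 1
  dn <- c(10, 100, 300, 600, 850)
  m5 <- fit_calibration(dn, dn * 0.001 + 0.002)
  expect_equal(m5$r2, 1.0)
})

test_that("calibration application follows SR = DN x slope + intercept with clipping", {
  m <- list(slope = 0.001, intercept = 0)
  expect_equal(apply_calibration(0, m), 0)
  expect_equal(apply_calibration(500, m), 0.5)
  m2 <- list(slope = 0.001, intercept = -0.05)
  expect_equal(apply_calibration(10, m2), 0)  # negative pre-clip
})

test_that("calibration round trip is exact", {
  set.seed(9)
  slope <- 0.0008; intercept <- 0.013
  sr <- runif(50, 0.02, 0.9)
  dn <- (sr - intercept) / slope
  m <- fit_calibration(dn[1:5], sr[1:5])
  expect_lt(max(abs(apply_calibration(dn, m) - sr)), 1e-10)
})

test_that("2019 NIR derivation applies the printed coefficients", {
  expect_equal(derive_nir_2019(0, 0), 0)
  expect_equal(derive_nir_2019(0.10, 0.05), 0.2544)
  expect_equal(derive_nir_2019(0.10, 0.05, normalize = TRUE), 0.2544 / 3.07)
  expect_equal(derive_nir_2019(0.01, 0.5), 0)  # floored
})

test_that("indices match hand arithmetic and stay in [-1, 1]", {
  bands <- c(Blue = 0.05, Green = 0.1, Red = 0.1, RE1 = 0.2, RE2 = 0.3,
             B900 = 0.4, B975 = 0.4, NIR = 0.5)
  f <- compute_indices(bands)
  expect_equal(unname(f$H[["NDVI"]]), (0.5 - 0.1) / (0.5 + 0.1))
  expect_equal(unname(f$H[["NDRE1"]]), (0.5 - 0.2) / (0.5 + 0.2))
  # R800 = R680 -> NDVI = 0
  b0 <- replace(bands, c("NIR", "Red"), c(0.3, 0.3))
  expect_equal(unname(compute_indices(b0)$H[["NDVI"]]), 0)
  # R800 = 0.5, R680 = 0.1 -> 0.6667; R800 = 0.6, R700 = 0.2 -> 0.5
  b1 <- replace(bands, c("NIR", "Red"), c(0.5, 0.1))
  expect_equal(unname(compute_indices(b1)$H[["NDVI"]]), 0.4 / 0.6)
  b2 <- replace(bands, c("NIR", "RE1"), c(0.6, 0.2))
  expect_equal(unname(compute_indices(b2)$H[["NDRE1"]]), 0.5)
  # canopy cover is the mean pixel GNDVI: pixels with GNDVI {0.2, 0.4} -> 0.3
  px <- rbind(bands, bands)
  px[, "Green"] <- c(0.5 * (1 - 0.2) / (1 + 0.2), 0.5 * (1 - 0.4) / (1 + 0.4))
  f2 <- compute_indices(bands, px)
  expect_equal(unname(f2$H[["CanopyCover"]]), 0.3)
  # thresholded variant counts pixels above the cutoff
  f3 <- compute_indices(bands, px, canopy = "threshold", threshold = 0.3)
  expect_equal(unname(f3$H[["CanopyCover"]]), 0.5)
  # normalized differences bounded for positive reflectance
  set.seed(2)
  for (i in 1:20) {
    bb <- setNames(runif(8, 0.01, 1.1), names(bands))
    h <- compute_indices(bb)$H
    expect_true(all(abs(h[c("NDVI", "NDRE1")]) <= 1))
  }
  bz <- replace(bands, c("NIR", "Red"), c(0, 0))
  expect_error(compute_indices(bz), "zero")
})

test_that("I is the stated sub-vector of H", {
  set.seed(6)
  bands <- setNames(runif(8, 0.05, 0.9), c("Blue", "Green", "Red", "RE1",
                                           "RE2", "B900", "B975", "NIR"))
  f <- compute_indices(bands)
  expect_identical(names(f$I), c("CanopyCover", "NDRE1", "NDVI"))
  expect_identical(unname(f$I), unname(f$H[names(f$I)]))
})

test_that("pixel aggregation is a per-plot mean, invariant to row order", {
  px <- data.frame(plot_id = c("p1", "p2", "p2"),
                   Blue = c(0.1, 0.2, 0.4), Green = c(0.2, 0.1, 0.3),
                   Red = 0.1, RE1 = 0.2, RE2 = 0.3, B900 = 0.4,
                   B975 = 0.4, NIR = c(0.5, 0.2, 0.4))
  ag <- aggregate_pixels(px)
  expect_equal(ag$Blue[ag$plot_id == "p1"], 0.1)   # single pixel
  expect_equal(ag$Blue[ag$plot_id == "p2"], 0.3)   # mean of {0.2, 0.4}
  expect_equal(ag$n_pixels, c(1L, 2L))
  ag2 <- aggregate_pixels(px[c(3, 1, 2), ])
  expect_equal(ag, ag2)
})

test_that("the feature table carries one row per cell with 11 H columns", {
  b <- generate_dataset(sim_config(n_lines = 40, n_snps = 60, n_envs = 2,
                                   seed = 12))
  f <- build_spectral_features(b$pixel_table, b$panel_table, b$plot_table)
  cells <- unique(b$plot_table[, c("line", "env")])
  expect_equal(nrow(f), nrow(cells))
  expect_true(all(c("Blue", "Green", "Red", "RE1", "RE2", "B900", "B975",
                    "NIR", "NDRE1", "NDVI", "CanopyCover") %in% names(f)))
  # calibration inverts the DN encoding: recovered reflectance plausible
  expect_true(all(f$NIR > 0 & f$NIR < 1.2))
})

test_that("single2019 mode derives NIR from calibrated blue and red", {
  b <- generate_dataset(sim_config(n_lines = 30, n_snps = 40, n_envs = 2,
                                   seed = 13))
  f <- build_spectral_features(b$pixel_table, b$panel_table, b$plot_table,
                               mode = "single2019")
  fp <- build_spectral_features(b$pixel_table, b$panel_table, b$plot_table,
                                mode = "panel")
  expect_equal(f$Blue, fp$Blue, tolerance = 1e-8)
  expect_equal(f$NIR,
               pmax(2.921 * f$Blue - 0.754 * f$Red, 0) / 3.07,
               tolerance = 1e-6)
})
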