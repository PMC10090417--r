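test_that("impossible configurations are rejected with a message", {
  expect_error(sim_config(n_envs = 2, mean_envs_per_line = 3),
               "mean_envs_per_line")
  expect_error(sim_config(h2_target = 0), "h2_target")
  expect_error(sim_config(h2_target = 0.3, var_ge = 5), "var_ge too large")
})

test_that("single environment forces zero realized G-by-E spread", {
  b <- generate_dataset(sim_config(n_lines = 60, n_snps = 100, n_envs = 1,
                                   mean_envs_per_line = 1, var_ge = 0.3,
                                   seed = 2))
  # every cell draws a gE value, but with one environment the line's total
  # value has no environment-specific component to vary across
  expect_equal(length(unique(b$plot_table$env)), 1L)
  ge_by_line <- tapply(b$truth$cells$ge, b$truth$cells$line,
                       function(v) diff(range(v)))
  expect_true(all(ge_by_line == 0))
})

test_that("realized plot-level heritability matches the target", {
  b <- generate_dataset(sim_config(n_lines = 400, n_snps = 1000,
                                   h2_target = 0.5, seed = 1))
  expect_lt(abs(b$truth$realized$h2 - 0.5), 0.05)
})

test_that("identical config and seed give byte-identical bundles", {
  cf <- sim_config(n_lines = 50, n_snps = 80, n_envs = 3, seed = 99)
  b1 <- generate_dataset(cf)
  b2 <- generate_dataset(cf)
  expect_identical(b1, b2)
})

test_that("bundle is self-consistent: plot lines exist in markers and every line is grown", {
  b <- generate_dataset(sim_config(n_lines = 80, n_snps = 120, n_envs = 4,
                                   seed = 5))
  expect_true(all(b$plot_table$line %in% rownames(b$markers)))
  expect_true(all(rownames(b$markers) %in% b$plot_table$line))
  expect_true(all(table(unique(b$plot_table[, c("line", "env")])$line) >= 1))
})

test_that("realized unbalance matches hand counts", {
  # fully balanced single-rep case
  pt <- expand.grid(line = c("A", "B"), env = c("E1", "E2", "E3"),
                    stringsAsFactors = FALSE)
  expect_equal(unbalance_summary(pt), list(n_e = 3, n_r = 1))
  # line A in 2 envs, line B in 1 env -> n_e = 1.5
  pt2 <- data.frame(line = c("A", "A", "B"), env = c("E1", "E2", "E1"))
  expect_equal(unbalance_summary(pt2)$n_e, 1.5)
  # 3 cells with replicate counts {1, 1, 2} -> n_r = 4/3
  pt3 <- data.frame(line = c("A", "B", "C", "C"),
                    env = rep("E1", 4))
  expect_equal(unbalance_summary(pt3)$n_r, 4 / 3)
})

test_that("mean realized heritability is calibrated over seeds", {
  h2s <- vapply(1:20, function(s) {
    generate_dataset(sim_config(n_lines = 150, n_snps = 200,
                                h2_target = 0.6, seed = s))$truth$realized$h2
  }, 0)
  expect_lt(abs(mean(h2s) - 0.6), 0.03)
})

test_that("spectral_signal controls the band-to-genetics correlation", {
  b0 <- generate_dataset(sim_config(n_lines = 300, n_snps = 200,
                                    spectral_signal = 0, seed = 31))
  b1 <- generate_dataset(sim_config(n_lines = 300, n_snps = 200,
                                    spectral_signal = 1, seed = 31))
  feats0 <- build_spectral_features(b0$pixel_table, b0$panel_table,
                                    b0$plot_table)
  feats1 <- build_spectral_features(b1$pixel_table, b1$panel_table,
                                    b1$plot_table)
  nir_line0 <- tapply(feats0$NIR, feats0$line, mean)
  nir_line1 <- tapply(feats1$NIR, feats1$line, mean)
  g0 <- b0$truth$g[names(nir_line0)]
  g1 <- b1$truth$g[names(nir_line1)]
  expect_lt(abs(cor(nir_line0, g0)), 2 / sqrt(300) + 0.05)
  # within one environment (removing env main effects) the s = 1 band is an
  # affine function of g + gE plus only small pixel noise
  e1 <- feats1[feats1$env == feats1$env[1], ]
  tot1 <- b1$truth$g[e1$line] +
    b1$truth$cells$ge[match(paste(e1$line, e1$env),
                            paste(b1$truth$cells$line, b1$truth$cells$env))]
  expect_gt(abs(cor(e1$NIR, tot1)), 0.95)
})

test_that("bundle round-trips through the CSV writers", {
  b <- generate_dataset(sim_config(n_lines = 30, n_snps = 40, n_envs = 2,
                                   seed = 8))
  d <- tempfile("bundle_")
  write_sim_bundle(b, d)
  expect_true(all(file.exists(file.path(d,
    c("plot_table.csv", "markers.csv", "pixels.csv", "panels.csv")))))
  m <- read_markers_csv(file.path(d, "markers.csv"))
  expect_equal(unname(m), unname(b$markers))
  expect_identical(rownames(m), rownames(b$markers))
})
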