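rcbd_plots <- function(n_geno = 8, n_block = 3, block_sd = 0, seed = 1) {
  set.seed(seed)
  g_eff <- rnorm(n_geno)
  b_eff <- rnorm(n_block, 0, block_sd)
  pt <- expand.grid(line = paste0("G", seq_len(n_geno)),
                    block = seq_len(n_block), stringsAsFactors = FALSE)
  pt$trial <- "T1"; pt$rep <- 1L; pt$is_check <- FALSE
  pt$yield <- 10 + g_eff[match(pt$line, paste0("G", seq_len(n_geno)))] +
    b_eff[pt$block] + rnorm(nrow(pt), 0, 0.3)
  pt$env <- "E1"
  pt
}

test_that("BLUEs equal raw genotype means under a balanced design with no block variance", {
  pt <- rcbd_plots(block_sd = 0)
  fb <- fit_blues(pt, design = "augmented")
  means <- tapply(pt$yield, pt$line, mean)
  expect_equal(fb$blues$blue, as.vector(means[fb$blues$line]),
               tolerance = 1e-6)
})

test_that("EM-REML recovers design variance components in an alpha lattice", {
  # 100 genotypes x 2 reps, 10 incomplete blocks per rep,
  # sigma2_block = 4, sigma2_e = 1
  sim_alpha <- function(seed) {
    set.seed(seed)
    n_g <- 100; n_rep <- 2; n_blk <- 10
    g_eff <- rnorm(n_g, 0, 2)
    pt <- expand.grid(line = sprintf("G%03d", 1:n_g), rep = 1:n_rep,
                      stringsAsFactors = FALSE)
    pt$trial <- "T1"; pt$is_check <- FALSE; pt$env <- "E1"
    pt$block <- unlist(lapply(1:n_rep, function(r) {
      sample(rep(1:n_blk, length.out = n_g))
    }))
    blk_eff <- matrix(rnorm(n_rep * n_blk, 0, 2), n_rep, n_blk)
    pt$yield <- 50 + g_eff[match(pt$line, sprintf("G%03d", 1:n_g))] +
      blk_eff[cbind(pt$rep, pt$block)] + rnorm(nrow(pt), 0, 1)
    pt
  }
  est <- vapply(1:30, function(s) {
    fb <- fit_blues(sim_alpha(s), design = "alpha_lattice")
    c(fb$varcomp[["block"]], fb$varcomp[["residual"]])
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 4) / 4, 0.15)
  expect_lt(abs(mean(est[2, ]) - 1) / 1, 0.15)
})

test_that("augmented-design fixed effects match a direct GLS oracle", {
  set.seed(5)
  pt <- data.frame(
    line = c("A", "B", "A", "B", "CHK", "CHK"),
    block = c(1, 1, 2, 2, 1, 2), trial = "T1", rep = 1L,
    is_check = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    env = "E1",
    yield = c(10.2, 11.5, 10.8, 12.1, 9.9, 10.4))
  fb <- fit_blues(pt, design = "augmented")
  # oracle: GLS at the EM-REML variance estimates, sum-to-zero genotypes
  X <- cbind(1, c(1, -1, 1, -1, 0, 0), as.numeric(pt$is_check))
  Z <- model.matrix(~ factor(pt$block) - 1)
  beta <- gls_oracle(pt$yield, X, list(Z), fb$varcomp[["block"]],
                     fb$varcomp[["residual"]])
  expect_equal(unname(fb$fit$beta), drop(beta), tolerance = 1e-6)
})

test_that("genotype confounded with checks is rejected", {
  pt <- rcbd_plots()
  pt$is_check <- pt$line == "G1"
  pt2 <- rbind(pt, transform(pt[pt$line == "G1", ], is_check = FALSE))
  expect_error(fit_blues(pt2, design = "augmented"), "confounded")
})

test_that("EM-REML restricted log-likelihood is non-decreasing", {
  pt <- rcbd_plots(n_geno = 12, n_block = 4, block_sd = 1.5, seed = 3)
  X <- model.matrix(~ factor(pt$line))
  Z <- model.matrix(~ factor(pt$block) - 1)
  fit <- gsfusion:::fit_mixed_emreml(pt$yield, X, list(block = Z),
                                     keep_loglik = TRUE)
  expect_true(all(diff(fit$loglik) >= -1e-7))
})

test_that("EM-REML agrees with lme4 REML on a random-intercept model", {
  skip_if_not_installed("lme4")
  pt <- rcbd_plots(n_geno = 15, n_block = 6, block_sd = 2, seed = 9)
  fit <- gsfusion:::fit_mixed_emreml(
    pt$yield, model.matrix(~ factor(pt$line)),
    list(block = model.matrix(~ factor(pt$block) - 1)),
    tol = 1e-10, max_iter = 2000)
  lf <- lme4::lmer(yield ~ factor(line) + (1 | block), data = pt,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$s2k[["block"]], vc$vcov[vc$grp == "block"],
               tolerance = 1e-3)
  expect_equal(fit$s2e, vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
})

test_that("BLUEs shift by exactly a constant added to all yields", {
  pt <- rcbd_plots(n_geno = 10, n_block = 3, block_sd = 1, seed = 7)
  fb1 <- fit_blues(pt, design = "augmented")
  pt$yield <- pt$yield + 100
  fb2 <- fit_blues(pt, design = "augmented")
  expect_equal(fb2$blues$blue, fb1$blues$blue + 100, tolerance = 1e-6)
})

test_that("across-environment components: perfect repeatability gives zero gE and residual", {
  vals <- rnorm(20, 10, 2)
  tbl <- data.frame(env = rep(c("E1", "E2"), each = 20),
                    line = rep(paste0("L", 1:20), 2),
                    value = rep(vals, 2))
  vc <- estimate_variance_components(tbl)
  expect_lt(vc$var_ge, 1e-4)
  expect_lt(vc$var_residual, 1e-4)
  expect_gt(vc$var_g, 1)
})

test_that("across-environment components recover simulation truth", {
  sim_tbl <- function(seed, n_line = 140, n_env = 3, n_rep = 2) {
    set.seed(seed)
    g <- rnorm(n_line, 0, 10)         # var_g = 100
    e <- rnorm(n_env, 0, 5)
    ge <- matrix(rnorm(n_line * n_env, 0, 5), n_line)   # var_ge = 25
    tbl <- expand.grid(line = seq_len(n_line), env = seq_len(n_env),
                       rep = seq_len(n_rep))
    tbl$value <- g[tbl$line] + e[tbl$env] + ge[cbind(tbl$line, tbl$env)] +
      rnorm(nrow(tbl), 0, sqrt(50))   # var_res = 50
    tbl
  }
  est <- vapply(1:30, function(s) {
    vc <- estimate_variance_components(sim_tbl(s))
    c(vc$var_g, vc$var_ge, vc$var_residual)
  }, numeric(3))
  expect_lt(abs(mean(est[1, ]) - 100) / 100, 0.15)
  expect_lt(abs(mean(est[2, ]) - 25) / 25, 0.15)
  expect_lt(abs(mean(est[3, ]) - 50) / 50, 0.15)
})

test_that("estimates are invariant to row order and gE needs two environments", {
  set.seed(8)
  tbl <- data.frame(env = rep(c("E1", "E2"), each = 15),
                    line = rep(paste0("L", 1:15), 2),
                    value = rnorm(30, 10))
  v1 <- estimate_variance_components(tbl)
  v2 <- estimate_variance_components(tbl[sample(nrow(tbl)), ])
  expect_equal(v1$var_g, v2$var_g, tolerance = 1e-10)
  expect_equal(v1$var_ge, v2$var_ge, tolerance = 1e-10)
  single <- estimate_variance_components(tbl[tbl$env == "E1", ])
  expect_true(is.na(single$var_ge))
})

test_that("heritability follows the entry-mean formula and its monotonicities", {
  expect_equal(heritability(2, 0, 0), 1)
  expect_equal(heritability(0, 1, 1), 0)
  expect_equal(heritability(1, 1, 1, n_e = 1, n_r = 1), 1 / 3)
  expect_error(heritability(0, 0, 0), "zero")
  h <- heritability(1, 1, 1, n_e = 2, n_r = 1.5)
  expect_gt(heritability(2, 1, 1, n_e = 2, n_r = 1.5), h)
  expect_gt(heritability(1, 1, 1, n_e = 3, n_r = 1.5), h)
  expect_gt(heritability(1, 1, 1, n_e = 2, n_r = 2), h)
})
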