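test_that("fold sizes differ by at most one and partition the observations", {
  f <- make_folds(700, k = 7, seed = 1)
  expect_true(all(table(f$assignment) == 100))
  f2 <- make_folds(10, k = 7, seed = 2)
  expect_equal(sort(as.integer(table(f2$assignment))),
               c(1L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_setequal(unique(f2$assignment), 1:7)
  expect_error(make_folds(5, k = 7), "must be >=")
  # degenerate leave-one-out mode still partitions correctly
  f3 <- make_folds(9, k = 9, seed = 3)
  expect_true(all(table(f3$assignment) == 1))
  # deterministic given the seed
  expect_identical(make_folds(50, k = 7, seed = 5),
                   make_folds(50, k = 7, seed = 5))
})

test_that("the cross-validation data fractions follow from the nested design", {
  n <- 700
  f <- make_folds(n, k = 7, seed = 1)
  outer_test <- sum(f$assignment == 1) / n
  expect_equal(100 * outer_test, 14.29, tolerance = 0.005)
  expect_equal(100 * (1 - outer_test), 85.71, tolerance = 0.005)
  tr <- which(f$assignment != 1)
  inner <- make_folds(length(tr), k = 10, seed = 2)
  expect_equal(100 * sum(inner$assignment != 1) / n, 77.14,
               tolerance = 0.005)
  expect_equal(100 * sum(inner$assignment == 1) / n, 8.57,
               tolerance = 0.005)
})

test_that("pearson handles the canonical cases", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_warning(p <- pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(p))
  expect_error(pearson(c(1, 2), c(1, 2)), "at least 3")
})

test_that("nrmse matches hand arithmetic and is scale invariant", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(0, 2), c(1, 1)), 1 / sqrt(2))
  set.seed(1)
  o <- rnorm(20); p <- rnorm(20)
  expect_equal(nrmse(o, p), nrmse(10 * o, 10 * p))
  expect_equal(nrmse(c(0, 2), c(1, 1), denominator = "range"), 0.5)
  expect_error(nrmse(c(1, 1), c(0, 2)), "constant")
})

test_that("7FCV predicts every observation exactly once and is deterministic", {
  dat <- make_cv_data(n_lines = 60, n_envs = 2, seed = 14)
  ps <- build_predictor("ETA8", dat$grm, dat$obs, dat$feats)
  cv <- run_7fcv(dat$obs, ps, model = "pls", seed = 3,
                 pls_control = list(a_max = 5))
  expect_false(anyNA(cv$predictions$predicted))
  expect_equal(nrow(cv$predictions), nrow(dat$obs))
  expect_true(all(table(cv$predictions$fold) >= 1))
  expect_true(all(abs(cv$per_env$cor) <= 1, na.rm = TRUE))
  cv2 <- run_7fcv(dat$obs, ps, model = "pls", seed = 3,
                  pls_control = list(a_max = 5))
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("PLS reaches near-perfect accuracy on noiseless linear data", {
  set.seed(15)
  n <- 140
  obs <- data.frame(line = sprintf("L%03d", 1:n),
                    env = rep(c("E1", "E2"), each = n / 2))
  X <- matrix(rnorm(n * 6), n)
  beta <- c(2, -1, 1, 0.5, -0.5, 1.5)
  obs$y <- drop(X %*% beta)
  ps <- structure(list(eta_id = "custom", terms = "X",
                       blocks = list(X = X), X = X,
                       fixed = matrix(1, n, 1), kernels = list(),
                       standardization = list(), designs = NULL),
                  class = "predictor_set")
  cv <- run_7fcv(obs, ps, model = "pls", seed = 2,
                 pls_control = list(a_max = 6))
  expect_true(all(cv$per_env$cor > 0.99))
  # single-environment collapse: Global equals the per-env correlation
  obs1 <- obs; obs1$env <- "E1"
  cv1 <- run_7fcv(obs1, ps, model = "pls", seed = 2,
                  pls_control = list(a_max = 6))
  expect_equal(cv1$global, cv1$per_env$cor[1], tolerance = 1e-10)
})

test_that("outer-fold test rows never leak into tuning or training", {
  dat <- make_cv_data(n_lines = 50, n_envs = 2, seed = 16)
  ps <- build_predictor("ETA8", dat$grm, dat$obs, dat$feats)
  cv1 <- run_7fcv(dat$obs, ps, model = "pls", seed = 5,
                  pls_control = list(a_max = 4))
  fold <- cv1$predictions$fold
  te <- which(fold == 1)
  obs2 <- dat$obs
  obs2$y[te] <- obs2$y[te] + 1000  # corrupt the held-out responses
  cv2 <- run_7fcv(obs2, ps, model = "pls", seed = 5,
                  pls_control = list(a_max = 4))
  expect_equal(cv2$predictions$predicted[te],
               cv1$predictions$predicted[te], tolerance = 1e-10)
})

test_that("LOEO holds out each environment exactly once", {
  dat <- make_cv_data(n_lines = 60, n_envs = 3, seed = 18)
  ps <- build_predictor("gH", dat$grm, dat$obs, dat$feats)
  lo <- run_loeo(dat$obs, ps, model = "pls", seed = 1,
                 pls_control = list(a_max = 5))
  expect_setequal(lo$per_env$env, unique(dat$obs$env))
  expect_false(anyNA(lo$predictions$predicted))
  expect_error(run_loeo(dat$obs[dat$obs$env == "E01", ], ps),
               "at least 2")
  expect_identical(loeo_predictors(), c("g", "H", "I", "gH", "gI"))
})

test_that("duplicated environments make LOEO with spectral features near-perfect", {
  # two identical environments built from noiseless features
  set.seed(19)
  n <- 80
  feats <- matrix(runif(n * 11, 0.1, 0.9), n,
                  dimnames = list(NULL, gsfusion:::H_NAMES))
  y <- drop(scale(feats) %*% rnorm(11))
  obs <- data.frame(line = rep(sprintf("L%03d", 1:n), 2),
                    env = rep(c("E1", "E2"), each = n),
                    y = rep(y, 2))
  fdf <- data.frame(line = obs$line, env = obs$env,
                    rbind(feats, feats), check.names = FALSE)
  grm <- diag(n); dimnames(grm) <- list(sprintf("L%03d", 1:n),
                                        sprintf("L%03d", 1:n))
  ps <- build_predictor("H", grm, obs, fdf)
  lo <- run_loeo(obs, ps, model = "pls", seed = 4,
                 pls_control = list(a_max = 8))
  expect_true(all(lo$per_env$cor > 0.95))
})
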