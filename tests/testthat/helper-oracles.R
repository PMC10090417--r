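# Independent oracles used across the suite. These deliberately take naive
# routes (direct inversion, NIPALS deflation with the classic normalization)
# so they share no code with the package implementations they check.

# classic NIPALS PLS1: w from X'y, unnormalized scores, p and q scaled by
# t't -- a different normalization convention than the kernel algorithm,
# but identical fitted values for a univariate response
nipals_pls1 <- function(X, y, a) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  E <- Xc
  f <- yc
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, a)
  Tm <- matrix(0, n, a)
  q <- numeric(a)
  for (h in seq_len(a)) {
    w <- crossprod(E, f)
    w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q[h] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - t_ * q[h]
    W[, h] <- w; P[, h] <- p_; Tm[, h] <- t_
  }
  fitted <- drop(Tm %*% q) + mean(y)
  list(fitted = fitted, T = Tm, q = q,
    predict = function(Xn) {
      Xn <- sweep(Xn, 2L, attr(Xc, "scaled:center"))
      Tn <- matrix(0, nrow(Xn), a)
      En <- Xn
      for (h in seq_len(a)) {
        Tn[, h] <- En %*% W[, h]
        En <- En - tcrossprod(Tn[, h], P[, h])
      }
      drop(Tn %*% q) + mean(y)
    })
}

# generalized least squares by direct matrix inversion:
# beta = (X' V^-1 X)^-1 X' V^-1 y with V = s2e I + sum_k s2k Z_k Z_k'
gls_oracle <- function(y, X, Z_list, s2k, s2e) {
  n <- length(y)
  V <- diag(s2e, n)
  for (k in seq_along(Z_list)) V <- V + s2k[k] * tcrossprod(Z_list[[k]])
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# closed-form single-kernel BLUP on a centered response
blup_oracle <- function(yc, K, lambda) {
  drop(K %*% solve(K + diag(lambda, nrow(K)), yc))
}

# small synthetic dataset prepared for CV tests: markers -> GRM, spectral
# features through the full calibration path, cell-mean response
make_cv_data <- function(n_lines = 150, n_envs = 3, seed = 21,
                         spectral_signal = 0.8, h2 = 0.4, ...) {
  b <- generate_dataset(sim_config(
    n_lines = n_lines, n_snps = 400, n_envs = n_envs,
    spectral_signal = spectral_signal, h2_target = h2, var_ge = 0.3,
    seed = seed, ...))
  mk <- impute_markers(filter_snps(b$markers))
  grm <- compute_grm(mk)
  feats <- build_spectral_features(b$pixel_table, b$panel_table,
                                   b$plot_table)
  cm <- cell_means(b$plot_table)
  list(bundle = b, grm = grm, feats = feats,
       obs = data.frame(line = cm$line, env = cm$env, y = cm$y))
}
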