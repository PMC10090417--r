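# EM-REML on Henderson's mixed-model equations.
#
# Model: y = X b + sum_k Z_k u_k + e,  u_k ~ N(0, s2_k I),  e ~ N(0, s2_e I).
# The MME coefficient matrix is assembled as W'W + blockdiag(0, lambda_k I)
# with lambda_k = s2_e / s2_k; its inverse times s2_e is the sampling
# covariance used by the EM trace terms:
#   s2_k <- (u_k'u_k + s2_e * tr(Cinv_kk)) / q_k
#   s2_e <- (y'y - sol'rhs) / (n - rank(X))
# EM-REML is monotone in the restricted likelihood; the (optional) per-step
# log-likelihood is computed densely from V for diagnostics and tests.

fit_mixed_emreml <- function(y, X, Z_list, tol = 1e-6, max_iter = 500L,
                             keep_loglik = FALSE, start = NULL) {
  stopifnot(is.numeric(y), nrow(X) == length(y))
  n <- length(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("fixed-effect design is rank deficient (confounded factors); ",
         "rank ", qrX$rank, " < ", ncol(X), " columns")
  }
  K <- length(Z_list)
  qk <- vapply(Z_list, ncol, 0L)
  W <- do.call(cbind, c(list(X), Z_list))
  WtW <- crossprod(W)
  rhs <- crossprod(W, y)
  p <- ncol(X)
  # index ranges of each random term inside the MME solution vector
  ends <- p + cumsum(qk)
  starts <- ends - qk + 1L
  vy <- stats::var(y)
  s2e <- if (is.null(start)) vy / 2 else start$s2e
  s2k <- if (is.null(start)) rep(vy / (2 * max(K, 1L)), K) else start$s2k
  floor_v <- 1e-10 * max(vy, 1e-12)

  loglik <- if (keep_loglik) numeric(0) else NULL
  reml_ll <- function(s2e, s2k) {
    V <- diag(s2e, n)
    for (k in seq_len(K)) V <- V + s2k[k] * tcrossprod(Z_list[[k]])
    cV <- chol(V)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(Vi_X, y))
    r <- y - X %*% beta
    Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
    -0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus[1] +
              sum(r * Vi_r))
  }

  sol <- NULL; Cinv <- NULL
  for (it in seq_len(max_iter)) {
    C <- WtW
    for (k in seq_len(K)) {
      idx <- starts[k]:ends[k]
      diag(C)[idx] <- diag(WtW)[idx] + s2e / s2k[k]
    }
    Cinv <- solve(C)
    sol <- Cinv %*% rhs
    s2e_new <- max(as.numeric(crossprod(y) - crossprod(sol, rhs)) /
                     (n - qrX$rank), floor_v)
    s2k_new <- s2k
    for (k in seq_len(K)) {
      idx <- starts[k]:ends[k]
      u <- sol[idx]
      s2k_new[k] <- max((sum(u^2) + s2e * sum(diag(Cinv)[idx])) / qk[k],
                        floor_v)
    }
    if (keep_loglik) loglik <- c(loglik, reml_ll(s2e_new, s2k_new))
    rel <- max(abs(c(s2e_new, s2k_new) - c(s2e, s2k)) /
                 pmax(abs(c(s2e, s2k)), floor_v))
    s2e <- s2e_new; s2k <- s2k_new
    if (rel < tol) break
  }
  names(s2k) <- names(Z_list)
  beta <- sol[seq_len(p)]
  names(beta) <- colnames(X)
  u <- lapply(seq_len(K), function(k) {
    v <- sol[starts[k]:ends[k]]
    names(v) <- colnames(Z_list[[k]])
    v
  })
  names(u) <- names(Z_list)
  list(beta = beta, u = u, s2e = s2e, s2k = s2k,
       iterations = it, converged = rel < tol,
       Cinv = Cinv, rank_X = qrX$rank, loglik = loglik)
}
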