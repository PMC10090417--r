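#' Bayesian multi-kernel GBLUP by Gibbs sampling
#'
#' Fits `y = X beta + sum_k u_k + e`, `u_k ~ N(0, sigma2_k K_k)`,
#' `e ~ N(0, sigma2_e I)`, with scaled-inverse-chi-square priors on every
#' variance. Each kernel is eigendecomposed once and its effects are sampled
#' in the eigenbasis (independent conditional normals per eigenvector), so a
#' full sweep costs one matrix-vector product per term. Masked responses
#' (`NA` in `y`) are imputed from the current model state at every
#' iteration, which is how test-set rows included in the kernels are
#' predicted: their stored `y` values are never read.
#'
#' Priors: df = 5 for every variance, with the scale set so each term's
#' prior mode equals an equal share of half the phenotypic variance (the
#' residual mode gets the other half). `fix_variances` freezes the variances
#' at their initial values (the infinite-df limit), giving a sampler whose
#' posterior mean matches closed-form BLUP.
#'
#' @param y numeric response with `NA` marking masked (to-predict) rows.
#' @param kernels named list of n x n symmetric PSD kernels spanning all
#'   rows of `y`.
#' @param fixed n x q fixed-effect design (e.g. environment one-hot with
#'   intercept); `NULL` for no fixed effects (requires a centered response).
#' @param n_iter,burn_in,thin chain controls.
#' @param seed RNG seed for the chain (dedicated stream; the caller's RNG
#'   state is restored on exit).
#' @param prior_df scaled-inverse-chi-square degrees of freedom.
#' @param fix_variances logical; if `TRUE`, variances stay at `init_var`.
#' @param init_var optional named list / vector with `residual` and one
#'   entry per kernel giving initial (or fixed) variances.
#' @param eig_tol relative eigenvalue cutoff below which kernel directions
#'   are dropped.
#' @return list of class `gblup_fit`: posterior means (`mu`/`beta`, `u` per
#'   term, `fitted`, `predicted` for masked rows), `samples` (thinned draws
#'   of fixed effects and variances), and bookkeeping.
#' @export
fit_gblup <- function(y, kernels, fixed = NULL,
                      n_iter = 12000L, burn_in = 2000L, thin = 5L,
                      seed = 1L, prior_df = 5,
                      fix_variances = FALSE, init_var = NULL,
                      eig_tol = 1e-8) {
  stopifnot(is.list(kernels), length(kernels) >= 1L,
            burn_in < n_iter, prior_df > 0)
  n <- length(y)
  mask <- is.na(y)
  if (all(mask)) stop("need at least one observed response")
  y_obs <- y[!mask]
  if (stats::sd(y_obs) == 0) stop("zero-variance response")
  if (is.null(fixed)) {
    X <- matrix(0, n, 0L)
  } else {
    X <- as.matrix(fixed)
    stopifnot(nrow(X) == n)
  }
  for (K in kernels) stopifnot(nrow(K) == n, ncol(K) == n)

  K_terms <- length(kernels)
  eig <- lapply(kernels, function(K) {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-6 * max(abs(e$values))) {
      stop("kernel is not PSD beyond repair tolerance")
    }
    keep <- e$values > eig_tol * max(e$values, 0)
    if (!any(keep)) stop("kernel has no positive eigenvalues")
    list(V = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })

  vy <- stats::var(y_obs)
  mode_share <- 0.5 * vy / K_terms
  scale_k <- vapply(kernels, function(K) {
    # scale so the prior mode of sigma2_k * mean(diag K) is an equal share
    mode_share / max(mean(diag(K)), 1e-12) * (prior_df + 2) / prior_df
  }, 0)
  scale_e <- 0.5 * vy * (prior_df + 2) / prior_df

  s2k <- vapply(names(kernels), function(nm) {
    v <- if (!is.null(init_var)) init_var[[nm]] else NULL
    if (is.null(v)) mode_share / max(mean(diag(kernels[[nm]])), 1e-12)
    else v
  }, 0)
  s2e <- if (!is.null(init_var) && !is.null(init_var[["residual"]]))
    init_var[["residual"]] else 0.5 * vy

  # dedicated RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  q <- ncol(X)
  if (q > 0L) {
    XtX_chol <- chol(crossprod(X) + diag(1e-10, q))
    beta <- rep(0, q)
  } else beta <- numeric(0)
  alpha <- lapply(eig, function(e) rep(0, length(e$d)))
  u <- lapply(eig, function(e) rep(0, n))
  ycur <- y
  ycur[mask] <- mean(y_obs)

  n_keep <- (n_iter - burn_in) %/% thin
  draws_var <- matrix(0, n_keep, K_terms + 1L,
                      dimnames = list(NULL, c(names(kernels), "residual")))
  draws_beta <- matrix(0, n_keep, q,
                       dimnames = list(NULL, colnames(X)))
  acc_fit <- rep(0, n)
  acc_u <- lapply(eig, function(e) rep(0, n))
  kept <- 0L

  for (it in seq_len(n_iter)) {
    u_sum <- Reduce(`+`, u)
    fit_now <- (if (q > 0L) drop(X %*% beta) else 0) + u_sum
    if (any(mask)) {
      ycur[mask] <- fit_now[mask] + stats::rnorm(sum(mask), 0, sqrt(s2e))
    }
    ## fixed effects
    if (q > 0L) {
      r <- ycur - u_sum
      bhat <- backsolve(XtX_chol,
                        forwardsolve(t(XtX_chol), crossprod(X, r)))
      beta <- drop(bhat) +
        drop(backsolve(XtX_chol, stats::rnorm(q))) * sqrt(s2e)
    }
    xb <- if (q > 0L) drop(X %*% beta) else rep(0, n)
    ## kernel terms in their eigenbases
    for (k in seq_len(K_terms)) {
      r_k <- ycur - xb - (Reduce(`+`, u) - u[[k]])
      z <- drop(crossprod(eig[[k]]$V, r_k))
      prec <- 1 / s2e + 1 / (s2k[k] * eig[[k]]$d)
      m_post <- (z / s2e) / prec
      alpha[[k]] <- m_post + stats::rnorm(length(z)) / sqrt(prec)
      u[[k]] <- drop(eig[[k]]$V %*% alpha[[k]])
    }
    ## variances
    if (!fix_variances) {
      for (k in seq_len(K_terms)) {
        ss <- sum(alpha[[k]]^2 / eig[[k]]$d)
        m_k <- length(eig[[k]]$d)
        s2k[k] <- (ss + prior_df * scale_k[k]) /
          stats::rchisq(1L, prior_df + m_k)
      }
      res <- ycur - xb - Reduce(`+`, u)
      s2e <- (sum(res^2) + prior_df * scale_e) /
        stats::rchisq(1L, prior_df + n)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws_var[kept, ] <- c(s2k, s2e)
      if (q > 0L) draws_beta[kept, ] <- beta
      fit_it <- xb + Reduce(`+`, u)
      acc_fit <- acc_fit + fit_it
      for (k in seq_len(K_terms)) acc_u[[k]] <- acc_u[[k]] + u[[k]]
    }
  }
  post_fit <- acc_fit / kept
  post_u <- lapply(acc_u, function(a) a / kept)
  names(post_u) <- names(kernels)
  structure(list(
    mu = if (q > 0L) colMeans(draws_beta) else NULL,
    beta = if (q > 0L) colMeans(draws_beta) else NULL,
    u = post_u,
    fitted = post_fit,
    predicted = post_fit[mask],
    mask = mask,
    var_post = colMeans(draws_var),
    samples = list(variances = draws_var, beta = draws_beta),
    n_kept = kept,
    control = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                   seed = seed, prior_df = prior_df,
                   fix_variances = fix_variances)),
    class = "gblup_fit")
}

#' Posterior-mean predictions for masked observations
#'
#' @param fit a `gblup_fit` whose response contained masked (`NA`) rows.
#' @return named numeric vector of posterior-mean predictions, aligned to
#'   the masked row indices (names = positions in the original response).
#' @export
predict_masked <- function(fit) {
  if (!any(fit$mask)) stop("fit contains no masked rows")
  stats::setNames(fit$fitted[fit$mask], which(fit$mask))
}
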