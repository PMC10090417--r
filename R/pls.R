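#' Univariate kernel-algorithm partial least squares
#'
#' Implements the nine-step kernel algorithm for PLS1. After centering `X`
#' and `y` (scaling optional), each round computes the cross-product
#' `S = E'f`; for a univariate response the dominant eigenvector of `S S'`
#' reduces to `w = S / ||S||` (the general SVD route is retained as a
#' cross-check option), scores `t = E w` are normalized to unit length,
#' loadings `p = E't` and `q = f_deflated' t` are taken, and `E` and `f` are
#' deflated by `t p'` and `t q`. From the collected `W, T, P, Q`:
#' `R = W (P'W)^-1`, `b = (T'T)^-1 T' y_c` on the undeflated centered
#' response, and `B = R b` maps back to the original variables. Extraction
#' stops early (recording the achieved number of components) when the
#' deflated matrix is numerically empty.
#'
#' @param X n x p numeric matrix with at least one nonconstant column.
#' @param y numeric response vector (nonconstant).
#' @param a number of latent components, `a <= min(n - 1, p)`.
#' @param scale standardize `X` columns before fitting.
#' @param w_method `"direct"` (`w = S/||S||`) or `"svd"` (dominant
#'   eigenvector of `S S'`); identical up to sign for univariate `y`.
#' @return list of class `pls_model` with `W`, `P`, `Q`, `T`, `R`, `b`, `B`,
#'   centering/scaling records, achieved `a`, and training `fitted` values.
#' @export
fit_pls <- function(X, y, a, scale = FALSE,
                    w_method = c("direct", "svd")) {
  w_method <- match.arg(w_method)
  stopifnot(is.matrix(X), length(y) == nrow(X), a >= 1L)
  n <- nrow(X); p <- ncol(X)
  if (a > min(n - 1L, p)) stop("a must be <= min(n - 1, p)")
  if (stats::sd(y) == 0) stop("constant response")
  x_center <- colMeans(X)
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- apply(X, 2L, stats::sd)
    x_scale[x_scale == 0] <- 1
  }
  Xc <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  if (all(apply(Xc, 2L, stats::sd) == 0)) stop("all columns constant")
  y_center <- mean(y)
  yc <- y - y_center

  E <- Xc; f <- yc
  W <- P <- matrix(0, p, a)
  Tm <- matrix(0, n, a)
  Q <- numeric(a)
  achieved <- 0L
  eps <- 1e-12 * max(abs(Xc))
  for (h in seq_len(a)) {
    S <- crossprod(E, f)                       # p x 1
    if (sqrt(sum(S^2)) <= eps * max(1, sqrt(sum(f^2)))) break
    w <- if (w_method == "direct") {
      S / sqrt(sum(S^2))
    } else {
      sv <- svd(tcrossprod(S), nu = 1L)        # dominant eigvec of S S'
      drop(sv$u[, 1L]) * sign(sum(sv$u[, 1L] * S))
    }
    t_ <- drop(E %*% w)
    nt <- sqrt(sum(t_^2))
    if (nt <= eps) break
    t_ <- t_ / nt
    p_ <- drop(crossprod(E, t_))
    q_ <- sum(f * t_)
    E <- E - tcrossprod(t_, p_)
    f <- f - t_ * q_
    W[, h] <- w; Tm[, h] <- t_; P[, h] <- p_; Q[h] <- q_
    achieved <- h
  }
  if (achieved == 0L) stop("no extractable component (X'y numerically zero)")
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  Tm <- Tm[, seq_len(achieved), drop = FALSE]
  Q <- Q[seq_len(achieved)]
  R <- W %*% solve(crossprod(P, W))
  b <- drop(solve(crossprod(Tm), crossprod(Tm, yc)))
  B <- drop(R %*% b)
  fitted <- drop(Tm %*% b) + y_center
  structure(list(W = W, P = P, Q = Q, T = Tm, R = R, b = b, B = B,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, a = achieved, fitted = fitted),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' Centers (and optionally rescales) new rows by the training records and
#' applies `B`; the algebraically identical score route
#' `T_new b` with `T_new = X_new R` is available via `route = "scores"` and
#' agrees with the coefficient route to numerical precision.
#'
#' @param model a `pls_model`.
#' @param X_new matrix with the training column count.
#' @param route `"coefficients"` (`X_new B`) or `"scores"` (`T_new b`).
#' @return predicted responses.
#' @export
predict_pls <- function(model, X_new, route = c("coefficients", "scores")) {
  route <- match.arg(route)
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1L)
  if (ncol(X_new) != length(model$x_center)) {
    stop("column-count mismatch: ", ncol(X_new), " vs ",
         length(model$x_center))
  }
  Xc <- sweep(sweep(X_new, 2L, model$x_center), 2L, model$x_scale, "/")
  if (route == "coefficients") {
    drop(Xc %*% model$B) + model$y_center
  } else {
    drop((Xc %*% model$R) %*% model$b) + model$y_center
  }
}

#' Choose the number of PLS components by inner cross-validation
#'
#' For `a = 1..a_max`, the mean validation NRMSE (or MSE) over `k_inner`
#' random folds is computed by refitting on each inner-training split;
#' `a_star` is the arg-min, with ties broken toward the smallest `a`
#' (parsimony). NRMSE normalizes the fold RMSE by the standard deviation of
#' the fold's observed values (range or mean denominators available).
#'
#' @param X,y training data.
#' @param a_max largest component count tried (capped at `min(n - 1, p)` per
#'   split as needed).
#' @param k_inner number of inner folds.
#' @param seed fold-assignment seed (dedicated stream; restores the caller's
#'   RNG state).
#' @param metric `"nrmse"` or `"mse"`.
#' @param denominator NRMSE denominator: `"sd"`, `"range"` or `"mean"` of
#'   the fold's observed values.
#' @param scale passed to [fit_pls()].
#' @return list with `a_star` and `curve` (per-`a` mean validation metric).
#' @export
tune_components <- function(X, y, a_max, k_inner = 10L, seed = 1L,
                            metric = c("nrmse", "mse"),
                            denominator = c("sd", "range", "mean"),
                            scale = FALSE) {
  metric <- match.arg(metric)
  denominator <- match.arg(denominator)
  n <- nrow(X)
  if (a_max < 1L) stop("a_max must be >= 1")
  if (n < k_inner) stop("need at least k_inner observations")
  fold <- make_folds(n, k = k_inner, seed = seed)$assignment
  scores <- matrix(NA_real_, k_inner, a_max)
  for (kf in seq_len(k_inner)) {
    tr <- which(fold != kf); va <- which(fold == kf)
    a_cap <- min(a_max, length(tr) - 1L, ncol(X))
    for (a in seq_len(a_cap)) {
      m <- fit_pls(X[tr, , drop = FALSE], y[tr], a = a, scale = scale)
      pred <- predict_pls(m, X[va, , drop = FALSE])
      scores[kf, a] <- if (metric == "mse") {
        mean((y[va] - pred)^2)
      } else {
        nrmse(y[va], pred, denominator = denominator)
      }
    }
  }
  curve <- colMeans(scores, na.rm = TRUE)
  a_star <- which.min(curve)   # which.min takes the first (smallest a) tie
  list(a_star = a_star, curve = curve)
}
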