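# run f with a dedicated RNG stream seeded by `seed`, restoring the
# caller's state afterwards so split seeds and model seeds stay decoupled
with_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  f()
}

#' Random k-fold partition at the observation level
#'
#' Uniformly random assignment with fold sizes `floor(n/k)` or
#' `ceiling(n/k)` (differing by at most one).
#'
#' @param n_obs number of observations.
#' @param k number of folds.
#' @param seed fold-stream seed.
#' @return list with `assignment` (integer vector in `1..k`), `k`, `seed`.
#' @export
make_folds <- function(n_obs, k = 7L, seed = 1L) {
  if (n_obs < k) stop("n_obs (", n_obs, ") must be >= k (", k, ")")
  assignment <- with_seed(seed, function() {
    sample(rep(seq_len(k), length.out = n_obs))
  })
  list(assignment = assignment, k = k, seed = seed)
}

#' Pearson correlation between observed and predicted values
#'
#' @param obs,pred numeric vectors of equal length (>= 3, nonconstant).
#' @return sample Pearson correlation, or `NA` with a warning when either
#'   vector is constant.
#' @export
pearson <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  if (length(obs) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(obs, pred)
}

#' Normalized root-mean-squared error
#'
#' `RMSE(obs, pred)` divided by a spread measure of the observed values
#' (standard deviation by default; range and mean available).
#'
#' @param obs,pred numeric vectors.
#' @param denominator `"sd"`, `"range"` or `"mean"`.
#' @return NRMSE value.
#' @export
nrmse <- function(obs, pred, denominator = c("sd", "range", "mean")) {
  denominator <- match.arg(denominator)
  stopifnot(length(obs) == length(pred))
  den <- switch(denominator,
                sd = stats::sd(obs),
                range = diff(range(obs)),
                mean = mean(obs))
  if (!is.finite(den) || den == 0) stop("constant observed values")
  sqrt(mean((obs - pred)^2)) / den
}

# fit on the training rows and predict the test rows, for either model
cv_fit_predict <- function(ps, y, test, model, seed,
                           pls_control = list(), gblup_control = list()) {
  if (model == "pls") {
    tr <- setdiff(seq_along(y), test)
    Xtr <- ps$X[tr, , drop = FALSE]
    a_max <- min(pls_control$a_max %||% 15L, length(tr) - 2L, ncol(Xtr))
    tune <- tune_components(
      Xtr, y[tr], a_max = a_max,
      k_inner = pls_control$k_inner %||% 10L,
      seed = seed,
      metric = pls_control$metric %||% "nrmse",
      scale = isTRUE(pls_control$scale))
    m <- fit_pls(Xtr, y[tr], a = tune$a_star,
                 scale = isTRUE(pls_control$scale))
    list(pred = predict_pls(m, ps$X[test, , drop = FALSE]),
         hyper = tune$a_star)
  } else {
    ymask <- y
    ymask[test] <- NA_real_
    fit <- do.call(fit_gblup, c(list(
      y = ymask, kernels = ps$kernels, fixed = ps$fixed, seed = seed),
      gblup_control))
    list(pred = unname(fit$fitted[test]), hyper = NA)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fold-average per-environment correlations and the line-averaged Global
summarize_7fcv <- function(obs_tbl, y, pred, fold) {
  k <- max(fold)
  envs <- sort(unique(obs_tbl$env))
  per_env <- matrix(NA_real_, k, length(envs),
                    dimnames = list(NULL, envs))
  pooled <- rep(NA_real_, k)
  skipped <- 0L
  for (kf in seq_len(k)) {
    te <- which(fold == kf)
    if (length(te) >= 3L && stats::sd(y[te]) > 0 && stats::sd(pred[te]) > 0)
      pooled[kf] <- stats::cor(y[te], pred[te])
    for (e in envs) {
      ix <- te[obs_tbl$env[te] == e]
      if (length(ix) < 3L) { skipped <- skipped + 1L; next }
      if (stats::sd(y[ix]) == 0 || stats::sd(pred[ix]) == 0) next
      per_env[kf, e] <- stats::cor(y[ix], pred[ix])
    }
  }
  env_cor <- colMeans(per_env, na.rm = TRUE)
  env_se <- apply(per_env, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  ## Global: correlation between per-line averages of observed and
  ## held-out-predicted values over whatever environments each line has
  yl <- tapply(y, obs_tbl$line, mean)
  pl <- tapply(pred, obs_tbl$line, mean)
  global <- pearson(as.numeric(yl), as.numeric(pl))
  global_se <- stats::sd(pooled, na.rm = TRUE) /
    sqrt(sum(!is.na(pooled)))
  list(per_env = data.frame(env = envs, cor = unname(env_cor),
                            se = unname(env_se), row.names = NULL),
       global = global, global_se = global_se,
       skipped_cells = skipped)
}

#' Seven-fold cross-validation (partially tested lines, tested environments)
#'
#' Observation-level random folds (a line can be trained in one environment
#' and tested in another). For PLS, the number of components is tuned per
#' outer fold by inner 10-fold cross-validation on the outer-training set
#' only, the model is refitted on the full outer-training set, and the outer
#' test fold is predicted; GBLUP needs no tuning and uses a masked-response
#' joint fit. Per-environment accuracy is the mean over folds of
#' within-fold-within-environment Pearson correlations (fold cells with
#' fewer than 3 test observations are skipped and counted); Global is the
#' correlation between per-line averages of observed and predicted values,
#' with a fold-wise standard error.
#'
#' @param obs_tbl data.frame with `line`, `env`, `y` (one row per
#'   observation).
#' @param ps a `predictor_set` built on the same rows ([build_predictor()]).
#' @param model `"pls"` or `"gblup"`.
#' @param k number of outer folds.
#' @param seed split seed; model/tuning seeds are derived from it but run in
#'   dedicated streams.
#' @param pls_control list: `a_max`, `k_inner`, `metric`, `scale`.
#' @param gblup_control list passed to [fit_gblup()] (chain controls).
#' @return list of class `cv_result`: `per_env`, `global`, `global_se`,
#'   `predictions` (data.frame with fold, hyperparameter, observed,
#'   predicted), `scheme`, `model`, `eta_id`.
#' @export
run_7fcv <- function(obs_tbl, ps, model = c("gblup", "pls"), k = 7L,
                     seed = 1L, pls_control = list(),
                     gblup_control = list()) {
  model <- match.arg(model)
  stopifnot(nrow(obs_tbl) == nrow(ps$X) || length(ps$kernels) > 0)
  n <- nrow(obs_tbl)
  y <- obs_tbl$y
  fold <- make_folds(n, k = k, seed = seed)$assignment
  pred <- rep(NA_real_, n)
  hyper <- rep(NA, k)
  for (kf in seq_len(k)) {
    te <- which(fold == kf)
    res <- cv_fit_predict(ps, y, te, model, seed = seed * 1000L + kf,
                          pls_control = pls_control,
                          gblup_control = gblup_control)
    pred[te] <- res$pred
    hyper[kf] <- res$hyper
  }
  sm <- summarize_7fcv(obs_tbl, y, pred, fold)
  structure(list(per_env = sm$per_env, global = sm$global,
                 global_se = sm$global_se,
                 skipped_cells = sm$skipped_cells,
                 predictions = data.frame(line = obs_tbl$line,
                                          env = obs_tbl$env, fold = fold,
                                          observed = y, predicted = pred),
                 hyper = hyper, scheme = "7FCV", model = model,
                 eta_id = ps$eta_id, seed = seed),
            class = "cv_result")
}

#' The default five leave-one-environment-out predictor sets
#'
#' Reconstructed as genomic only (`g`), multispectral only (`H`, `I`), and
#' the two fusions with the G-by-E kernel (`gH`, `gI`); exposed as
#' configuration since any [build_predictor()] id is accepted by
#' [run_loeo()].
#'
#' @return character vector of predictor ids.
#' @export
loeo_predictors <- function() c("g", "H", "I", "gH", "gI")

#' Leave-one-environment-out cross-validation
#'
#' Each environment is held out once; its observations form the single test
#' fold, so the per-environment correlation comes from that one fold. The
#' Global accuracy pools all held-out predictions (default) and the average
#' of per-environment correlations is also reported, with the standard
#' error taken across environments. PLS component tuning is nested inside
#' each training set exactly as under 7FCV.
#'
#' @param obs_tbl data.frame with `line`, `env`, `y`.
#' @param ps a `predictor_set`; ids without an environment block
#'   ([loeo_predictors()]) are the intended inputs, but any id is accepted.
#' @param model `"pls"` or `"gblup"`.
#' @param seed seed for nested tuning / chains.
#' @param global `"pooled"` (correlation over all held-out predictions) or
#'   `"mean_env"` (average of per-environment correlations).
#' @param pls_control,gblup_control as in [run_7fcv()].
#' @return `cv_result` as in [run_7fcv()].
#' @export
run_loeo <- function(obs_tbl, ps, model = c("gblup", "pls"), seed = 1L,
                     global = c("pooled", "mean_env"),
                     pls_control = list(), gblup_control = list()) {
  model <- match.arg(model)
  global <- match.arg(global)
  envs <- sort(unique(obs_tbl$env))
  if (length(envs) < 2L) stop("LOEO needs at least 2 environments")
  n <- nrow(obs_tbl)
  y <- obs_tbl$y
  pred <- rep(NA_real_, n)
  per_env <- data.frame(env = envs, cor = NA_real_, se = NA_real_)
  hyper <- rep(NA, length(envs))
  for (i in seq_along(envs)) {
    te <- which(obs_tbl$env == envs[i])
    if (length(te) == n) stop("training set empty for environment ",
                              envs[i])
    res <- cv_fit_predict(ps, y, te, model, seed = seed * 1000L + i,
                          pls_control = pls_control,
                          gblup_control = gblup_control)
    pred[te] <- res$pred
    hyper[i] <- res$hyper
    if (length(te) >= 3L && stats::sd(y[te]) > 0 &&
        stats::sd(res$pred) > 0) {
      per_env$cor[i] <- stats::cor(y[te], res$pred)
    }
  }
  global_val <- if (global == "pooled") pearson(y, pred) else
    mean(per_env$cor, na.rm = TRUE)
  global_se <- stats::sd(per_env$cor, na.rm = TRUE) /
    sqrt(sum(!is.na(per_env$cor)))
  structure(list(per_env = per_env, global = global_val,
                 global_mean_env = mean(per_env$cor, na.rm = TRUE),
                 global_se = global_se,
                 predictions = data.frame(line = obs_tbl$line,
                                          env = obs_tbl$env,
                                          observed = y, predicted = pred),
                 hyper = hyper, scheme = "LOEO", model = model,
                 eta_id = ps$eta_id, seed = seed),
            class = "cv_result")
}
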