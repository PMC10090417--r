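#' Per-environment BLUEs of grain yield
#'
#' Fits, within a single environment, the design-appropriate mixed linear
#' model by EM-REML on Henderson's mixed-model equations and returns best
#' linear unbiased estimates for every entry. Genotype and check effects are
#' fixed; design factors are random:
#'
#' * `alpha_lattice`: `y = mu + g_i + check_i + t_j + r_k(j) + b_l(jk) + e`,
#'   with random trial, replicate-within-trial and incomplete-block effects;
#' * `augmented`: `y = mu + g_i + check_i + b_j + e`, with random blocks.
#'
#' Non-check genotype effects use a sum-to-zero constraint and BLUEs are
#' reported as intercept + effect; check entries get their own fixed dummy
#' columns. Random terms whose factor has fewer than two levels in the data
#' are dropped (their variance reported as `NA`).
#'
#' @param plots data.frame for one environment with columns `line`,
#'   `is_check` (logical), `yield`, and the design factors `trial`, `rep`,
#'   `block` (`trial`/`rep` ignored under `augmented`).
#' @param design `"alpha_lattice"` or `"augmented"`.
#' @param tol,max_iter EM-REML convergence controls.
#' @return list with `blues` (data.frame `line`, `blue`, `se`),
#'   `varcomp` (named vector `trial`, `rep`, `block`, `residual`), and the
#'   underlying `fit`.
#' @export
fit_blues <- function(plots, design = c("alpha_lattice", "augmented"),
                      tol = 1e-6, max_iter = 500L) {
  design <- match.arg(design)
  stopifnot(all(c("line", "yield") %in% names(plots)))
  if (!"is_check" %in% names(plots)) plots$is_check <- FALSE
  y <- plots$yield
  is_chk <- as.logical(plots$is_check)

  test_lines <- sort(unique(plots$line[!is_chk]))
  check_lines <- sort(unique(plots$line[is_chk]))
  if (any(test_lines %in% check_lines)) {
    stop("genotype confounded with check: line(s) appear both as check ",
         "and as test entry: ",
         paste(intersect(test_lines, check_lines), collapse = ", "))
  }

  n <- nrow(plots)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  cs <- NULL
  if (length(test_lines) >= 2L) {
    gf <- factor(ifelse(is_chk, NA, plots$line), levels = test_lines)
    cs <- stats::contr.sum(length(test_lines))
    rownames(cs) <- test_lines
    Xg <- matrix(0, n, ncol(cs),
                 dimnames = list(NULL, paste0("g", seq_len(ncol(cs)))))
    obs_t <- which(!is_chk)
    Xg[obs_t, ] <- cs[as.integer(gf[obs_t]), , drop = FALSE]
    X <- cbind(X, Xg)
  }
  if (length(check_lines) >= 1L) {
    Xc <- vapply(check_lines, function(l) as.numeric(plots$line == l),
                 numeric(n))
    colnames(Xc) <- paste0("check_", check_lines)
    X <- cbind(X, Xc)
  }

  inc <- function(f) {
    f <- droplevels(factor(f))
    if (nlevels(f) < 2L) return(NULL)
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- levels(f)
    m
  }
  Z_list <- list()
  if (design == "alpha_lattice") {
    Z_list$trial <- inc(plots$trial)
    Z_list$rep   <- inc(interaction(plots$trial, plots$rep, drop = TRUE))
    Z_list$block <- inc(interaction(plots$trial, plots$rep, plots$block,
                                    drop = TRUE))
  } else {
    Z_list$block <- inc(plots$block)
  }
  dropped <- names(Z_list)[vapply(Z_list, is.null, TRUE)]
  Z_list <- Z_list[!vapply(Z_list, is.null, TRUE)]

  fit <- fit_mixed_emreml(y, X, Z_list, tol = tol, max_iter = max_iter)

  # BLUE_i = mu + g_i (sum-to-zero over test entries) or mu + check effect
  contrasts <- matrix(0, length(test_lines) + length(check_lines), ncol(X))
  colnames(contrasts) <- colnames(X)
  rownames(contrasts) <- c(test_lines, check_lines)
  contrasts[, "(Intercept)"] <- 1
  if (length(test_lines) >= 2L) {
    contrasts[test_lines, paste0("g", seq_len(ncol(cs)))] <- cs
  }
  for (l in check_lines) contrasts[l, paste0("check_", l)] <- 1

  est <- drop(contrasts %*% fit$beta)
  Cpp <- fit$Cinv[seq_len(ncol(X)), seq_len(ncol(X)), drop = FALSE]
  se <- sqrt(pmax(fit$s2e * rowSums((contrasts %*% Cpp) * contrasts), 0))

  vc <- c(trial = NA_real_, rep = NA_real_, block = NA_real_,
          residual = fit$s2e)
  vc[names(fit$s2k)] <- fit$s2k
  if (design == "augmented") vc <- vc[c("block", "residual")]
  blues <- data.frame(line = rownames(contrasts), blue = est, se = se,
                      is_check = rownames(contrasts) %in% check_lines,
                      row.names = NULL)
  list(blues = blues, varcomp = vc, dropped_terms = dropped, fit = fit)
}

#' Across-environment variance components on adjusted means
#'
#' Fits `value = mu + env (fixed) + g (random) + gE (random) + e` by EM-REML
#' and summarizes the incidence unbalance. The table may contain repeated
#' (line, env) rows (replicate-level values); with exactly one row per cell
#' the gE and residual components are confounded and only their sum is well
#' identified. With a single environment the gE component is not estimable
#' and is reported as `NA`.
#'
#' @param blue_table data.frame with columns `env`, `line`, `value`.
#' @param tol,max_iter EM-REML controls.
#' @return list with `var_g`, `var_ge`, `var_residual`, `n_e`, `n_r`, `H2`
#'   (entry-mean heritability, see [heritability()]), and the raw `fit`.
#' @export
estimate_variance_components <- function(blue_table, tol = 1e-6,
                                         max_iter = 500L) {
  stopifnot(all(c("env", "line", "value") %in% names(blue_table)))
  tbl <- blue_table[order(blue_table$env, blue_table$line), , drop = FALSE]
  envf  <- factor(tbl$env)
  linef <- factor(tbl$line)
  y <- tbl$value
  X <- if (nlevels(envf) < 2L) {
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ envf)
  }
  Zg <- stats::model.matrix(~ linef - 1)
  colnames(Zg) <- levels(linef)
  Z_list <- list(g = Zg)
  single_env <- nlevels(envf) < 2L
  if (!single_env) {
    cellf <- interaction(linef, envf, drop = TRUE)
    Zge <- stats::model.matrix(~ cellf - 1)
    colnames(Zge) <- levels(cellf)
    Z_list$ge <- Zge
  }
  fit <- fit_mixed_emreml(y, X, Z_list, tol = tol, max_iter = max_iter)

  ub <- unbalance_summary(tbl)
  var_ge <- if (single_env) NA_real_ else unname(fit$s2k["ge"])
  h2 <- heritability(unname(fit$s2k["g"]),
                     if (single_env) 0 else var_ge,
                     fit$s2e, ub$n_e, ub$n_r)
  list(var_g = unname(fit$s2k["g"]), var_ge = var_ge,
       var_residual = fit$s2e, n_e = ub$n_e, n_r = ub$n_r, H2 = h2,
       fit = fit)
}

#' Entry-mean heritability
#'
#' `H2 = var_g / (var_g + var_ge / n_e + var_residual / (n_e * n_r))`, with
#' `n_e` the average number of environments per line and `n_r` the average
#' number of replicates per line-by-environment cell.
#'
#' @param var_g,var_ge,var_residual variance components (>= 0).
#' @param n_e,n_r average numbers of environments and replicates (>= 1).
#' @return heritability in [0, 1].
#' @export
heritability <- function(var_g, var_ge, var_residual, n_e = 1, n_r = 1) {
  stopifnot(var_g >= 0, var_ge >= 0, var_residual >= 0, n_e >= 1, n_r >= 1)
  denom <- var_g + var_ge / n_e + var_residual / (n_e * n_r)
  if (denom == 0) stop("all variance components are zero")
  var_g / denom
}

#' Incidence unbalance summary
#'
#' `n_e` is the mean over lines of the number of distinct environments the
#' line appears in; `n_r` is the mean over observed line-by-environment
#' cells of the number of rows (replicates) in the cell.
#'
#' @param tbl data.frame with `line` and `env` columns (one row per plot or
#'   per replicate value).
#' @return list with `n_e` and `n_r`.
#' @export
unbalance_summary <- function(tbl) {
  stopifnot(nrow(tbl) > 0L, all(c("line", "env") %in% names(tbl)))
  key <- paste(tbl$line, tbl$env, sep = "\r")
  n_e <- mean(tapply(tbl$env, tbl$line, function(e) length(unique(e))))
  n_r <- mean(table(key))
  list(n_e = unname(n_e), n_r = unname(n_r))
}
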