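#' Configuration for the synthetic winter-wheat trial generator
#'
#' Defaults emulate the unbalanced, partially replicated multi-location
#' soft-white-winter-wheat trials the package targets: several hundred lines,
#' a handful of locations per year, each line grown in ~1.3-1.7 locations on
#' average, fewer than two replicates per line-by-location cell, polygenic
#' yield with moderately high entry heritability, strong location main
#' effects, and multispectral bands that track the plot's total
#' genetic + environmental value.
#'
#' Genetic variance is fixed at 1 (yield is generated on a unit-genetic-
#' variance scale); the residual variance is derived from `h2_target` as
#' `var_e = 1/h2 - 1 - var_ge`, so `h2_target` is the plot-level ratio
#' `var_g / (var_g + var_ge + var_e)`.
#'
#' @param n_lines number of breeding lines.
#' @param n_snps number of (clean) SNPs used to build genetic values.
#' @param n_envs number of environments (locations).
#' @param mean_envs_per_line target average number of environments per line
#'   (the Poisson mean of the truncated per-line environment-count draw).
#' @param replicate_fraction proportion of line-by-environment cells grown in
#'   two replicates (the rest get one plot).
#' @param h2_target plot-level narrow-sense heritability in (0, 1).
#' @param var_env variance of environment main effects (genetic-variance
#'   units).
#' @param var_ge genotype-by-environment variance; must satisfy
#'   `var_ge < 1/h2_target - 1`.
#' @param spectral_signal correlation in [0, 1] between band values and the
#'   plot's total genetic + environmental value.
#' @param design `"alpha_lattice"` or `"augmented"`.
#' @param missing_marker_rate proportion of marker calls set missing.
#' @param bad_snp_fraction fraction (of `n_snps`) of extra injected SNPs that
#'   deliberately fail quality control (monomorphic, >50% missing, >5%
#'   heterozygous, in rotation).
#' @param n_checks number of replicated check lines (augmented design).
#' @param n_pixels pixel samples per plot in the pixel table.
#' @param block_size plots per incomplete block.
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 400L, n_snps = 1000L, n_envs = 4L,
                       mean_envs_per_line = 1.5, replicate_fraction = 0.5,
                       h2_target = 0.66, var_env = 2, var_ge = 0.3,
                       spectral_signal = 0.8,
                       design = c("alpha_lattice", "augmented"),
                       missing_marker_rate = 0.05, bad_snp_fraction = 0.03,
                       n_checks = 3L, n_pixels = 16L, block_size = 10L,
                       seed = 1L) {
  design <- match.arg(design)
  stopifnot(n_lines >= 2L, n_snps >= 1L, n_envs >= 1L,
            replicate_fraction >= 0, replicate_fraction <= 1,
            missing_marker_rate >= 0, missing_marker_rate < 1,
            bad_snp_fraction >= 0, bad_snp_fraction <= 1,
            spectral_signal >= 0, spectral_signal <= 1,
            h2_target > 0, h2_target < 1, var_env >= 0, var_ge >= 0)
  if (mean_envs_per_line > n_envs) {
    stop("impossible configuration: mean_envs_per_line (",
         mean_envs_per_line, ") exceeds n_envs (", n_envs, ")")
  }
  if (mean_envs_per_line < 1) {
    stop("impossible configuration: mean_envs_per_line must be >= 1")
  }
  var_e <- 1 / h2_target - 1 - var_ge
  if (var_e <= 0) {
    stop("impossible configuration: var_ge too large for h2_target ",
         "(need var_ge < 1/h2_target - 1 = ", 1 / h2_target - 1, ")")
  }
  structure(list(n_lines = as.integer(n_lines), n_snps = as.integer(n_snps),
                 n_envs = as.integer(n_envs),
                 mean_envs_per_line = mean_envs_per_line,
                 replicate_fraction = replicate_fraction,
                 h2_target = h2_target, var_env = var_env, var_ge = var_ge,
                 var_e = var_e, spectral_signal = spectral_signal,
                 design = design,
                 missing_marker_rate = missing_marker_rate,
                 bad_snp_fraction = bad_snp_fraction,
                 n_checks = as.integer(n_checks),
                 n_pixels = as.integer(n_pixels),
                 block_size = as.integer(block_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# plausible mean reflectance and sensitivity of each band to canopy state;
# healthy/denser canopies absorb red and reflect NIR, so visible bands load
# negatively and NIR-side bands positively.
BAND_BASE <- c(Blue = 0.06, Green = 0.11, Red = 0.09, RE1 = 0.20,
               RE2 = 0.32, B900 = 0.42, B975 = 0.40, NIR = 0.48)
BAND_LOAD <- c(Blue = -0.012, Green = -0.018, Red = -0.030, RE1 = 0.025,
               RE2 = 0.050, B900 = 0.070, B975 = 0.065, NIR = 0.090)
# true affine DN map per band: DN = (SR - intercept) / slope
PANEL_SLOPE <- c(Blue = 6e-4, Green = 6.5e-4, Red = 7e-4, RE1 = 7.5e-4,
                 RE2 = 8e-4, B900 = 8.5e-4, B975 = 9e-4, NIR = 1e-3)
PANEL_INTERCEPT <- c(Blue = 0.004, Green = -0.003, Red = 0.002, RE1 = -0.005,
                     RE2 = 0.006, B900 = -0.002, B975 = 0.003, NIR = -0.004)
PANEL_REFLECTANCE <- c(0.02, 0.10, 0.30, 0.60, 0.85)

#' Generate a complete synthetic trial bundle
#'
#' Draws, from a single seed, a self-consistent dataset: a pre-QC marker
#' matrix (independent binomial(2, p) SNPs, allele frequencies in
#' [0.05, 0.5], plus injected filter-failing SNPs and missing calls),
#' polygenic genetic values `g = M beta` rescaled to unit variance,
#' environment, G-by-E, design and residual effects composing plot yield,
#' a plot table under the configured field design, pixel-level band digital
#' numbers whose underlying reflectance is an affine function of the plot's
#' standardized total value mixed with independent noise at
#' `spectral_signal`, and a calibration-panel table obtained by inverting
#' the known affine DN map (5 panels at 2-85% reflectance). The `truth`
#' element records every latent quantity and the realized variance
#' components.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle` with elements `markers`, `plot_table`,
#'   `pixel_table`, `panel_table`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  lines <- sprintf("L%04d", seq_len(cf$n_lines))
  envs <- sprintf("E%02d", seq_len(cf$n_envs))

  ## markers: independent per-SNP draws with allele frequency p in
  ## [0.05, 0.5]; lines are inbred, so calls are homozygous (0/2) apart
  ## from a small residual heterozygosity rate
  het_rate <- 0.01
  p <- stats::runif(cf$n_snps, 0.05, 0.5)
  M <- vapply(p, function(pp) 2 * stats::rbinom(cf$n_lines, 1L, pp),
              numeric(cf$n_lines))
  n_het <- round(het_rate * length(M))
  if (n_het > 0) M[sample(length(M), n_het)] <- 1
  dimnames(M) <- list(lines, sprintf("S%05d", seq_len(cf$n_snps)))

  ## genetic values from the clean codes, rescaled to unit variance
  beta <- stats::rnorm(cf$n_snps)
  g <- drop(M %*% beta)
  g <- (g - mean(g)) / stats::sd(g)
  names(g) <- lines

  ## inject missingness and filter-failing SNPs into the released matrix
  M_rel <- M
  if (cf$missing_marker_rate > 0) {
    holes <- which(stats::runif(length(M_rel)) < cf$missing_marker_rate)
    M_rel[holes] <- NA_real_
  }
  n_bad <- round(cf$bad_snp_fraction * cf$n_snps)
  if (n_bad > 0) {
    kinds <- rep(c("mono", "miss", "het"), length.out = n_bad)
    bad <- vapply(seq_len(n_bad), function(j) {
      col <- switch(kinds[j],
        mono = rep(2, cf$n_lines),
        miss = {
          v <- stats::rbinom(cf$n_lines, 2L, 0.3)
          v[sample(cf$n_lines, ceiling(0.6 * cf$n_lines))] <- NA_real_
          v
        },
        het = {
          v <- stats::rbinom(cf$n_lines, 2L, 0.3)
          v[sample(cf$n_lines, ceiling(0.15 * cf$n_lines))] <- 1
          v
        })
      as.numeric(col)
    }, numeric(cf$n_lines))
    colnames(bad) <- sprintf("BAD%03d", seq_len(n_bad))
    M_rel <- cbind(M_rel, bad)
  }

  ## unbalanced incidence: per-line environment subsets of size
  ## ~ Poisson(mean) truncated to [1, n_envs]
  k_env <- pmin(pmax(stats::rpois(cf$n_lines,
                                  cf$mean_envs_per_line - 1) + 1L, 1L),
                cf$n_envs)
  env_of <- lapply(k_env, function(k) sample(envs, k))
  ## guarantee every environment is populated
  for (e in envs) {
    if (!any(vapply(env_of, function(s) e %in% s, TRUE))) {
      i <- sample(cf$n_lines, 1L)
      env_of[[i]] <- unique(c(env_of[[i]], e))
    }
  }

  env_eff <- stats::rnorm(cf$n_envs, 0, sqrt(cf$var_env))
  names(env_eff) <- envs

  cells <- data.frame(
    line = rep(lines, vapply(env_of, length, 0L)),
    env = unlist(env_of), stringsAsFactors = FALSE)
  cells <- cells[order(cells$env, cells$line), , drop = FALSE]
  ge <- stats::rnorm(nrow(cells), 0, sqrt(cf$var_ge))
  cells$ge <- ge
  cells$n_rep <- 1L + (stats::runif(nrow(cells)) < cf$replicate_fraction)

  checks <- if (cf$design == "augmented" && cf$n_checks > 0)
    lines[seq_len(cf$n_checks)] else character(0)

  ## plot layout per environment
  plot_rows <- list()
  mu <- 5  # overall mean on the unit-genetic-variance scale
  for (e in envs) {
    ce <- cells[cells$env == e, , drop = FALSE]
    if (cf$design == "alpha_lattice") {
      recs <- ce[rep(seq_len(nrow(ce)), ce$n_rep), c("line", "ge")]
      recs$rep <- unlist(lapply(ce$n_rep, seq_len))
      recs <- recs[order(recs$rep), , drop = FALSE]
      recs$block <- unlist(tapply(seq_len(nrow(recs)), recs$rep,
        function(ix) ceiling(sample(seq_along(ix)) / cf$block_size)))
      recs$is_check <- FALSE
    } else {
      ## augmented: unreplicated test entries in blocks, checks in every block
      tst <- ce[!ce$line %in% checks, , drop = FALSE]
      n_blocks <- max(1L, ceiling(nrow(tst) / cf$block_size))
      tst$block <- ceiling(sample(seq_len(nrow(tst))) / cf$block_size)
      tst$rep <- 1L
      tst$is_check <- FALSE
      chk_ge <- ce$ge[match(checks, ce$line)]
      chk_ge[is.na(chk_ge)] <- stats::rnorm(sum(is.na(chk_ge)), 0,
                                            sqrt(cf$var_ge))
      chk <- data.frame(line = rep(checks, each = n_blocks),
                        ge = rep(chk_ge, each = n_blocks),
                        block = rep(seq_len(n_blocks), length(checks)),
                        rep = 1L, is_check = TRUE)
      recs <- rbind(tst[, c("line", "ge", "rep", "block", "is_check")],
                    chk[, c("line", "ge", "rep", "block", "is_check")])
    }
    recs$env <- e
    recs$trial <- "T1"
    plot_rows[[e]] <- recs
  }
  plots <- do.call(rbind, plot_rows)
  rownames(plots) <- NULL

  ## design and residual effects
  var_rep <- 0.02; var_block <- 0.05
  repf <- interaction(plots$env, plots$rep, drop = TRUE)
  blkf <- interaction(plots$env, plots$rep, plots$block, drop = TRUE)
  rep_eff <- stats::rnorm(nlevels(repf), 0, sqrt(var_rep))
  blk_eff <- stats::rnorm(nlevels(blkf), 0, sqrt(var_block))
  resid <- stats::rnorm(nrow(plots), 0, sqrt(cf$var_e))
  plots$yield <- mu + env_eff[plots$env] + g[plots$line] + plots$ge +
    rep_eff[as.integer(repf)] + blk_eff[as.integer(blkf)] + resid
  plots$plot_id <- sprintf("P%05d", seq_len(nrow(plots)))
  plots <- plots[, c("plot_id", "env", "trial", "rep", "block", "line",
                     "is_check", "yield")]

  ## multispectral bands: reflectance = base + load * latent, where latent
  ## mixes the plot's standardized total value with independent noise
  ge_plot_val <- cells$ge[match(paste(plots$line, plots$env),
                                paste(cells$line, cells$env))]
  ge_plot_val[is.na(ge_plot_val)] <- 0  # checks added outside the cell draw
  total <- g[plots$line] + env_eff[plots$env] + ge_plot_val
  tv <- (total - mean(total)) / max(stats::sd(total), 1e-12)
  s <- cf$spectral_signal
  n_plot <- nrow(plots)
  plot_refl <- sapply(BAND_NAMES, function(b) {
    noise <- stats::rnorm(n_plot)
    latent <- s * tv + sqrt(1 - s^2) * noise
    pmin(pmax(BAND_BASE[[b]] + BAND_LOAD[[b]] * latent, 0.005), 1.2)
  })
  rownames(plot_refl) <- plots$plot_id

  ## pixel samples: plot reflectance + small pixel noise, encoded as DN by
  ## inverting the known affine calibration map
  px_id <- rep(plots$plot_id, each = cf$n_pixels)
  pixel_sd <- 0.004
  pix <- sapply(BAND_NAMES, function(b) {
    sr <- rep(plot_refl[, b], each = cf$n_pixels) +
      stats::rnorm(length(px_id), 0, pixel_sd)
    sr <- pmax(sr, 0.001)
    (sr - PANEL_INTERCEPT[[b]]) / PANEL_SLOPE[[b]]
  })
  pixel_table <- data.frame(plot_id = px_id, pix, check.names = FALSE)

  panel_table <- do.call(rbind, lapply(BAND_NAMES, function(b) {
    data.frame(band = b, reflectance = PANEL_REFLECTANCE,
               dn = (PANEL_REFLECTANCE - PANEL_INTERCEPT[[b]]) /
                 PANEL_SLOPE[[b]])
  }))

  ## realized plot-level variance components (environment main effects are
  ## fixed by convention, so h2 is within-environment)
  g_plot <- g[plots$line]
  ge_plot <- ge_plot_val
  realized <- list(var_g = stats::var(g_plot), var_ge = stats::var(ge_plot),
                   var_e = stats::var(resid))
  realized$h2 <- realized$var_g /
    (realized$var_g + realized$var_ge + realized$var_e)

  structure(list(
    markers = M_rel,
    plot_table = plots,
    pixel_table = pixel_table,
    panel_table = panel_table,
    truth = list(g = g, env_eff = env_eff,
                 cells = cells[, c("line", "env", "ge")],
                 beta = beta, mu = mu,
                 var_components = c(var_g = 1, var_env = cf$var_env,
                                    var_ge = cf$var_ge, var_e = cf$var_e,
                                    var_rep = var_rep,
                                    var_block = var_block),
                 realized = realized,
                 panel_slope = PANEL_SLOPE,
                 panel_intercept = PANEL_INTERCEPT),
    config = cf), class = "sim_bundle")
}

#' Realized incidence unbalance of a bundle
#'
#' `n_e` is the mean number of distinct environments per line; `n_r` the
#' mean number of replicate plots per observed line-by-environment cell.
#'
#' @param bundle a `sim_bundle` (or any list with a `plot_table`).
#' @return list with `n_e` and `n_r`.
#' @export
realized_unbalance <- function(bundle) {
  unbalance_summary(bundle$plot_table)
}

#' Write a bundle's tables to a directory as plain CSV/JSON
#'
#' Produces `plot_table.csv`, `markers.csv` (rows = lines, `NA` = missing),
#' `pixels.csv`, `panels.csv` and `truth.json`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$plot_table, file.path(dir, "plot_table.csv"),
                   row.names = FALSE)
  mk <- data.frame(line = rownames(bundle$markers), bundle$markers,
                   check.names = FALSE)
  utils::write.csv(mk, file.path(dir, "markers.csv"), row.names = FALSE)
  utils::write.csv(bundle$pixel_table, file.path(dir, "pixels.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$panel_table, file.path(dir, "panels.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- bundle$truth
    tr$g <- as.list(tr$g)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Per-cell (line-by-environment) mean yields from a plot table
#'
#' Averages replicate plots within each observed cell; the unit at which the
#' prediction models operate.
#'
#' @param plot_table data.frame with `line`, `env`, `yield`.
#' @return data.frame `line`, `env`, `y` (one row per observed cell).
#' @export
cell_means <- function(plot_table) {
  agg <- stats::aggregate(list(y = plot_table$yield),
                          by = plot_table[, c("line", "env")], mean)
  agg[order(agg$env, agg$line), , drop = FALSE]
}
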