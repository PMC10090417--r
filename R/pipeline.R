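#' End-to-end pipeline: simulate/load, calibrate, BLUEs, predictors, CV
#'
#' Runs the analysis stages in dependency order and persists every
#' intermediate table under `out_dir`:
#'
#' 1. data: either a [sim_config()] (synthetic bundle, written to
#'    `out_dir/data/`) or a directory of input CSVs
#'    (`plot_table.csv`, `markers.csv`, `pixels.csv`, `panels.csv`);
#' 2. markers: QC filter, imputation, GRM;
#' 3. spectral: calibration, indices, per-cell H/I features;
#' 4. BLUEs: per-environment mixed-model adjusted means, plus
#'    across-environment variance components and heritability;
#' 5. predictors + cross-validation for every requested `eta` / model /
#'    scheme combination.
#'
#' A machine-readable manifest of seeds and active design-decision toggles
#' is written to `manifest.json` (when jsonlite is installed).
#'
#' @param config list with elements: exactly one of `sim` (a [sim_config()])
#'   or `input_dir`; optional `etas` (default `c("ETA1","ETA2","ETA8")`),
#'   `models` (default `"pls"`), `schemes` (default `"7fcv"`),
#'   `loeo_etas` (default [loeo_predictors()] intersected with requested),
#'   `k` (outer folds, default 7), `seed` (default 1), `spectral_mode`
#'   (default `"panel"`), `impute_method`, `response` (`"blue"` to model
#'   per-environment BLUEs, `"cell_mean"` for raw cell means),
#'   `pls` / `gblup` control lists.
#' @param out_dir output directory.
#' @return list with `results` (data.frame of per-env and Global rows per
#'   run), `cv` (the raw `cv_result` objects), `varcomp`, `features`,
#'   `blues`, paths of everything written.
#' @export
run_pipeline <- function(config, out_dir = tempfile("gsfusion_run_")) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package needed to read a config file")
    config <- yaml::read_yaml(config)
    if (!is.null(config$sim)) config$sim <- do.call(sim_config, config$sim)
  }
  has_sim <- !is.null(config$sim)
  has_dir <- !is.null(config$input_dir)
  if (has_sim == has_dir) {
    stop("config must contain exactly one of `sim` or `input_dir`")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  stage <- "data"
  res <- tryCatch({
    if (has_sim) {
      bundle <- generate_dataset(config$sim)
      write_sim_bundle(bundle, file.path(out_dir, "data"))
      plot_table <- bundle$plot_table
      markers <- bundle$markers
      pixel_table <- bundle$pixel_table
      panel_table <- bundle$panel_table
    } else {
      dd <- config$input_dir
      if (!dir.exists(dd)) stop("input_dir does not exist: ", dd)
      plot_table <- utils::read.csv(file.path(dd, "plot_table.csv"),
                                    stringsAsFactors = FALSE)
      markers <- read_markers_csv(file.path(dd, "markers.csv"))
      pixel_table <- utils::read.csv(file.path(dd, "pixels.csv"),
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE)
      panel_table <- utils::read.csv(file.path(dd, "panels.csv"),
                                     stringsAsFactors = FALSE)
    }

    stage <- "markers"
    mk <- filter_snps(markers)
    mk <- impute_markers(mk, method = config$impute_method %||% "mean")
    grm <- compute_grm(mk)
    write_grm_csv(grm, file.path(out_dir, "grm.csv"))

    stage <- "spectral"
    feats <- build_spectral_features(
      pixel_table, panel_table, plot_table,
      mode = config$spectral_mode %||% "panel")
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)

    stage <- "blues"
    design <- if (has_sim) config$sim$design else
      config$design %||% "alpha_lattice"
    blues_list <- lapply(split(plot_table, plot_table$env), function(pe) {
      fb <- fit_blues(pe, design = design)
      data.frame(env = pe$env[1L], fb$blues)
    })
    blues <- do.call(rbind, c(blues_list, make.row.names = FALSE))
    utils::write.csv(blues, file.path(out_dir, "blues.csv"),
                     row.names = FALSE)
    vc_tbl <- data.frame(env = plot_table$env, line = plot_table$line,
                         value = plot_table$yield)
    vc <- estimate_variance_components(vc_tbl)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(vc[c("var_g", "var_ge", "var_residual",
                                "n_e", "n_r", "H2")],
                           file.path(out_dir, "varcomp.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    stage <- "cv"
    response <- config$response %||% "blue"
    obs <- if (response == "blue") {
      data.frame(line = blues$line, env = blues$env, y = blues$blue)
    } else {
      cm <- cell_means(plot_table)
      data.frame(line = cm$line, env = cm$env, y = cm$y)
    }
    obs <- obs[order(obs$env, obs$line), , drop = FALSE]
    obs <- obs[obs$line %in% rownames(grm), , drop = FALSE]
    rownames(obs) <- NULL

    etas <- config$etas %||% c("ETA1", "ETA2", "ETA8")
    models <- config$models %||% "pls"
    schemes <- config$schemes %||% "7fcv"
    cv_runs <- list()
    rows <- list()
    for (scheme in schemes) {
      ids <- if (scheme == "loeo") config$loeo_etas %||% c("g", "H", "gH")
        else etas
      for (eta in ids) {
        ps <- build_predictor(eta, grm, obs, features = feats)
        for (model in models) {
          cv <- if (scheme == "7fcv") {
            run_7fcv(obs, ps, model = model, k = config$k %||% 7L,
                     seed = seed, pls_control = config$pls %||% list(),
                     gblup_control = config$gblup %||% list())
          } else {
            run_loeo(obs, ps, model = model, seed = seed,
                     pls_control = config$pls %||% list(),
                     gblup_control = config$gblup %||% list())
          }
          tag <- paste(scheme, model, eta, sep = "_")
          cv_runs[[tag]] <- cv
          rows[[tag]] <- rbind(
            data.frame(scheme = scheme, model = model, eta = eta,
                       env = cv$per_env$env, cor = cv$per_env$cor,
                       se = cv$per_env$se),
            data.frame(scheme = scheme, model = model, eta = eta,
                       env = "Global", cor = cv$global, se = cv$global_se))
          utils::write.csv(cv$predictions,
                           file.path(out_dir,
                                     paste0("predictions_", tag, ".csv")),
                           row.names = FALSE)
        }
      }
    }
    results <- do.call(rbind, c(rows, make.row.names = FALSE))
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)

    manifest <- list(
      seed = seed,
      stages = c("data", "markers", "spectral", "blues", "cv"),
      decisions = list(
        impute_method = config$impute_method %||% "mean",
        grm_centered = FALSE,
        spectral_mode = config$spectral_mode %||% "panel",
        canopy_cover = "mean_gndvi",
        index_source = "plot_mean_bands",
        nrmse_denominator = "sd",
        feature_standardization = TRUE,
        response = response,
        fold_level = "observation",
        loeo_global = "pooled",
        heritability = "entry_mean"),
      etas = etas, models = models, schemes = schemes)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
    }
    list(results = results, cv = cv_runs, varcomp = vc, features = feats,
         blues = blues, grm = grm, out_dir = out_dir, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
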