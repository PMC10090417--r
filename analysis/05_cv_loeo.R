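#!/usr/bin/env Rscript
# Stage 5: tested-lines-in-UNtested-environments accuracy (leave one
# environment out). Evaluates the five environment-free predictor sets
# (genomics only, spectral only in its H and I versions, and the two
# fusions with the G-by-E kernel) on year 1 under both models, then
# compares against the 7FCV table from stage 4: predicting a whole held-out
# location is expected to be the harder problem wherever location main
# effects matter. Writes results/cv/loeo_results.csv.

library(gsfusion)

year_dir <- "results/sim/year1"
markers <- read_markers_csv(file.path(year_dir, "markers.csv"))
feats <- read.csv("results/features/year1_features.csv",
                  check.names = FALSE)
blues <- read.csv("results/blues/year1_blues.csv")

grm <- compute_grm(impute_markers(filter_snps(markers)))
obs <- data.frame(line = blues$line, env = blues$env, y = blues$blue)
obs <- obs[order(obs$env, obs$line), ]
rownames(obs) <- NULL

rows <- list()
for (id in loeo_predictors()) {
  ps <- build_predictor(id, grm, obs, feats)
  for (model in c("pls", "gblup")) {
    cv <- run_loeo(obs, ps, model = model, seed = 17,
                   pls_control = list(a_max = 12),
                   gblup_control = list(n_iter = 3000, burn_in = 1000))
    rows[[paste(model, id)]] <- rbind(
      data.frame(model = model, eta = id, env = cv$per_env$env,
                 cor = cv$per_env$cor, se = NA_real_),
      data.frame(model = model, eta = id, env = "Global",
                 cor = cv$global, se = cv$global_se))
    cat(sprintf("%-5s %-3s Global r = %.3f (per-env mean %.3f)\n",
                model, id, cv$global, cv$global_mean_env))
  }
}
res <- do.call(rbind, c(rows, make.row.names = FALSE))
dir.create("results/cv", showWarnings = FALSE, recursive = TRUE)
write.csv(res, "results/cv/loeo_results.csv", row.names = FALSE)

if (file.exists("results/cv/7fcv_results.csv")) {
  r7 <- read.csv("results/cv/7fcv_results.csv")
  m7 <- mean(r7$cor[r7$env == "Global"], na.rm = TRUE)
  ml <- mean(res$cor[res$env == "Global"], na.rm = TRUE)
  cat(sprintf("\nmean Global accuracy: 7FCV %.3f vs LOEO %.3f\n", m7, ml))
}
cat("full table written to results/cv/loeo_results.csv\n")
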