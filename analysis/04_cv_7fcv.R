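#!/usr/bin/env Rscript
# Stage 4: tested-lines-in-tested-environments accuracy (7-fold CV).
# For year 1, evaluate the nine multi-source predictor sets under both the
# kernel PLS model (components tuned by nested 10-fold NRMSE) and the
# Bayesian multi-kernel GBLUP (masked-response prediction, shortened chains
# at desk scale). Accuracy is the per-environment fold-average Pearson
# correlation and the Global correlation of per-line averages. Writes
# results/cv/7fcv_results.csv.

library(gsfusion)

year_dir <- "results/sim/year1"
markers <- read_markers_csv(file.path(year_dir, "markers.csv"))
plots <- read.csv(file.path(year_dir, "plot_table.csv"))
feats <- read.csv("results/features/year1_features.csv",
                  check.names = FALSE)
blues <- read.csv("results/blues/year1_blues.csv")

grm <- compute_grm(impute_markers(filter_snps(markers)))
obs <- data.frame(line = blues$line, env = blues$env, y = blues$blue)
obs <- obs[order(obs$env, obs$line), ]
rownames(obs) <- NULL

dir.create("results/cv", showWarnings = FALSE, recursive = TRUE)
rows <- list()
for (eta in paste0("ETA", 1:9)) {
  ps <- build_predictor(eta, grm, obs, feats)
  for (model in c("pls", "gblup")) {
    cv <- run_7fcv(obs, ps, model = model, seed = 11,
                   pls_control = list(a_max = 12),
                   gblup_control = list(n_iter = 3000, burn_in = 1000))
    rows[[paste(model, eta)]] <- rbind(
      data.frame(model = model, eta = eta, env = cv$per_env$env,
                 cor = cv$per_env$cor, se = cv$per_env$se),
      data.frame(model = model, eta = eta, env = "Global",
                 cor = cv$global, se = cv$global_se))
    cat(sprintf("%-5s %-5s Global r = %.3f (SE %.3f)\n", model, eta,
                cv$global, cv$global_se))
  }
}
res <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(res, "results/cv/7fcv_results.csv", row.names = FALSE)

glob <- res[res$env == "Global", ]
worst <- glob[order(glob$cor), ][1, ]
cat(sprintf("\nweakest predictor overall: %s under %s (r = %.3f)\n",
            worst$eta, worst$model, worst$cor))
cat("full table written to results/cv/7fcv_results.csv\n")
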