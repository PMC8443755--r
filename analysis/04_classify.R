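#!/usr/bin/env Rscript
# Stage 4: the classifier benchmark. For every algorithm in the zoo, choose
# the feature count by CV accuracy (cap 10), tune hyperparameters by
# exhaustive stratified-CV5 grid search, and evaluate once on the 20%
# protein-balanced holdout; a stratified dummy classifier is the baseline.
# Synthetic responses are balanced at their medians (their scale is
# arbitrary, unlike the published nM / percent cutoffs).

suppressPackageStartupMessages(library(acdtol))
seed <- 20260926

man <- run_pipeline(pipeline_config(
  out_dir = "results/classification", seed = seed, balance_cutoffs = TRUE,
  algorithms = c("LOG", "KRR", "LDA", "QDA", "SVC", "NuSVC", "POL3",
                 "KNN", "BNB", "GNB", "GPC"),
  responses = "soluble_fraction_pct",
  synth = synth_config(seed = seed)))

m <- man$metrics
hold <- m[m$split == "holdout" & m$algorithm != "DUMMY", ]
best <- hold[which.max(hold$accuracy), ]
message("holdout leaderboard (soluble fraction):")
for (i in order(-hold$accuracy)) {
  message(sprintf("  %-5s acc %.3f prec %.3f rec %.3f F1 %.3f",
                  hold$algorithm[i], hold$accuracy[i], hold$precision[i],
                  hold$recall[i], hold$f1[i]))
}
dummy <- m[m$algorithm == "DUMMY", ]
message(sprintf("dummy baseline: acc %.3f", dummy$accuracy[1]))
message("best model: ", best$algorithm, " (holdout accuracy ",
        best$accuracy, "); full table in results/classification/")
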