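#!/usr/bin/env Rscript
# Stage 5: feature importance of the tuned logistic model, normalised so the
# most important feature scores 100 and every other score is its percentage
# of that weight. Checks that the planted informative features carry the
# signal.

suppressPackageStartupMessages(library(acdtol))
imp_file <- "results/classification/importance_soluble_fraction_pct.csv"
if (!file.exists(imp_file)) stop("run analysis/04_classify.R first")
imp <- read.csv(imp_file)
imp <- imp[order(-imp$importance), ]
message("logistic feature importance (top 100 = most important):")
for (i in seq_len(nrow(imp))) {
  message(sprintf("  %-10s %6.1f", imp$feature[i], imp$importance[i]))
}
planted <- c("feat_01", "feat_02", "feat_03")
hit <- intersect(imp$feature[imp$importance > 50], planted)
message(length(hit), " of the 3 planted informative features score above ",
        "half the top weight (", paste(hit, collapse = ", "), ")")
write.csv(imp, "results/importance_ranked.csv", row.names = FALSE)
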