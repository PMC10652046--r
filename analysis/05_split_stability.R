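#!/usr/bin/env Rscript
# Step 5 — split-stability diagnostic.
#
# The factorial design is exhaustive, so the models are trained on all data;
# as a stability check this profiles held-out R^2 over 50 random 80/20
# train/test splits of each emergent property's modelling table.

library(factorscreen)

if (!file.exists("results/measurements.csv")) {
  stop("run analysis/01_simulate.R first")
}
meas <- read_measurements("results/measurements.csv")
design <- enumerate_design()
avg <- average_replicates(apply_viability_mask(design, meas))
tf <- default_transforms()
seed <- 2026L

rows <- list()
for (prop in unique(avg$property)) {
  sub <- avg[avg$property == prop, ]
  sub$value <- apply_transform(sub$value, tf[[prop]])
  X <- encode_one_hot(sub, response = "value")
  res <- split_evaluate(X, n_splits = 50, train_fraction = 0.8,
                        seed = seed + length(rows))
  rows[[prop]] <- data.frame(
    response = prop, n_splits = length(res$r2_test),
    n_skipped = res$n_skipped,
    mean_r2 = res$summary["mean"], sd_r2 = res$summary["sd"],
    min_r2 = res$summary["min"], max_r2 = res$summary["max"]
  )
  cat(sprintf("%-13s held-out R2: mean %.2f (sd %.2f, range %.2f..%.2f, %d splits)\n",
              prop, res$summary["mean"], res$summary["sd"],
              res$summary["min"], res$summary["max"], length(res$r2_test)))
}
tab <- do.call(rbind, rows)
write.table(tab, "results/split_stability.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Wrote results/split_stability.tsv\n")
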