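#!/usr/bin/env Rscript
# Step 1 — generate the synthetic inhibitor screen.
#
# Simulates the 2^5 factorial screen (inhibitors U, S, L, R, P; days 2/4/6;
# 3 replicates) from the screen-like ground truth: negative main effects on
# cell number and proliferation (largest for R), a synergistic L:R
# interaction on proliferation and apoptosis, antagonistic U:P and R:P
# interactions on cell number, the L+R lethality rule after day 2, and a
# seven-gene panel with correlated noise. Writes the long-format tables the
# later steps read.

library(factorscreen)

seed <- 2026L
dir.create("results", showWarnings = FALSE)

ds <- make_screen_fixture(seed = seed)
write_measurements(ds$measurements, "results/measurements.csv")
write_expression(ds$expression, "results/expression.csv")

cat("Simulated screen (seed ", seed, "):\n", sep = "")
cat(" ", nrow(ds$measurements), "measurement rows across",
    length(unique(ds$measurements$condition)), "conditions\n")
cat(" ", nrow(ds$expression), "expression rows for",
    length(unique(ds$expression$gene)), "genes\n")
lr <- unique(ds$measurements$condition[
  grepl("L", ds$measurements$condition) & grepl("R", ds$measurements$condition)])
cat("  L+R conditions present only at day 2 (lethality rule):",
    length(lr), "conditions\n")

truth <- ds$truth
cat("\nPlanted interactions:\n")
print(truth$interactions, row.names = FALSE)
cat("\nWrote results/measurements.csv and results/expression.csv\n")
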