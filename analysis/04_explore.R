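#!/usr/bin/env Rscript
# Step 4 — unsupervised structure in the paired day-6 condition matrix.
#
# Builds the condition x variable matrix (four emergent properties plus the
# seven-gene panel at day 6), computes the Pearson correlation matrix with
# rank-based significance and hierarchical ordering, a z-scored PCA, and
# silhouette-guided k-means clustering of the conditions.

library(factorscreen)

if (!file.exists("results/measurements.csv")) {
  stop("run analysis/01_simulate.R first")
}
meas <- read_measurements("results/measurements.csv")
expr <- read_expression("results/expression.csv")
design <- enumerate_design()
avg <- average_replicates(apply_viability_mask(design, meas))
seed <- 2026L

day6 <- avg[avg$day == 6, ]
M <- reshape(day6[c("condition", "property", "value")], idvar = "condition",
             timevar = "property", direction = "wide")
names(M) <- sub("^value\\.", "", names(M))
E <- aggregate(log2fc ~ condition + gene, data = expr[expr$day == 6, ], FUN = mean)
Ew <- reshape(E, idvar = "condition", timevar = "gene", direction = "wide")
names(Ew) <- sub("^log2fc\\.", "", names(Ew))
M <- merge(M, Ew, by = "condition")
rownames(M) <- M$condition
M <- as.matrix(M[, -1])
cat("Paired day-6 matrix:", nrow(M), "conditions x", ncol(M), "variables\n")

cm <- correlation_matrix(M)
ord <- cm$ordering
write.csv(round(cm$r[ord, ord], 4), "results/correlation_r.csv")
write.csv(signif(cm$p[ord, ord], 4), "results/correlation_p.csv")
cat(sprintf("Rex1-Oct4 r = %.2f (p = %.3g); Dnmt3b-Fgf5 r = %.2f (p = %.3g)\n",
            cm$r["Rex1", "Oct4"], cm$p["Rex1", "Oct4"],
            cm$r["Dnmt3b", "Fgf5"], cm$p["Dnmt3b", "Fgf5"]))

pca <- pca_zscore(M)
cat(sprintf("PCA: PC1 %.0f%%, PC2 %.0f%% of variance\n",
            100 * pca$variance_explained[1], 100 * pca$variance_explained[2]))

cl <- cluster_with_silhouette(scale(M), k_range = 2:6, n_starts = 25,
                              seed = seed)
cat("Silhouette by k:\n")
print(round(cl$silhouette_by_k, 3))
cat("Chosen k =", cl$chosen_k, "\n")
assign_tab <- data.frame(condition = rownames(M),
                         cluster = cl$assignments,
                         silhouette = round(cl$silhouette, 3),
                         PC1 = round(pca$scores[, 1], 3),
                         PC2 = round(pca$scores[, 2], 3))
write.csv(assign_tab, "results/clusters.csv", row.names = FALSE)
for (k in sort(unique(cl$assignments))) {
  members <- rownames(M)[cl$assignments == k]
  cat(sprintf("cluster %d (%d conditions): %s\n", k, length(members),
              paste(members, collapse = " ")))
}
cat("Wrote results/correlation_{r,p}.csv and results/clusters.csv\n")
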