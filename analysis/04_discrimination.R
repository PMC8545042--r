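#!/usr/bin/env Rscript
# Group discrimination over the cortical cluster read-outs produced by
# 03_cluster_pipeline.R: per-read-out group statistics, t-tests and ROC
# AUCs, then the five-parameter principal component analysis with
# KMO/Bartlett gating and varimax rotation.

library(taurefkin)

readouts <- read_tsv("results/cluster_readouts.tsv")
names(readouts) <- sub("^slope_(\\d+)_(\\d+)$", "slope_\\1_\\2",
                       names(readouts))
cortical <- readouts[readouts$class == "cortical", ]

rep <- discrimination_report(cortical, cortical$group)
write_tsv(rep$stats, "results/discrimination_stats.tsv")

cat("Per-read-out discrimination of 3/4R vs 4R (cortical clusters):\n")
print(rep$stats[, c("readout", "mean_1", "sd_1", "mean_2", "sd_2", "p",
                    "auc")], digits = 3, row.names = FALSE)

if (!inherits(rep$pca, "pca_skipped")) {
  pca <- rep$pca
  cat(sprintf("\nPCA of {%s}:\n", paste(rep$pca_variables, collapse = ", ")))
  cat(sprintf("  KMO %.3f; Bartlett chi2 %.1f (df %d, p %.2g)\n",
              pca$kmo, pca$bartlett$statistic, pca$bartlett$df,
              pca$bartlett$p))
  cat(sprintf("  Eigenvalues: %s; %d component(s) above 1.0 explain %.1f%% of variance\n",
              paste(sprintf("%.3f", pca$eigenvalues), collapse = ", "),
              pca$n_retained, 100 * pca$var_explained))
  for (j in seq_len(pca$n_retained)) {
    cat(sprintf("  AUC of component %d: %.3f\n", j,
                pca$component_auc[[j]]$auc))
  }
  jsonlite::write_json(
    list(variables = pca$variables, discarded = pca$discarded,
         kmo = pca$kmo, bartlett = pca$bartlett,
         eigenvalues = pca$eigenvalues, n_retained = pca$n_retained,
         var_explained = pca$var_explained,
         rotated_loadings = as.data.frame(pca$rotated_loadings),
         component_auc = lapply(pca$component_auc, function(a) a$auc)),
    "results/pca_block.json", auto_unbox = TRUE, digits = 6, pretty = TRUE)
  cat("Wrote results/discrimination_stats.tsv and results/pca_block.json\n")
} else {
  cat("PCA skipped:", rep$pca$message, "\n")
}
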