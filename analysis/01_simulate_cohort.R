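#!/usr/bin/env Rscript
# Simulate the default synthetic cohort (11 healthy controls, 10 3/4R-like
# and 29 4R-like subjects) and record the per-subject ground truth: which
# regions carry lesions, their sizes and their kinetic parameters.  The
# dynamic images themselves are regenerated on demand by later stages (the
# generator is deterministic under the per-subject seeds), so only the
# truth tables are written here.

library(taurefkin)

seed <- 1
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec()
atlas <- phantom_atlas()
manifest <- cohort_manifest(spec, seed = seed)
write_tsv(manifest, "results/cohort_manifest.tsv")

truth <- list()
for (i in seq_len(nrow(manifest))) {
  sub <- simulate_subject(atlas, spec, manifest$group[i],
                          seed = manifest$seed[i])
  if (nrow(sub$lesions) > 0) {
    les <- sub$lesions
    les$subject <- manifest$subject[i]
    les$group <- manifest$group[i]
    les$k2prime_true <- sub$k2prime_true
    truth[[i]] <- les
  }
}
truth <- do.call(rbind, truth)
write_tsv(truth, "results/lesion_truth.tsv")

cat(sprintf("Simulated %d subjects (%s).\n", nrow(manifest),
            paste(sprintf("%s n=%d", names(table(manifest$group)),
                          table(manifest$group)), collapse = ", ")))
cat(sprintf("Painted %d lesions: %d cortical, %d subcortical.\n",
            nrow(truth), sum(truth$class == "cortical"),
            sum(truth$class == "subcortical")))
cat(sprintf("Mean lesion DVR: 3/4R cortical %.2f, 4R cortical %.2f.\n",
            mean(truth$DVR[truth$group == "3/4R" &
                             truth$class == "cortical"]),
            mean(truth$DVR[truth$group == "4R" &
                             truth$class == "cortical"])))
cat("Wrote results/cohort_manifest.tsv and results/lesion_truth.tsv\n")
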