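#!/usr/bin/env Rscript
# Stage 3: the repeated stratified multi-class linear-SVM ensembles.
#
# 500 stratified 70/30 resamples, one-vs-one linear SVMs with loss-weighted
# decoding, majority-vote final labels. Three evaluations mirror the study
# design: the pattern-based classifier (derivation subjects train-only), the
# ROI-based classifier on the full cohort, and the ROI-based classifier on
# the reduced dataset. All share one split-scheme seed so the comparison is
# split-for-split.

library(petdx)

cohort <- readRDS("scratch/cohort.rds")
feats <- readRDS("scratch/features.rds")
leakage <- cohort$subjects$id[cohort$subjects$leakage]

scheme_leak <- split_scheme(500, leakage_ids = leakage, master_seed = 2024)
scheme_full <- split_scheme(500, master_seed = 2024)
roi_all <- feature_matrix(feats$roi_fm$values, feats$roi_fm$class_labels, FALSE)

ens <- list(
  pattern      = run_ensemble(feats$pattern_fm, scheme_leak),
  roi_full     = run_ensemble(roi_all, scheme_full),
  roi_reduced  = run_ensemble(feats$roi_fm, scheme_leak))
reports <- list(
  pattern     = evaluate_ensemble(ens$pattern, feats$pattern_fm),
  roi_full    = evaluate_ensemble(ens$roi_full, roi_all),
  roi_reduced = evaluate_ensemble(ens$roi_reduced, feats$roi_fm))
saveRDS(list(ensembles = ens, reports = reports), "scratch/classify.rds")

perf <- do.call(rbind, lapply(names(reports), function(nm)
  cbind(model = nm, n = reports[[nm]]$n, metrics_table_row(reports[[nm]]))))
write.csv(perf, "results/performance.csv", row.names = FALSE)

for (nm in names(reports)) {
  r <- reports[[nm]]
  cat(sprintf("\n%s (n = %d): overall accuracy %d%%\n", nm, r$n,
              percent(r$overall_accuracy)))
  print(r$per_class, digits = 2, row.names = FALSE)
  write.csv(as.data.frame(unclass(r$confusion)),
            sprintf("results/confusion_%s.csv", nm))
}
cat("\nWrote results/performance.csv\n")
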