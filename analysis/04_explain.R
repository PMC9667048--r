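#!/usr/bin/env Rscript
# Stage 4: model explanation of the ROI-based classifier.
#
# (1) NCA feature weights on the full dataset (L-BFGS, lambda by
#     cross-validated 1-NN loss) rank the regions;
# (2) the per-iteration feature-selection frequency histogram;
# (3) per-class F1 as a function of the number of top-ranked regions;
# (4) Shapley attributions of the per-class decoded scores, aggregated into
#     class-specific regional importance maps (written as NIfTI volumes).

library(petdx)

cohort <- readRDS("scratch/cohort.rds")
feats <- readRDS("scratch/features.rds")
roi_fm <- feats$roi_fm

X <- scale(roi_fm$values)
sel <- select_lambda(X, roi_fm$class_labels, c(0.005, 0.02, 0.08), n_folds = 5,
                     seed = 11)
cat(sprintf("lambda* = %g (CV 1-NN loss %.3f)\n", sel$lambda,
            min(sel$losses$mean_loss)))
nca <- fit_nca(X, roi_fm$class_labels, sel$lambda)
ranked <- names(sort(nca$w, decreasing = TRUE))
write.csv(data.frame(feature = names(nca$w), weight = nca$w,
                     row.names = NULL),
          "results/nca_weights.csv", row.names = FALSE)
cat("NCA ranking:", paste(ranked, collapse = " > "), "\n")

freq <- selection_frequency(roi_fm, split_scheme(50, master_seed = 2024),
                            lambda = sel$lambda)
write.csv(data.frame(feature = names(freq$frequency),
                     frequency = freq$frequency, row.names = NULL),
          "results/selection_frequency.csv", row.names = FALSE)

topk <- f1_vs_topk(roi_fm, ranked, split_scheme(100, master_seed = 2024))
write.csv(topk$curve, "results/f1_vs_topk.csv", row.names = FALSE)
cat("Smallest k attaining the maximal F1 per class:\n")
print(topk$best_k)

shap <- ensemble_shap_importance(
  feature_matrix(roi_fm$values, roi_fm$class_labels, FALSE),
  split_scheme(500, master_seed = 2024), n_runs = 5, n_samples = 100,
  seed = 33, subjects_per_run = 20)
write.csv(shap, "results/shapley_values.csv", row.names = FALSE)
imp <- class_importance_map(shap, cohort$atlas)
write.csv(data.frame(feature = rownames(imp$values), imp$values,
                     check.names = FALSE),
          "results/importance.csv", row.names = FALSE)
dir.create("scratch/importance_maps", showWarnings = FALSE)
for (cl in colnames(imp$values))
  write_volume_nifti(pet_volume(imp$maps[[cl]], cohort$atlas$spacing_mm,
                                cohort$atlas$labels > 0),
                     sprintf("scratch/importance_maps/%s.nii.gz", cl))

cat("\nTop-2 regions per class by mean |Shapley| value:\n")
for (cl in colnames(imp$values)) {
  top <- rownames(imp$values)[order(imp$values[, cl], decreasing = TRUE)[1:2]]
  cat(sprintf("  %-3s : %s\n", cl, paste(top, collapse = ", ")))
}
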