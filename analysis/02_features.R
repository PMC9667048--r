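#!/usr/bin/env Rscript
# Stage 2: preprocessing, pattern derivation and feature extraction.
#
# Every scan is smoothed (10 mm FWHM, mask-renormalized) and scaled to unit
# global uptake. Four metabolic patterns are derived by SSM/PCA from the
# derivation subjects only (ADRP/DLBRP/FTDRP vs the NC identification cohort,
# plus a pooled dementia-vs-NC stand-in for the healthy resting-state
# pattern), and two feature sets are extracted: the 4 pattern-expression
# Z-scores and the 8 regional uptake ratios.

library(petdx)

cohort <- readRDS("scratch/cohort.rds")
volumes <- lapply(cohort$volumes, preprocess_volume, fwhm_mm = 10)

ids <- split(cohort$subjects$id[cohort$subjects$leakage],
             cohort$subjects$class[cohort$subjects$leakage])
patterns <- list(
  derive_pattern(volumes[ids$AD], volumes[ids$NC], name = "ADRP"),
  derive_pattern(volumes[ids$DLB], volumes[ids$NC], name = "DLBRP"),
  derive_pattern(volumes[ids$FTD], volumes[ids$NC], name = "FTDRP"),
  derive_pattern(volumes[c(ids$AD, ids$DLB, ids$FTD)], volumes[ids$NC],
                 name = "DMN"))
for (p in patterns)
  cat(sprintf("%-6s component %d, %4.1f%% of SRP variance, |t| = %.1f\n",
              p$name, p$meta$component, 100 * p$meta$var_explained,
              abs(p$meta$t_stat)))

pattern_fm <- pattern_feature_matrix(volumes, patterns, cohort$subjects)
roi_fm <- roi_feature_matrix(volumes, cohort$atlas, cohort$subjects)
write_feature_matrix(pattern_fm, "results/features_pattern.csv")
write_feature_matrix(roi_fm, "results/features_roi.csv")
saveRDS(list(patterns = patterns, pattern_fm = pattern_fm, roi_fm = roi_fm),
        "scratch/features.rds")

z_by_class <- aggregate(pattern_fm$values,
                        by = list(class = pattern_fm$class_labels), mean)
cat("\nMean pattern-expression Z by true class:\n")
print(z_by_class, digits = 2)
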