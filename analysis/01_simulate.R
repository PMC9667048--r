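#!/usr/bin/env Rscript
# Stage 1: simulate the four-class FDG-PET study cohort.
#
# 206 synthetic scans (63 AD, 79 DLB, 23 FTD, 41 NC) on a common 20^3 grid of
# 8 mm voxels, parcellated into 8 toy regions. Each dementia class carries a
# planted 25% hypometabolism in two disjoint regions; the first 20/20/10/29
# subjects per class are flagged as pattern-derivation (leakage) cases,
# mirroring the study's reduced-dataset bookkeeping.

library(petdx)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

spec <- cohort_spec(seed = 42)
cohort <- simulate_cohort(spec)
cohort$subjects <- flag_derivation_subjects(
  cohort$subjects, c(AD = 20, DLB = 20, FTD = 10, NC = 29))

write_subject_table(cohort$subjects, "results/subjects.csv")
sizes <- table(cohort$atlas$labels[cohort$atlas$labels > 0])
write.csv(data.frame(roi = cohort$atlas$label_table$name,
                     n_voxels = as.integer(sizes)),
          "results/atlas_parcels.csv", row.names = FALSE)
saveRDS(cohort, "scratch/cohort.rds")

cat(sprintf("Simulated %d subjects (%s)\n", nrow(cohort$subjects),
            paste(sprintf("%s=%d", names(table(cohort$subjects$class)),
                          table(cohort$subjects$class)), collapse = ", ")))
cat(sprintf("Derivation (leakage) subjects: %d; test-eligible: %d\n",
            sum(cohort$subjects$leakage), sum(!cohort$subjects$leakage)))
cat(sprintf("Atlas: %d parcels tiling %d mask voxels\n",
            nrow(cohort$atlas$label_table), sum(cohort$atlas$labels > 0)))
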