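#!/usr/bin/env Rscript
# Simulate the synthetic resting-state cohort used throughout the analysis:
# 41 "patients" and 41 "controls" (the recruitment shape of a typical
# tinnitus resting-state study), 240 volumes at TR = 2 s on a 24 x 28 x 24
# grid of 3 mm voxels.  Two regions carry planted band-limited signal:
#   * "frontal": higher amplitude in patients in both analysed bands
#     (a group main effect),
#   * "orbitofrontal": higher slow-4 amplitude in patients only
#     (a group x band interaction).
# THQ couples to frontal slow-4 amplitude and tinnitus duration to frontal
# slow-5 amplitude, both at r = 0.5.  Roughly 2 runs per group carry motion
# above the 2.0 mm / 2.0 degree limits.
#
# Writes: results/cohort/participants.tsv, motion summaries, one example
# subject's 4D NIfTI, and results/cache/cohort.rds for the later stages.

library(bandalff)

seed <- as.integer(Sys.getenv("BANDALFF_SEED", "20260925"))
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)

bands <- standard_bands()
spec <- synthetic_spec(
  n_group1 = 41L, n_group2 = 41L,
  grid_dims = c(24L, 28L, 24L), voxel_size_mm = 3,
  n_timepoints = 240L, tr_seconds = 2,
  roi_list = list(
    roi_box("frontal_slow-4", c(4, 18, 14), c(10, 24, 20), bands[["slow-4"]],
            base_amplitude = 1, group1_multiplier = 1.4,
            group2_multiplier = 1.0),
    roi_box("frontal_slow-5", c(4, 18, 14), c(10, 24, 20), bands[["slow-5"]],
            base_amplitude = 1, group1_multiplier = 1.4,
            group2_multiplier = 1.0),
    roi_box("orbitofrontal_slow-4", c(14, 6, 4), c(20, 12, 10),
            bands[["slow-4"]], base_amplitude = 1,
            group1_multiplier = 1.5, group2_multiplier = 1.0)),
  covariate_couplings = list(
    coupling_spec("thq", "frontal_slow-4", 0.5),
    coupling_spec("duration_months", "frontal_slow-5", 0.5)),
  noise_sd = 1, drift_slope_sd = 0.005,
  motion_outlier_fraction = 2 / 41,
  seed = substream_seed(seed, "cohort"))

cohort <- generate_cohort(spec)
saveRDS(list(spec = spec, cohort = cohort), "results/cache/cohort.rds")

write_pheno_tsv(cohort$pheno, "results/cohort/participants.tsv")
write_motion_text(cohort$motions[[1]], "results/cohort/sub-001_motion.txt")
write_bold_nifti(subject_run(cohort, 1), "results/cohort/sub-001_bold.nii.gz")

cat("Cohort:", nrow(cohort$pheno), "subjects (",
    sum(cohort$pheno$group == 1), "patients,",
    sum(cohort$pheno$group == 2), "controls )\n")
cat("Designated motion outliers:", sum(cohort$pheno$motion_outlier), "\n")
cat("Patient THQ: mean", round(mean(cohort$pheno$thq, na.rm = TRUE), 1),
    "sd", round(sd(cohort$pheno$thq, na.rm = TRUE), 1), "\n")
cat("Planted THQ ~ frontal slow-4 amplitude r:",
    round(cor(cohort$amplitudes[cohort$pheno$group == 1, "frontal_slow-4"],
              cohort$pheno$thq[cohort$pheno$group == 1]), 3), "\n")
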