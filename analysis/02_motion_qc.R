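#!/usr/bin/env Rscript
# Motion quality control: apply the strict > 2.0 mm / > 2.0 degree exclusion
# rule to every subject's realignment trace and record who survives.

library(bandalff)

stash <- readRDS("results/cache/cohort.rds")
cohort <- stash$cohort

keep <- screen_cohort_motion(cohort$motions)
details <- lapply(cohort$motions, screen_motion)

qc <- data.frame(
  subject_id = cohort$pheno$subject_id,
  group = cohort$pheno$group,
  retained = keep,
  reason = vapply(details, function(d)
    if (d$decision == "keep") "" else
      sprintf("%s axis %d = %.2f at volume %d", d$parameter, d$axis,
              d$value, d$timepoint), character(1)))
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write.table(qc, "results/qc/motion_qc.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
saveRDS(which(keep), "results/cache/retained.rds")

cat("Retained", sum(keep), "of", length(keep), "runs;",
    sum(cohort$pheno$group == 1 & keep), "patients and",
    sum(cohort$pheno$group == 2 & keep), "controls.\n")
print(qc[!qc$retained, c("subject_id", "group", "reason")], row.names = FALSE)
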