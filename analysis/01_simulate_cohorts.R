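#!/usr/bin/env Rscript
# Simulate the study cohorts: 66 healthy controls spanning a range of
# kidney function (for deriving the renal adjustment of HE4) and two
# endometrial-cancer cohorts (training n=120, validation n=240) with dMI
# outcomes drawn from the published continuous model.  Creatinine is
# back-solved from the drawn eGFR, so the downstream pipeline has to
# recompute eGFR itself.
#
#   Rscript analysis/01_simulate_cohorts.R [seed]

library(he4ren)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed)
controls <- generate_controls(cfg)

cfg_train <- generator_config(seed = seed + 1L, n_patients = 120L)
cfg_valid <- generator_config(seed = seed + 2L, n_patients = 240L)
training <- generate_ec_cohort(cfg_train, cohort_label = "training")
validation <- generate_ec_cohort(cfg_valid, cohort_label = "validation")

write_cohort(controls, "results/controls.csv")
write_cohort(training, "results/training.csv")
write_cohort(validation, "results/validation.csv")

cat(sprintf("controls: n=%d, eGFR range %.1f-%.1f, %d CKD-positive (<60)\n",
            nrow(controls), min(controls$egfr), max(controls$egfr),
            sum(controls$ckd_flag)))
for (d in list(training, validation)) {
  cat(sprintf(
    "%s: n=%d | median age %.0f, creatinine %.0f umol/l, HE4 %.1f pmol/l, CA125 %.1f U/ml | dMI %.1f%% | grades 1/2/3/NA: %d/%d/%d/%d\n",
    d$cohort[1], nrow(d), median(d$age), median(d$creatinine_umol_l),
    median(d$he4), median(d$ca125), 100 * mean(d$dmi),
    sum(d$grade == 1, na.rm = TRUE), sum(d$grade == 2, na.rm = TRUE),
    sum(d$grade == 3, na.rm = TRUE), sum(is.na(d$grade))))
}
cat("wrote results/{controls,training,validation}.csv\n")
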