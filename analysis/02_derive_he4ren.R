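#!/usr/bin/env Rscript
# Derive the renal adjustment of HE4 from the control cohort: refit the
# piecewise log-linear model of ln(HE4) on eGFR with the knot fixed at 90,
# compare raw and adjusted HE4 in their dependence on age, and compute the
# 95th-percentile reference value of HE4ren among CKD-positive controls.
#
#   Rscript analysis/02_derive_he4ren.R

library(he4ren)

controls <- read_cohort("results/controls.csv",
                        cohort_schema(required = c("age", "creatinine_umol_l",
                                                   "he4")))
controls$egfr <- egfr_ckd_epi_female(controls$age, controls$creatinine_umol_l)
fit <- fit_piecewise_loglinear(controls[, c("egfr", "he4")])
print(fit)
write_model_json(fit, "results/piecewise_fit.json")

# the frozen published constant, not the refit, defines the transform used
# downstream, so that the risk models match their published coefficients
adjusted <- adjust_cohort(controls)
write_cohort(adjusted, "results/controls_adjusted.csv")

rho_raw <- spearman_rho(adjusted$he4, adjusted$age)
rho_adj <- spearman_rho(adjusted$he4ren, adjusted$age)
cat(sprintf("Spearman rho vs age: raw HE4 %.3f, HE4ren %.3f\n",
            rho_raw, rho_adj))

ckd <- adjusted$egfr < 60
p95 <- percentile(adjusted$he4ren[ckd], 95)
cat(sprintf("95th percentile of HE4ren in %d CKD-positive controls: %.1f pmol/l\n",
            sum(ckd), p95))

write.csv(data.frame(
  quantity = c("slope_coeff_x100", "slope_ci_lo", "slope_ci_hi",
               "intercept_ln", "residual_sd", "rho_age_he4",
               "rho_age_he4ren", "p95_he4ren_ckd", "n_ckd"),
  value = c(fit$slope_coeff, fit$slope_ci, fit$intercept, fit$residual_sd,
            rho_raw, rho_adj, p95, sum(ckd))
), "results/he4ren_derivation.csv", row.names = FALSE)
cat("wrote results/piecewise_fit.json, results/controls_adjusted.csv, results/he4ren_derivation.csv\n")
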