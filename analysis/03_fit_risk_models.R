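#!/usr/bin/env Rscript
# Develop the dMI risk models on the training cohort: HE4ren adjustment,
# backward-elimination logistic regression on the grade 1-or-2 subset
# (continuous candidates: age, ln HE4ren, grade-1, ln CA125), then the
# categorical model on the published binary risk factors and its
# points-based score system with simplified weights.
#
#   Rscript analysis/03_fit_risk_models.R

library(he4ren)

ec_schema <- cohort_schema(
  required = c("age", "creatinine_umol_l", "he4", "ca125", "grade", "dmi"),
  numeric = c("age", "creatinine_umol_l", "he4", "ca125", "grade"))
training <- read_cohort("results/training.csv", ec_schema)
training$dmi <- training$dmi == "TRUE"
training <- adjust_cohort(training)
write_cohort(training, "results/training_adjusted.csv")

g12 <- training[!is.na(training$grade) & training$grade != 3, ]
cat(sprintf("training G1-or-G2 subset: n=%d (%d grade-3/missing rows set aside)\n",
            nrow(g12), nrow(training) - nrow(g12)))

# continuous model development
g12$log_he4ren <- log(g12$he4ren)
g12$log_ca125 <- log(g12$ca125)
g12$grade_num <- g12$grade - 1
cont <- fit_logistic_backward(
  g12, outcome = "dmi",
  candidates = c("age", "log_he4ren", "grade_num", "log_ca125"))
print(cont)
write_model_json(cont, "results/continuous_fit.json")

# categorical model: published binary factors, backward elimination with
# the same stay criterion, then coefficient-x10 scores
fac <- categorize_patient(g12)
dcat <- cbind(fac, dmi = g12$dmi)
catfit <- fit_logistic_backward(
  dcat, outcome = "dmi",
  candidates = c("grade2", "he4ren_high", "ca125_high", "age_high"))
print(catfit)
write_model_json(catfit, "results/categorical_fit.json")

if (!catfit$intercept_only) {
  sm <- derive_score_model(catfit)
  cat("score model (coefficient x 10):\n")
  print(sm$scores)
  cat("simplified weights (minor=1 / intermediate=2 / major=3):\n")
  print(sm$simplified_weights)
  write_model_json(sm, "results/score_model.json")
}

write_model_json(published_constants(), "results/published_constants.json")
cat("wrote results/{continuous_fit,categorical_fit,score_model,published_constants}.json\n")
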