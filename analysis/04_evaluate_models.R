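#!/usr/bin/env Rscript
# Evaluate the published continuous model and the simplified weighted
# classifier on the training cohort and the held-out validation cohort:
# ROC/AUC, confusion metrics at the working probability cut-offs
# (25%, 33%, 43%), the training-optimal cut-off, and ROC coordinates.
#
#   Rscript analysis/04_evaluate_models.R

library(he4ren)

ec_schema <- cohort_schema(
  required = c("age", "creatinine_umol_l", "he4", "ca125", "grade", "dmi"),
  numeric = c("age", "creatinine_umol_l", "he4", "ca125", "grade"))

evaluate_cohort <- function(path, label) {
  d <- read_cohort(path, ec_schema)
  d$dmi <- d$dmi == "TRUE"
  d <- adjust_cohort(d)
  g12 <- d[!is.na(d$grade) & d$grade != 3, ]
  p <- predict_dmi_continuous(g12$age, g12$he4ren, g12$grade)
  rep <- eval_report(p, g12$dmi)
  cat(sprintf("\n== %s (G1-or-G2 n=%d) ==\n", label, nrow(g12)))
  print(rep)
  simp <- classify_cohort(g12, model = "simplified")
  m <- confusion_metrics(as.integer(simp$risk == "high"), g12$dmi, 1)
  cat(sprintf("simplified classifier: sens %.3f, spec %.3f, ppv %.3f, npv %.3f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv))
  list(data = g12, p = p, report = rep, simplified = m)
}

train <- evaluate_cohort("results/training.csv", "training")
valid <- evaluate_cohort("results/validation.csv", "validation")

opt <- optimal_cutoff(train$p, train$data$dmi)
cat(sprintf("\ntraining-optimal probability cut-off (max sens+spec): %d%% (sum %.3f)\n",
            round(100 * as.numeric(opt)), attr(opt, "youden_sum")))

metrics <- rbind(
  cbind(cohort = "training", model = "continuous", train$report$metrics),
  cbind(cohort = "validation", model = "continuous", valid$report$metrics),
  cbind(cohort = "training", model = "simplified", train$simplified),
  cbind(cohort = "validation", model = "simplified", valid$simplified))
write.csv(metrics, "results/evaluation_metrics.csv", row.names = FALSE)
write.csv(roc_curve(valid$p, valid$data$dmi), "results/roc_validation.csv",
          row.names = FALSE)
write.csv(data.frame(
  quantity = c("auc_training", "auc_validation", "optimal_cutoff"),
  value = c(train$report$auc, valid$report$auc, as.numeric(opt))
), "results/evaluation_summary.csv", row.names = FALSE)
cat("wrote results/{evaluation_metrics,roc_validation,evaluation_summary}.csv\n")
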