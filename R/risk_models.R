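# Prediction of deep myometrial invasion (dMI, >= 50% of the uterine wall)
# in grade 1-or-2 endometrial cancer from age, renally adjusted HE4 and
# histological grade.  Grade 3 patients are managed as a high-risk group
# upstream and are never scored by these models.
#
# The published final continuous model is
#   P(dMI) = 1 / (1 + e^{15.2 - 0.1 age - 2.1 ln(HE4ren) - 0.9 (grade-1)})
# i.e. logit(P) = -15.2 + 0.1 age + 2.1 ln(HE4ren) + 0.9 (grade-1),
# with HE4ren in pmol/l and natural logarithms throughout.

#' Published final continuous dMI model coefficients (log-odds scale)
#'
#' Named vector: `intercept` = -15.2, `age` = 0.1 per year,
#' `log_he4ren` = 2.1 per natural-log unit, `grade` = 0.9 per grade step
#' above 1.
#' @export
DMI_CONTINUOUS_COEF <- c(intercept = -15.2, age = 0.1,
                         log_he4ren = 2.1, grade = 0.9)

#' Published categorical cut-offs and simplified weights
#'
#' Risk factors: grade 2, HE4ren >= 45 pmol/l, CA125 >= 35 U/ml,
#' age >= 60 years (all boundaries inclusive). Simplified weights:
#' grade 2 is a minor factor (1 point), elevated HE4ren and CA125 are
#' intermediate (2 points each), age >= 60 is major (3 points); a weighted
#' sum >= 4 classifies the patient as high-risk for dMI.
#' @export
DMI_CATEGORICAL_CUTOFFS <- list(he4ren = 45, ca125 = 35, age = 60)

#' @rdname DMI_CATEGORICAL_CUTOFFS
#' @export
DMI_SIMPLIFIED_WEIGHTS <- c(grade2 = 1, he4ren_high = 2,
                            ca125_high = 2, age_high = 3)

#' @rdname DMI_CATEGORICAL_CUTOFFS
#' @export
DMI_SIMPLIFIED_THRESHOLD <- 4

.check_grade_12 <- function(grade) {
  if (anyNA(grade)) {
    stop("grade is missing; the dMI models require a known grade",
         call. = FALSE)
  }
  if (any(grade == 3)) {
    stop("grade 3 patients are outside this model: they are managed as a ",
         "high-risk group without scoring", call. = FALSE)
  }
  if (!all(grade %in% c(1, 2))) {
    stop("grade must be 1 or 2", call. = FALSE)
  }
}

#' Probability of deep myometrial invasion (continuous model)
#'
#' Evaluates the final continuous logistic model for grade 1-or-2
#' endometrial cancer patients. The default coefficients are exactly the
#' published ones ([DMI_CONTINUOUS_COEF]); the HE4ren term uses the
#' natural logarithm.
#'
#' @param age Age in years.
#' @param he4ren Renally adjusted HE4 in pmol/l, positive.
#' @param grade Histological grade, 1 or 2. Grade 3 raises an error
#'   directing to the high-risk pathway.
#' @param coefficients Named vector with `intercept`, `age`, `log_he4ren`,
#'   `grade` entries on the log-odds scale.
#' @return Probability of dMI in (0, 1); strictly increasing in age,
#'   he4ren and grade under the default coefficients.
#' @examples
#' predict_dmi_continuous(65, 60.5, 1)  # 0.4789
#' predict_dmi_continuous(60, 45, 2)    # 0.4241
#' @export
predict_dmi_continuous <- function(age, he4ren, grade,
                                   coefficients = DMI_CONTINUOUS_COEF) {
  .check_grade_12(grade)
  if (!is.numeric(he4ren) || any(!is.finite(he4ren)) || any(he4ren <= 0)) {
    stop("he4ren must be positive and finite (pmol/l)", call. = FALSE)
  }
  lp <- coefficients[["intercept"]] + coefficients[["age"]] * age +
    coefficients[["log_he4ren"]] * log(he4ren) +
    coefficients[["grade"]] * (grade - 1)
  stats::plogis(lp)
}

#' Dichotomise a patient into the categorical risk factors
#'
#' Applies the published inclusive cut-offs: grade 2, HE4ren >= 45 pmol/l,
#' CA125 >= 35 U/ml, age >= 60 years.
#'
#' @param patients Data frame with columns `age`, `he4ren`, `ca125`,
#'   `grade` (1 or 2; grade 3 errors).
#' @param cutoffs List with entries `he4ren`, `ca125`, `age`; defaults
#'   [DMI_CATEGORICAL_CUTOFFS].
#' @return Data frame with integer 0/1 columns `grade2`, `he4ren_high`,
#'   `ca125_high`, `age_high`.
#' @examples
#' categorize_patient(data.frame(age = 60, he4ren = 45, ca125 = 35, grade = 2))
#' @export
categorize_patient <- function(patients, cutoffs = DMI_CATEGORICAL_CUTOFFS) {
  stopifnot(is.data.frame(patients))
  missing_cols <- setdiff(c("age", "he4ren", "ca125", "grade"),
                          names(patients))
  if (length(missing_cols) > 0) {
    stop("patients is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  .check_grade_12(patients$grade)
  data.frame(
    grade2      = as.integer(patients$grade == 2),
    he4ren_high = as.integer(patients$he4ren >= cutoffs$he4ren),
    ca125_high  = as.integer(patients$ca125 >= cutoffs$ca125),
    age_high    = as.integer(patients$age >= cutoffs$age)
  )
}

#' Backward-elimination binary logistic regression
#'
#' Fits a binary logistic model and iteratively removes the candidate
#' predictor with the largest Wald p-value exceeding `alpha_stay`,
#' refitting after each removal, until every retained predictor satisfies
#' p <= `alpha_stay`. Ties in the elimination p-value are broken by
#' removing the predictor with the smaller absolute standardised effect
#' (|coefficient| x predictor SD). Constant (zero-variance) candidates are
#' dropped up front with a log entry; rows with missing values in the
#' outcome or any candidate are dropped with a logged count.
#'
#' @param data Data frame containing `outcome` and all `candidates`.
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha_stay Significance level for a variable to remain in the
#'   model; default 0.1.
#' @return Object of class `fitted_logistic`: a coefficient table
#'   (estimate, SE, OR = exp(estimate), Wald 95% CI, p-value), the
#'   intercept row, the elimination trace (predictor, p at removal, step),
#'   counts of dropped rows/constant predictors, and the final `glm` fit.
#'   If every candidate is eliminated the intercept-only model is returned
#'   with `intercept_only = TRUE` (flagged, not an error).
#' @export
fit_logistic_backward <- function(data, outcome, candidates,
                                  alpha_stay = 0.1) {
  stopifnot(is.data.frame(data), is.character(outcome),
            is.character(candidates), length(candidates) >= 1)
  missing_cols <- setdiff(c(outcome, candidates), names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[, c(outcome, candidates), drop = FALSE])
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  y <- as.integer(data[[outcome]])
  if (!all(y %in% c(0L, 1L))) {
    stop("outcome must be binary (logical or 0/1)", call. = FALSE)
  }
  if (sum(y) < 10 || sum(1 - y) < 10) {
    stop("need at least 10 events and 10 non-events to fit", call. = FALSE)
  }
  # drop zero-variance candidates up front (they carry no information and
  # make the design singular)
  sds <- vapply(candidates, function(v) stats::sd(data[[v]]), numeric(1))
  constant_dropped <- candidates[sds == 0]
  current <- candidates[sds > 0]
  trace <- data.frame(predictor = character(0), p_at_removal = numeric(0),
                      step = integer(0), stringsAsFactors = FALSE)
  step <- 0L
  fit <- NULL
  repeat {
    rhs <- if (length(current) == 0) "1" else paste(current, collapse = " + ")
    form <- stats::as.formula(paste0("y01 ~ ", rhs))
    dfit <- data
    dfit$y01 <- y
    separation <- FALSE
    fit <- withCallingHandlers(
      stats::glm(form, data = dfit, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    coefs <- summary(fit)$coefficients
    if (separation && length(current) > 0) {
      std <- abs(coefs[current, "Estimate"]) * sds[current]
      worst <- current[which.max(std)]
      if (max(abs(coefs[current, "Estimate"])) > 10) {
        stop("complete separation detected; offending predictor: ", worst,
             call. = FALSE)
      }
    }
    if (length(current) == 0) break
    p <- coefs[current, "Pr(>|z|)"]
    if (max(p) <= alpha_stay) break
    worst_p <- max(p)
    tied <- current[abs(p - worst_p) < 1e-12]
    if (length(tied) > 1) {
      std <- abs(coefs[tied, "Estimate"]) * sds[tied]
      remove <- tied[which.min(std)]
    } else {
      remove <- tied
    }
    step <- step + 1L
    trace <- rbind(trace, data.frame(predictor = remove,
                                     p_at_removal = worst_p,
                                     step = step,
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, remove)
  }
  coefs <- summary(fit)$coefficients
  tab <- data.frame(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"],
    se = coefs[, "Std. Error"],
    or = exp(coefs[, "Estimate"]),
    ci_lo = exp(coefs[, "Estimate"] - 1.96 * coefs[, "Std. Error"]),
    ci_hi = exp(coefs[, "Estimate"] + 1.96 * coefs[, "Std. Error"]),
    p = coefs[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = tab,
    retained = current,
    intercept_only = length(current) == 0,
    alpha_stay = alpha_stay,
    elimination_trace = trace,
    n_rows_dropped = n_dropped,
    constant_dropped = constant_dropped,
    n = length(y),
    n_events = sum(y),
    glm_fit = fit
  ), class = "fitted_logistic")
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat("Backward-elimination logistic model (alpha_stay =",
      x$alpha_stay, ")\n")
  cat("n =", x$n, "(", x$n_events, "events );",
      x$n_rows_dropped, "rows dropped for missingness\n")
  if (x$intercept_only) cat("NOTE: intercept-only model (no candidate retained)\n")
  print(x$coefficients, digits = 4)
  if (nrow(x$elimination_trace) > 0) {
    cat("Eliminated (in order):",
        paste(sprintf("%s (p=%.3f)", x$elimination_trace$predictor,
                      x$elimination_trace$p_at_removal), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Derive a points-based score model from a logistic fit on binary factors
#'
#' Each factor's score is its logistic coefficient multiplied by 10 and
#' rounded to one decimal. The probability of dMI for a patient with total
#' score S is recovered as `plogis(intercept + S / 10)`, which reproduces
#' the logistic probability up to the rounding of the scores. Simplified
#' integer weights (1 = minor, 2 = intermediate, 3 = major risk factor)
#' are assigned by ranking the scores: the smallest-score factor gets 1,
#' the largest gets 3, and the rest get 2 — which reproduces the published
#' assignment (grade2 -> 1, HE4ren and CA125 -> 2, age -> 3) whenever the
#' published significance ordering holds.
#'
#' @param fit A `fitted_logistic` whose retained predictors are all binary
#'   0/1 factors (a type error otherwise).
#' @return Object of class `score_model`: `scores` (named, one decimal),
#'   `intercept` (log-odds), `simplified_weights` (named integers), and
#'   `high_risk_threshold` (default [DMI_SIMPLIFIED_THRESHOLD]).
#' @export
derive_score_model <- function(fit) {
  stopifnot(inherits(fit, "fitted_logistic"))
  mf <- stats::model.frame(fit$glm_fit)
  for (v in fit$retained) {
    vals <- mf[[v]]
    if (!all(vals %in% c(0, 1))) {
      stop("derive_score_model requires binary 0/1 predictors; ",
           v, " is not binary", call. = FALSE)
    }
  }
  tab <- fit$coefficients
  factor_rows <- tab$term != "(Intercept)"
  scores <- round(10 * tab$estimate[factor_rows], 1)
  names(scores) <- tab$term[factor_rows]
  intercept <- tab$estimate[!factor_rows]
  structure(list(
    scores = scores,
    intercept = intercept,
    simplified_weights = simplify_weights(scores),
    high_risk_threshold = DMI_SIMPLIFIED_THRESHOLD
  ), class = "score_model")
}

#' Band point scores into simplified integer weights
#'
#' Ranks factor scores and maps them to minor/intermediate/major weights
#' 1/2/3: lowest score -> 1, highest -> 3, everything between -> 2. With a
#' single factor the weight is 2; with two, 1 and 3.
#'
#' @param scores Named numeric vector of per-factor scores.
#' @return Named integer vector of weights in {1, 2, 3}.
#' @export
simplify_weights <- function(scores) {
  if (length(scores) == 0) return(stats::setNames(integer(0), character(0)))
  w <- rep(2L, length(scores))
  if (length(scores) > 1) {
    w[which.min(scores)] <- 1L
    w[which.max(scores)] <- 3L
  }
  stats::setNames(w, names(scores))
}

#' Map a total score to the probability of dMI
#'
#' Inverts the coefficient-x10 construction: a patient whose factor scores
#' sum to S has `logit(P) = intercept + S/10`.
#'
#' @param total_score Sum of the per-factor scores.
#' @param intercept Model intercept on the log-odds scale.
#' @return Probability in (0, 1), monotone increasing in `total_score`.
#' @export
score_to_probability <- function(total_score, intercept) {
  stats::plogis(intercept + total_score / 10)
}

#' Simplified weighted low/high-risk classification
#'
#' Sums the simplified integer weights over the positive risk factors and
#' classifies the patient high-risk for dMI when the sum reaches the
#' threshold: with the published weights (grade2 = 1, HE4ren >= 45 and
#' CA125 >= 35 each = 2, age >= 60 = 3) a sum <= 3 is low-risk
#' (probability of dMI below 25%) and a sum >= 4 is high-risk.
#'
#' @param factors Data frame of 0/1 columns as from [categorize_patient()].
#' @param weights Named weights; default [DMI_SIMPLIFIED_WEIGHTS].
#' @param threshold High-risk threshold on the weighted sum; default
#'   [DMI_SIMPLIFIED_THRESHOLD].
#' @return Data frame with `score` (integer weighted sum) and `risk`
#'   (`"low"` or `"high"`).
#' @examples
#' f <- data.frame(grade2 = 1, he4ren_high = 1, ca125_high = 0, age_high = 0)
#' simplified_risk_class(f)  # score 3, low
#' @export
simplified_risk_class <- function(factors,
                                  weights = DMI_SIMPLIFIED_WEIGHTS,
                                  threshold = DMI_SIMPLIFIED_THRESHOLD) {
  stopifnot(is.data.frame(factors))
  missing_cols <- setdiff(names(weights), names(factors))
  if (length(missing_cols) > 0) {
    stop("factors is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fmat <- as.matrix(factors[, names(weights), drop = FALSE])
  if (!all(fmat %in% c(0, 1))) {
    stop("risk factors must be binary 0/1", call. = FALSE)
  }
  s <- as.integer(fmat %*% weights)
  data.frame(score = s, risk = ifelse(s >= threshold, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Classify a cohort into low/high risk of deep myometrial invasion
#'
#' Applies one of the dMI models to every patient. Grade 3 rows are never
#' scored: they are routed to the high-risk class with the annotation
#' `"managed as high-risk"`. Rows with missing grade are returned
#' unclassified (`NA` risk) with the annotation `"missing grade"`.
#'
#' * `model = "continuous"`: probability from [predict_dmi_continuous()],
#'   high-risk when probability >= `cutoff` (default 0.25; the
#'   training-set optimum reported for this model is 0.43).
#' * `model = "simplified"`: categorical factors via [categorize_patient()]
#'   then [simplified_risk_class()]; `cutoff` is ignored (the published
#'   weights encode the 25% probability cut-off).
#' * `model = "categorical"`: requires a `score_model` (with fitted scores
#'   and intercept); probability from [score_to_probability()], high-risk
#'   when probability >= `cutoff`.
#'
#' @param cohort Data frame with `age`, `he4ren`, `grade`, plus `ca125`
#'   for the categorical/simplified models.
#' @param model `"continuous"`, `"categorical"` or `"simplified"`.
#' @param cutoff Probability cut-off for the continuous and categorical
#'   models; default 0.25.
#' @param coefficients Continuous-model coefficients; default the
#'   published [DMI_CONTINUOUS_COEF].
#' @param score_model A `score_model`, required for `model = "categorical"`.
#' @param cutoffs Biomarker cut-offs for categorisation; default
#'   [DMI_CATEGORICAL_CUTOFFS].
#' @return The cohort with columns `probability` (NA where not defined),
#'   `score` (simplified/categorical models), `risk` (`"low"`/`"high"`)
#'   and `annotation` appended.
#' @export
classify_cohort <- function(cohort,
                            model = c("continuous", "categorical",
                                      "simplified"),
                            cutoff = 0.25,
                            coefficients = DMI_CONTINUOUS_COEF,
                            score_model = NULL,
                            cutoffs = DMI_CATEGORICAL_CUTOFFS) {
  model <- match.arg(model)
  stopifnot(is.data.frame(cohort))
  need <- if (model == "continuous") c("age", "he4ren", "grade")
          else c("age", "he4ren", "ca125", "grade")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (model == "categorical" && !inherits(score_model, "score_model")) {
    stop("model = \"categorical\" requires a fitted score_model ",
         "(the published categorical intercept is not part of the frozen ",
         "defaults)", call. = FALSE)
  }
  n <- nrow(cohort)
  out <- cohort
  out$probability <- rep(NA_real_, n)
  out$score <- rep(NA_real_, n)
  out$risk <- rep(NA_character_, n)
  out$annotation <- rep("", n)

  g3 <- !is.na(cohort$grade) & cohort$grade == 3
  gmiss <- is.na(cohort$grade)
  scoreable <- !g3 & !gmiss
  out$risk[g3] <- "high"
  out$annotation[g3] <- "managed as high-risk"
  out$annotation[gmiss] <- "missing grade"

  if (any(scoreable)) {
    sub <- cohort[scoreable, , drop = FALSE]
    if (model == "continuous") {
      p <- predict_dmi_continuous(sub$age, sub$he4ren, sub$grade,
                                  coefficients = coefficients)
      out$probability[scoreable] <- p
      out$risk[scoreable] <- ifelse(p >= cutoff, "high", "low")
    } else {
      fac <- categorize_patient(sub, cutoffs = cutoffs)
      if (model == "simplified") {
        cls <- simplified_risk_class(fac)
        out$score[scoreable] <- cls$score
        out$risk[scoreable] <- cls$risk
      } else {
        fmat <- as.matrix(fac[, names(score_model$scores), drop = FALSE])
        total <- as.numeric(fmat %*% score_model$scores)
        p <- score_to_probability(total, score_model$intercept)
        out$probability[scoreable] <- p
        out$score[scoreable] <- total
        out$risk[scoreable] <- ifelse(p >= cutoff, "high", "low")
      }
    }
  }
  out
}
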