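test_that("continuous dMI model reproduces the published worked probabilities", {
  expect_equal(predict_dmi_continuous(65, 60.5, 1), 0.4789, tolerance = 1e-4)
  expect_equal(predict_dmi_continuous(60, 45, 2), 0.4241, tolerance = 1e-4)
  expect_equal(predict_dmi_continuous(80, 150, 2), 0.9856, tolerance = 1e-4)
})

test_that("continuous model is monotone in age, he4ren and grade", {
  base <- predict_dmi_continuous(65, 60, 1)
  expect_gt(predict_dmi_continuous(66, 60, 1), base)
  expect_gt(predict_dmi_continuous(65, 61, 1), base)
  expect_gt(predict_dmi_continuous(65, 60, 2), base)
})

test_that("continuous model routes grade-3 and missing-grade patients out", {
  expect_error(predict_dmi_continuous(65, 60, 3), "high-risk")
  expect_error(predict_dmi_continuous(65, 60, NA), "missing")
  expect_error(predict_dmi_continuous(65, -5, 1), "he4ren")
})

test_that("probability is the same for supplied he4ren and he4 adjusted above the knot", {
  he4 <- 72.3
  adj <- he4ren(he4, 115)   # identity above the knot
  expect_identical(predict_dmi_continuous(61, adj, 2),
                   predict_dmi_continuous(61, he4, 2))
})

test_that("categorisation uses inclusive boundaries exactly as published", {
  on_boundary <- data.frame(age = 60, he4ren = 45, ca125 = 35, grade = 2)
  expect_equal(unlist(categorize_patient(on_boundary)),
               c(grade2 = 1L, he4ren_high = 1L, ca125_high = 1L, age_high = 1L))
  just_below <- data.frame(age = 59.9, he4ren = 44.9, ca125 = 34.9, grade = 1)
  expect_equal(unlist(categorize_patient(just_below)),
               c(grade2 = 0L, he4ren_high = 0L, ca125_high = 0L, age_high = 0L))
  mixed <- data.frame(age = 75, he4ren = 30, ca125 = 40, grade = 1)
  expect_equal(unlist(categorize_patient(mixed)),
               c(grade2 = 0L, he4ren_high = 0L, ca125_high = 1L, age_high = 1L))
  expect_error(categorize_patient(data.frame(age = 70, he4ren = 50,
                                             ca125 = 40, grade = 3)),
               "high-risk")
})

test_that("backward elimination drops a noise predictor and keeps real ones", {
  d <- simulate_from_printed_model(4000, seed = 5)
  set.seed(99)
  d$noise <- rnorm(nrow(d))
  fit <- fit_logistic_backward(d, "dmi",
                               c("age", "log_he4ren", "grade_num", "noise"))
  expect_setequal(fit$retained, c("age", "log_he4ren", "grade_num"))
  expect_equal(fit$elimination_trace$predictor, "noise")
  expect_gt(fit$elimination_trace$p_at_removal, 0.1)
  expect_true(all(fit$coefficients$p[fit$coefficients$term != "(Intercept)"]
                  <= 0.1))
})

test_that("OR and Wald CI columns are exact transforms of the coefficients", {
  d <- simulate_from_printed_model(800, seed = 21)
  fit <- fit_logistic_backward(d, "dmi", c("age", "log_he4ren", "grade_num"))
  tab <- fit$coefficients
  expect_equal(tab$or, exp(tab$estimate), tolerance = 1e-12)
  expect_equal(tab$ci_lo, exp(tab$estimate - 1.96 * tab$se), tolerance = 1e-12)
  expect_equal(tab$ci_hi, exp(tab$estimate + 1.96 * tab$se), tolerance = 1e-12)
})

test_that("constant candidates are dropped up front with a log entry", {
  d <- simulate_from_printed_model(600, seed = 8)
  d$flat <- 1
  fit <- fit_logistic_backward(d, "dmi", c("age", "log_he4ren", "flat"))
  expect_identical(fit$constant_dropped, "flat")
  expect_false("flat" %in% fit$retained)
})

test_that("complete separation raises an error naming the predictor", {
  d <- simulate_from_printed_model(300, seed = 13)
  d$leak <- as.numeric(d$dmi) * 2 - 1   # perfectly separates
  expect_error(fit_logistic_backward(d, "dmi", c("age", "leak")),
               "separation.*leak")
})

test_that("rows with missing candidates are dropped and counted", {
  d <- simulate_from_printed_model(500, seed = 30)
  d$age[1:7] <- NA
  fit <- fit_logistic_backward(d, "dmi", c("age", "log_he4ren"))
  expect_equal(fit$n_rows_dropped, 7)
  expect_equal(fit$n, 493)
})

test_that("elimination requires minimum events and a known binary outcome", {
  d <- simulate_from_printed_model(500, seed = 2)
  d$dmi <- FALSE
  d$dmi[1:5] <- TRUE
  expect_error(fit_logistic_backward(d, "dmi", "age"), "10 events")
  expect_error(fit_logistic_backward(d, "dmi", "nope"), "missing column")
})

test_that("score model multiplies coefficients by ten with one-decimal rounding", {
  set.seed(41)
  n <- 1200
  f1 <- rbinom(n, 1, 0.4)
  f2 <- rbinom(n, 1, 0.3)
  y <- runif(n) < plogis(-1 + 0.5 * f1 + 1.23 * f2)
  d <- data.frame(f1 = f1, f2 = f2, y = y)
  fit <- fit_logistic_backward(d, "y", c("f1", "f2"), alpha_stay = 1)
  sm <- derive_score_model(fit)
  est <- fit$coefficients$estimate[fit$coefficients$term != "(Intercept)"]
  expect_equal(unname(sm$scores), round(10 * est, 1))
  # score -> probability mapping reproduces the logistic fit up to rounding
  for (combo in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    total <- sum(sm$scores * combo)
    exact <- plogis(sm$intercept + sum(est * combo))
    expect_equal(score_to_probability(total, sm$intercept), exact,
                 tolerance = 0.0125)  # 0.25 * (0.05 rounding slack) per factor
  }
})

test_that("score model rejects non-binary predictors", {
  d <- simulate_from_printed_model(600, seed = 17)
  fit <- fit_logistic_backward(d, "dmi", c("age", "grade_num"))
  expect_error(derive_score_model(fit), "not binary")
})

test_that("a total score of 27.1 maps to 25% under the matching intercept", {
  expect_equal(score_to_probability(27.1, log(1 / 3) - 2.71), 0.25,
               tolerance = 1e-12)
  # monotone in total score
  p <- score_to_probability(seq(0, 40, by = 5), -2)
  expect_true(all(diff(p) > 0))
})

test_that("simplified weight banding reproduces the published 1/2/2/3 assignment", {
  # published significance ordering: grade weakest, age strongest
  scores <- c(grade2 = 4.1, he4ren_high = 9.8, ca125_high = 8.6,
              age_high = 12.7)
  expect_equal(simplify_weights(scores),
               c(grade2 = 1L, he4ren_high = 2L, ca125_high = 2L,
                 age_high = 3L))
  expect_equal(unname(simplify_weights(c(a = 5))), 2L)
  expect_equal(length(simplify_weights(numeric(0))), 0)
})

test_that("simplified classifier agrees with the exhaustive 16-row truth table", {
  combos <- expand.grid(grade2 = 0:1, he4ren_high = 0:1,
                        ca125_high = 0:1, age_high = 0:1)
  got <- simplified_risk_class(combos)
  # brute-force oracle: recompute the weighted sum arithmetic long-hand
  for (i in seq_len(nrow(combos))) {
    s <- combos$grade2[i] * 1 + combos$he4ren_high[i] * 2 +
      combos$ca125_high[i] * 2 + combos$age_high[i] * 3
    expect_equal(got$score[i], s)
    expect_identical(got$risk[i], if (s >= 4) "high" else "low")
  }
  # published boundary cases
  f3 <- data.frame(grade2 = 1, he4ren_high = 1, ca125_high = 0, age_high = 0)
  expect_identical(simplified_risk_class(f3)$risk, "low")   # sum 3
  f4 <- data.frame(grade2 = 0, he4ren_high = 1, ca125_high = 1, age_high = 0)
  expect_identical(simplified_risk_class(f4)$risk, "high")  # sum 4
  expect_identical(simplified_risk_class(
    data.frame(grade2 = 0, he4ren_high = 0, ca125_high = 0, age_high = 0)
  )$risk, "low")
})

test_that("cohort classification applies cut-offs and routes grade 3 to high risk", {
  cohort <- data.frame(
    age = c(65, 60, 70, 55), he4ren = c(60.5, 30, 80, 50),
    ca125 = c(20, 10, 50, 12), grade = c(1, 1, 3, NA)
  )
  cont <- classify_cohort(cohort, model = "continuous", cutoff = 0.43)
  expect_equal(cont$probability[1], 0.4789, tolerance = 1e-4)
  expect_identical(cont$risk[1], "high")
  expect_identical(cont$risk[3], "high")
  expect_identical(cont$annotation[3], "managed as high-risk")
  expect_true(is.na(cont$probability[3]))
  expect_true(is.na(cont$risk[4]))
  expect_identical(cont$annotation[4], "missing grade")

  simp <- classify_cohort(
    data.frame(age = 50, he4ren = 50, ca125 = 10, grade = 2),
    model = "simplified")
  expect_identical(simp$risk, "low")   # factors (1,1,0,0), sum 3

  expect_error(classify_cohort(cohort, model = "categorical"),
               "score_model")
  expect_error(classify_cohort(cohort[, c("age", "grade")],
                               model = "continuous"), "missing required")
})
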