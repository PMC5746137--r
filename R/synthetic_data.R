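# Seeded generators for the two cohorts the analysis needs: a control
# cohort of healthy women spanning a range of kidney function (for
# deriving the HE4ren transform) and an endometrial-cancer cohort (for
# developing and validating the dMI risk models).  The generating
# mechanisms are the package's own models run forward: observed HE4 is a
# renally independent baseline inflated by exp(-s*10^-2*(eGFR-90)) below
# the knot — exactly what the HE4ren transform inverts — and dMI is drawn
# from the published continuous logistic model, so that refitting the
# pipeline on generated data is a closed loop with known truth.

#' Configuration for the synthetic cohort generators
#'
#' Defaults emulate the study's cohort structure: 66 controls with a wide
#' eGFR range; 120 cancer patients with median age ~65, median creatinine
#' ~67 umol/l, median HE4 ~60 pmol/l, median CA125 ~18 U/ml, grade
#' distribution ~45/37/17% (plus ~2% missing) and dMI prevalence ~40%.
#'
#' @param seed Integer seed; identical seed implies identical cohorts.
#' @param n_controls Number of control subjects (default 66).
#' @param n_patients Number of cancer patients (default 120).
#' @param age_mean,age_sd,age_range Age law: normal(65, 8) truncated to
#'   [40, 90] years.
#' @param egfr_intercept,egfr_age_slope,egfr_noise_sd,egfr_range Age-to-eGFR
#'   coupling: eGFR = 130 - 0.9 * age + normal(0, 12), clipped to
#'   [15, 120] ml/min/1.73 m^2 (the age coupling is what makes raw HE4
#'   age-correlated).
#' @param he4_log_mean,he4_log_sd Baseline ln-HE4 law: normal(ln 45, 0.35),
#'   independent of age — the latent renally independent HE4.
#' @param slope_coeff Renal inflation constant (x10^2 scale); default the
#'   published [HE4REN_SLOPE].
#' @param grade_probs Multinomial probabilities for grade 1, 2, 3 and
#'   missing (default 0.45, 0.367, 0.167, 0.017 — must sum to 1).
#' @param ca125_log_mean,ca125_log_sd ln-CA125 law: normal(ln 17, 0.6).
#' @param ca125_dmi_shift Additive ln-CA125 shift in dMI-positive patients
#'   (default +0.5; set 0 for cohorts in which CA125 carries no dMI
#'   signal).
#' @param grade3_dmi_prob Fixed dMI probability for grade-3 patients
#'   (default 0.55; the published model covers grades 1-2 only).
#' @param ckd_egfr_threshold eGFR below which a control is flagged CKD
#'   positive (default 60).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_controls = 66L,
                             n_patients = 120L,
                             age_mean = 65, age_sd = 8,
                             age_range = c(40, 90),
                             egfr_intercept = 130, egfr_age_slope = 0.9,
                             egfr_noise_sd = 12, egfr_range = c(15, 120),
                             he4_log_mean = log(45), he4_log_sd = 0.35,
                             slope_coeff = HE4REN_SLOPE,
                             grade_probs = c(g1 = 0.45, g2 = 0.367,
                                             g3 = 0.167, missing = 0.017),
                             ca125_log_mean = log(17), ca125_log_sd = 0.6,
                             ca125_dmi_shift = 0.5,
                             grade3_dmi_prob = 0.55,
                             ckd_egfr_threshold = 60) {
  cfg <- list(seed = as.integer(seed), n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              egfr_intercept = egfr_intercept,
              egfr_age_slope = egfr_age_slope,
              egfr_noise_sd = egfr_noise_sd, egfr_range = egfr_range,
              he4_log_mean = he4_log_mean, he4_log_sd = he4_log_sd,
              slope_coeff = slope_coeff, grade_probs = grade_probs,
              ca125_log_mean = ca125_log_mean, ca125_log_sd = ca125_log_sd,
              ca125_dmi_shift = ca125_dmi_shift,
              grade3_dmi_prob = grade3_dmi_prob,
              ckd_egfr_threshold = ckd_egfr_threshold)
  bad <- character(0)
  if (cfg$n_controls < 1) bad <- c(bad, "n_controls")
  if (cfg$n_patients < 1) bad <- c(bad, "n_patients")
  for (k in c("age_sd", "egfr_noise_sd", "he4_log_sd", "ca125_log_sd")) {
    if (cfg[[k]] < 0) bad <- c(bad, k)
  }
  # the default probabilities come from printed cohort percentages that
  # sum to 100.1% after rounding; accept within 1% and renormalise exactly
  if (length(cfg$grade_probs) != 4 || any(cfg$grade_probs < 0) ||
      abs(sum(cfg$grade_probs) - 1) > 0.01) {
    bad <- c(bad, "grade_probs")
  } else {
    cfg$grade_probs <- cfg$grade_probs / sum(cfg$grade_probs)
  }
  if (cfg$grade3_dmi_prob < 0 || cfg$grade3_dmi_prob > 1) {
    bad <- c(bad, "grade3_dmi_prob")
  }
  if (length(bad) > 0) {
    stop("invalid generator configuration key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  # simple rejection sampler; bounds are several SDs wide so it is cheap
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

.draw_covariates <- function(n, cfg) {
  age <- .rtruncnorm(n, cfg$age_mean, cfg$age_sd,
                     cfg$age_range[1], cfg$age_range[2])
  egfr <- cfg$egfr_intercept - cfg$egfr_age_slope * age +
    stats::rnorm(n, 0, cfg$egfr_noise_sd)
  egfr <- pmin(pmax(egfr, cfg$egfr_range[1]), cfg$egfr_range[2])
  he4_baseline <- exp(stats::rnorm(n, cfg$he4_log_mean, cfg$he4_log_sd))
  # renal inflation: observed HE4 rises as eGFR falls below the knot;
  # above the knot the observed value IS the baseline
  he4 <- he4_baseline * exp(-cfg$slope_coeff * 1e-2 *
                              pmin(egfr - HE4REN_KNOT, 0))
  creatinine <- creatinine_from_egfr_female(age, egfr)
  data.frame(age = age, creatinine_umol_l = creatinine, egfr = egfr,
             he4_baseline = he4_baseline, he4 = he4)
}

#' Generate a synthetic control cohort
#'
#' Healthy (non-cancer) women spanning a range of kidney function.
#' Creatinine is back-solved from the drawn eGFR via
#' [creatinine_from_egfr_female()], so a downstream pipeline recomputes
#' the same eGFR from creatinine; observed HE4 equals the latent baseline
#' inflated below the knot by the generator's renal mechanism (the exact
#' inverse of [he4ren()]).
#'
#' @param cfg A [generator_config()].
#' @return Data frame with columns `age`, `creatinine_umol_l`, `egfr`,
#'   `he4_baseline` (latent), `he4` (observed), `ckd_flag`.
#' @export
generate_controls <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  d <- .draw_covariates(cfg$n_controls, cfg)
  d$ckd_flag <- d$egfr < cfg$ckd_egfr_threshold
  d
}

#' Generate a synthetic endometrial-cancer cohort
#'
#' Covariates follow the same laws as the controls; histological grade is
#' multinomial (with a small missing fraction); dMI is Bernoulli with
#' probability given by the published continuous model
#' ([predict_dmi_continuous()]) on (age, latent HE4ren, grade) for grades
#' 1-2 and a fixed configurable probability for grade 3. Rows with
#' missing recorded grade still receive a dMI outcome through a latent
#' grade drawn from the grade-1..3 distribution. CA125 is log-normal with
#' an additive ln-scale shift in dMI-positive patients.
#'
#' @param cfg A [generator_config()].
#' @param cohort_label Value for the `cohort` tag column (default
#'   `"simulated"`).
#' @return Data frame with columns `age`, `creatinine_umol_l`, `egfr`,
#'   `he4_baseline`, `he4`, `grade` (1/2/3 or NA), `ca125`, `dmi`
#'   (logical), `cohort`.
#' @export
generate_ec_cohort <- function(cfg = generator_config(),
                               cohort_label = "simulated") {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  d <- .draw_covariates(n, cfg)
  gp <- cfg$grade_probs
  grade_draw <- sample.int(4L, n, replace = TRUE, prob = gp)
  # a latent true grade drives the outcome even when the record is missing
  latent <- ifelse(grade_draw == 4L,
                   sample.int(3L, n, replace = TRUE,
                              prob = gp[1:3] / sum(gp[1:3])),
                   grade_draw)
  grade <- ifelse(grade_draw == 4L, NA_integer_, grade_draw)
  # latent HE4ren equals the baseline by construction of the inflation
  p_dmi <- ifelse(latent == 3L, cfg$grade3_dmi_prob,
                  predict_dmi_continuous(d$age, d$he4_baseline,
                                         pmin(latent, 2L)))
  dmi <- stats::runif(n) < p_dmi
  ca125 <- exp(stats::rnorm(n, cfg$ca125_log_mean, cfg$ca125_log_sd) +
                 cfg$ca125_dmi_shift * dmi)
  d$grade <- grade
  d$ca125 <- ca125
  d$dmi <- dmi
  d$cohort <- cohort_label
  d
}
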