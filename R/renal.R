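# CKD-EPI 2009 creatinine equation, female coefficients, no race term.
# Creatinine is handled in umol/l at every interface and converted to
# mg/dl internally (divisor 88.4, the molar mass conversion).

.CKD_EPI_KAPPA <- 0.7     # mg/dl, female
.CKD_EPI_ALPHA <- -0.329  # female exponent below kappa
.CKD_EPI_BETA  <- -1.209  # shared exponent above kappa
.CKD_EPI_FEMALE_FACTOR <- 1.018

#' Convert serum creatinine from umol/l to mg/dl
#'
#' @param creatinine_umol_l Serum creatinine in umol/l; must be positive.
#'   Values outside the plausible clinical range 20--1500 umol/l trigger a
#'   warning (not an error).
#' @return Creatinine in mg/dl (`umol/l / 88.4`).
#' @examples
#' creatinine_umol_to_mgdl(88.4)  # 1.0
#' @export
creatinine_umol_to_mgdl <- function(creatinine_umol_l) {
  if (!is.numeric(creatinine_umol_l) || any(!is.finite(creatinine_umol_l)) ||
      any(creatinine_umol_l <= 0)) {
    stop("creatinine must be a positive finite number (umol/l)", call. = FALSE)
  }
  if (any(creatinine_umol_l < 20 | creatinine_umol_l > 1500)) {
    warning("creatinine outside the plausible clinical range 20-1500 umol/l",
            call. = FALSE)
  }
  creatinine_umol_l / 88.4
}

#' Estimated glomerular filtration rate (CKD-EPI 2009, female)
#'
#' Computes eGFR in ml/min/1.73 m^2 from age and serum creatinine using the
#' CKD-EPI 2009 creatinine equation with female coefficients and no race
#' adjustment:
#' \deqn{141 \cdot \min(S_{cr}/0.7, 1)^{-0.329} \cdot
#'       \max(S_{cr}/0.7, 1)^{-1.209} \cdot 0.993^{age} \cdot 1.018}
#' with \eqn{S_{cr}} in mg/dl. No cap at 90 is applied: the value the
#' equation yields is returned as is, so that downstream knot logic at
#' eGFR = 90 is well defined. Only the female equation is provided; the
#' cohorts this package models are all-female and male input is rejected
#' rather than silently mishandled.
#'
#' @param age Age in years, in [18, 110].
#' @param creatinine_umol_l Serum creatinine in umol/l, positive.
#' @param sex Must be `"female"` (the default); anything else errors.
#' @return eGFR in ml/min/1.73 m^2. Strictly decreasing in creatinine at
#'   fixed age and strictly decreasing in age at fixed creatinine.
#' @examples
#' egfr_ckd_epi_female(65, 67)   # 82.60
#' egfr_ckd_epi_female(50, 50)   # 108.36
#' @export
egfr_ckd_epi_female <- function(age, creatinine_umol_l, sex = "female") {
  if (!identical(sex, "female")) {
    stop("only the female CKD-EPI equation is supported (all-female cohorts); ",
         "got sex = ", deparse(sex), call. = FALSE)
  }
  if (!is.numeric(age) || any(!is.finite(age)) ||
      any(age < 18) || any(age > 110)) {
    stop("age must be in [18, 110] years", call. = FALSE)
  }
  scr <- creatinine_umol_to_mgdl(creatinine_umol_l)
  r <- scr / .CKD_EPI_KAPPA
  141 * pmin(r, 1)^.CKD_EPI_ALPHA * pmax(r, 1)^.CKD_EPI_BETA *
    0.993^age * .CKD_EPI_FEMALE_FACTOR
}

#' Back-solve creatinine from a target eGFR (female CKD-EPI)
#'
#' Analytic inverse of [egfr_ckd_epi_female()]: given age and a target eGFR
#' it returns the serum creatinine (umol/l) that yields exactly that eGFR.
#' The equation is strictly decreasing in creatinine, so the inverse is
#' unique; the branch (creatinine above or below kappa = 0.7 mg/dl) is
#' selected by comparing the target with the eGFR at the branch boundary
#' for that age. Used by the synthetic cohort generator so that the
#' pipeline's own eGFR step is exercised on generated creatinine values.
#'
#' Every positive eGFR is formally attainable by some positive creatinine,
#' but extreme targets back-solve to physically meaningless concentrations;
#' solutions outside 1--5000 umol/l are rejected as a domain error.
#'
#' @param age Age in years, in [18, 110].
#' @param egfr Target eGFR in ml/min/1.73 m^2, positive.
#' @return Creatinine in umol/l such that
#'   `egfr_ckd_epi_female(age, result)` equals `egfr` to machine precision.
#' @examples
#' creatinine_from_egfr_female(65, 82.60)  # ~67 umol/l
#' @export
creatinine_from_egfr_female <- function(age, egfr) {
  if (!is.numeric(age) || any(!is.finite(age)) ||
      any(age < 18) || any(age > 110)) {
    stop("age must be in [18, 110] years", call. = FALSE)
  }
  if (!is.numeric(egfr) || any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("egfr must be a positive finite number", call. = FALSE)
  }
  # eGFR at the branch boundary Scr = kappa for this age
  boundary <- 141 * 0.993^age * .CKD_EPI_FEMALE_FACTOR
  expo <- ifelse(egfr <= boundary, 1 / .CKD_EPI_BETA, 1 / .CKD_EPI_ALPHA)
  scr <- .CKD_EPI_KAPPA * (egfr / boundary)^expo
  creat <- scr * 88.4
  if (any(creat < 1 | creat > 5000)) {
    stop("target eGFR not attainable at a clinically meaningful creatinine ",
         "for this age", call. = FALSE)
  }
  creat
}
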