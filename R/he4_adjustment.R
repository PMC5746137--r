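# The HE4ren transform: serum HE4 is cleared by glomerular filtration and
# rises log-linearly as eGFR falls below ~90 ml/min/1.73 m^2.  Projecting
# an observed HE4 back to its eGFR = 90 equivalent removes that renal
# inflation.  The published adjustment constant is 2.182 (x 10^-2 per unit
# eGFR); it is the frozen default everywhere so that downstream risk models
# reproduce the published behaviour, and can be refit from a control cohort
# with fit_piecewise_loglinear().

#' Published HE4ren adjustment constant
#'
#' The renal-inflation slope of ln(HE4) per unit eGFR below the knot,
#' scaled by 10^2 (so the value 2.182 means ln(HE4) falls by 0.02182 per
#' ml/min/1.73 m^2 of eGFR gained below 90).
#' @export
HE4REN_SLOPE <- 2.182

#' Fixed knot of the piecewise HE4--eGFR model (ml/min/1.73 m^2)
#' @export
HE4REN_KNOT <- 90

#' Renally adjusted HE4 (HE4ren)
#'
#' Projects an observed serum HE4 concentration to its eGFR = 90
#' equivalent:
#' \deqn{HE4ren = \exp[\ln(HE4) + s \cdot (eGFR - 90) \cdot 10^{-2}]}
#' for eGFR <= 90, and HE4ren = HE4 unchanged for eGFR > 90. The transform
#' is continuous at the knot, multiplicative in HE4, and deflating below
#' the knot (eGFR < 90 implies HE4ren < HE4).
#'
#' @param he4 Observed serum HE4 in pmol/l, positive. Values below
#'   10 pmol/l are below the assay's validated linearity and trigger a
#'   warning.
#' @param egfr eGFR in ml/min/1.73 m^2, positive.
#' @param slope_coeff Adjustment constant on the x10^2 scale; default the
#'   published [HE4REN_SLOPE].
#' @param knot eGFR knot; default [HE4REN_KNOT].
#' @return Adjusted HE4 in pmol/l.
#' @examples
#' he4ren(50, 120)    # 50: identity above the knot
#' he4ren(100, 40)    # 33.59
#' he4ren(62.6, 84)   # 54.92
#' @export
he4ren <- function(he4, egfr, slope_coeff = HE4REN_SLOPE, knot = HE4REN_KNOT) {
  if (!is.numeric(he4) || any(!is.finite(he4)) || any(he4 <= 0)) {
    stop("he4 must be positive and finite (pmol/l)", call. = FALSE)
  }
  if (!is.numeric(egfr) || any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("egfr must be positive and finite", call. = FALSE)
  }
  if (any(he4 < 10)) {
    warning("HE4 below 10 pmol/l is below the assay's validated linearity",
            call. = FALSE)
  }
  # above the knot the observed value is returned unchanged (exactly)
  n <- max(length(he4), length(egfr))
  out <- rep_len(he4, n)
  e <- rep_len(egfr, n)
  idx <- e <= knot
  out[idx] <- exp(log(out[idx]) + slope_coeff * (e[idx] - knot) * 1e-2)
  out
}

#' Fit the piecewise log-linear HE4--eGFR model on a control cohort
#'
#' Least-squares fit of
#' \deqn{\ln(HE4) = intercept + \beta \cdot \min(eGFR - knot, 0) + \epsilon}
#' on non-cancer controls: a single basis term that is linear below the
#' knot and identically zero above it, so the fitted curve is flat above
#' the knot and continuous at it by construction. The returned
#' `slope_coeff` is \eqn{-\beta \times 10^2}, matching the sign convention
#' in which HE4 rises as eGFR falls (positive adjustment constant).
#'
#' @param controls Data frame with columns `egfr` (ml/min/1.73 m^2) and
#'   `he4` (pmol/l); at least 3 rows and at least 2 distinct eGFR values
#'   at or below the knot.
#' @param knot Fixed knot; default [HE4REN_KNOT]. The knot is not
#'   estimated.
#' @return Object of class `piecewise_fit`: list with `knot`,
#'   `slope_coeff` (x10^2 scale), `slope_ci` (Wald-type 95% CI for
#'   `slope_coeff`), `intercept` (ln pmol/l at the knot), `residual_sd`,
#'   `n`, and the underlying `lm` fit.
#' @export
fit_piecewise_loglinear <- function(controls, knot = HE4REN_KNOT) {
  stopifnot(is.data.frame(controls))
  missing_cols <- setdiff(c("egfr", "he4"), names(controls))
  if (length(missing_cols) > 0) {
    stop("controls is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(controls) < 3) {
    stop("need at least 3 control subjects", call. = FALSE)
  }
  below <- controls$egfr[controls$egfr <= knot]
  if (length(below) == 0) {
    stop("no controls with eGFR at or below the knot; ",
         "the renal slope is not identifiable", call. = FALSE)
  }
  if (length(unique(below)) < 2) {
    stop("need at least 2 distinct eGFR values at or below the knot",
         call. = FALSE)
  }
  basis <- pmin(controls$egfr - knot, 0)
  fit <- stats::lm(log(he4) ~ basis, data = data.frame(
    he4 = controls$he4, basis = basis))
  if (anyNA(stats::coef(fit))) {
    stop("singular piecewise fit: degenerate control design", call. = FALSE)
  }
  beta <- unname(stats::coef(fit)["basis"])
  ci <- tryCatch(stats::confint(fit, "basis", level = 0.95),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(
    knot = knot,
    slope_coeff = -beta * 100,
    slope_ci = sort(-as.numeric(ci) * 100),
    intercept = unname(stats::coef(fit)[1]),
    residual_sd = summary(fit)$sigma,
    n = nrow(controls),
    lm_fit = fit
  ), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Piecewise log-linear HE4 ~ eGFR fit (knot at", x$knot, ")\n")
  cat(sprintf("  slope_coeff (x10^2): %.4f  [95%% CI %.4f, %.4f]\n",
              x$slope_coeff, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept (ln pmol/l at knot): %.4f\n", x$intercept))
  cat(sprintf("  residual SD (ln scale): %.4f   n = %d\n",
              x$residual_sd, x$n))
  invisible(x)
}

#' Append eGFR and HE4ren columns to a cohort table
#'
#' Computes eGFR from `age` and `creatinine_umol_l` where no `egfr` column
#' is supplied (recording the provenance), then appends an `he4ren` column
#' via [he4ren()]. Unknown columns are preserved untouched and row count
#' is preserved.
#'
#' @param records Data frame with columns `he4` plus either `egfr` or both
#'   `age` and `creatinine_umol_l`.
#' @param slope_coeff,knot Passed to [he4ren()].
#' @return The input with `egfr` (if computed) and `he4ren` columns
#'   appended, and an attribute `egfr_provenance` set to `"computed"` or
#'   `"supplied"`.
#' @export
adjust_cohort <- function(records, slope_coeff = HE4REN_SLOPE,
                          knot = HE4REN_KNOT) {
  stopifnot(is.data.frame(records))
  if (!"he4" %in% names(records)) {
    stop("cohort is missing required column(s): he4", call. = FALSE)
  }
  if ("egfr" %in% names(records)) {
    provenance <- "supplied"
  } else {
    needed <- setdiff(c("age", "creatinine_umol_l"), names(records))
    if (length(needed) > 0) {
      stop("cohort is missing required column(s): ",
           paste(c(needed), collapse = ", "),
           " (need egfr, or age + creatinine_umol_l)", call. = FALSE)
    }
    provenance <- "computed"
    records$egfr <- if (nrow(records) > 0) {
      egfr_ckd_epi_female(records$age, records$creatinine_umol_l)
    } else numeric(0)
  }
  records$he4ren <- if (nrow(records) > 0) {
    he4ren(records$he4, records$egfr, slope_coeff = slope_coeff, knot = knot)
  } else numeric(0)
  attr(records, "egfr_provenance") <- provenance
  records
}
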