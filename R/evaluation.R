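# ROC/AUC and confusion metrics for the dMI risk models.  AUC is computed
# through the Mann-Whitney identity (midrank formula, ties credited 1/2),
# so it equals the probability that a random case outranks a random
# control.  The classification rule at a cut-off is inclusive (score >=
# cutoff => predicted positive), matching the inclusive ">=" biomarker
# cut-offs used throughout the models.

#' Area under the ROC curve (Mann-Whitney identity)
#'
#' Computes AUC as the pairwise concordance probability: the fraction of
#' (case, control) pairs in which the case's score exceeds the control's,
#' ties counted one half. Implemented via the midrank formula
#' \eqn{AUC = (R_1 - n_1(n_1+1)/2) / (n_1 n_0)} where \eqn{R_1} is the
#' midrank sum of the cases.
#'
#' @param scores Numeric risk scores or probabilities.
#' @param labels Binary labels (logical or 0/1); 1 = positive (dMI).
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || length(scores) == 0) {
    stop("scores and labels must be non-empty and of equal length",
         call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (logical or 0/1)", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined with a single class present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a probability cut-off
#'
#' Predicted positive iff score >= cutoff (inclusive). PPV and NPV are
#' returned as `NaN` with the corresponding `ppv_defined` / `npv_defined`
#' flag set to `FALSE` when their denominator is zero.
#'
#' @param scores Numeric risk scores or probabilities.
#' @param labels Binary labels; 1 = positive.
#' @param cutoff Classification threshold.
#' @return One-row data frame: `cutoff`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `ppv_defined`, `npv_defined`, `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_metrics(c(0.6, 0.5, 0.4, 0.3), c(1, 0, 1, 0), 0.45)
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  if (length(scores) == 0 || length(scores) != length(labels)) {
    stop("scores and labels must be non-empty and of equal length",
         call. = FALSE)
  }
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  data.frame(
    cutoff = cutoff,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
    npv = if (tn + fn > 0) tn / (tn + fn) else NaN,
    ppv_defined = tp + fp > 0,
    npv_defined = tn + fn > 0,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Optimal cut-off by maximal sensitivity + specificity
#'
#' Evaluates every candidate cut-off on the grid and returns the one
#' maximising the Youden-type sum sensitivity + specificity. Ties are
#' broken toward the larger cut-off (favouring specificity); when a tie
#' occurs the returned value carries the attribute `tied = TRUE`.
#'
#' @param scores Numeric risk scores or probabilities.
#' @param labels Binary labels; 1 = positive.
#' @param grid Candidate cut-offs; default the whole-percent grid
#'   `seq(0.01, 0.99, by = 0.01)` (the scale on which the published
#'   cut-offs 43%, 33% and 25% live).
#' @return The optimal cut-off (scalar from `grid`), with attributes
#'   `youden_sum` and `tied`.
#' @export
optimal_cutoff <- function(scores, labels, grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(grid) == 0) stop("candidate grid is empty", call. = FALSE)
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("both classes must be present", call. = FALSE)
  }
  sums <- vapply(grid, function(ct) {
    m <- confusion_metrics(scores, labels, ct)
    m$sensitivity + m$specificity
  }, numeric(1))
  best <- max(sums)
  hits <- grid[abs(sums - best) < 1e-12]
  structure(max(hits), youden_sum = best, tied = length(hits) > 1)
}

#' Spearman rank correlation (midranks)
#'
#' Pearson correlation of midranks (average ranks for ties) — the
#' convention under which the published age correlations of HE4 (0.637)
#' versus HE4ren (0.210) are reported.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return Correlation in [-1, 1]; `NA` with a warning when either vector
#'   is constant (undefined).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("rank correlation undefined for a constant vector",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Percentile by linear interpolation
#'
#' The linear-interpolation quantile between order statistics
#' (`stats::quantile` type 7, the default of mainstream numeric stacks),
#' fixed and documented here because reference percentiles of small
#' control cohorts are convention-sensitive.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in [0, 100], e.g. 95.
#' @return The q-th percentile.
#' @examples
#' percentile(1:100, 95)  # 95.05
#' @export
percentile <- function(values, q) {
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)
  if (!is.numeric(q) || q < 0 || q > 100) {
    stop("q must be a percentage in [0, 100]", call. = FALSE)
  }
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}

#' Evaluation report: AUC plus metrics at a set of cut-offs
#'
#' @param scores Numeric risk scores or probabilities.
#' @param labels Binary labels; 1 = positive.
#' @param cutoffs Probability cut-offs to tabulate; default the published
#'   working set c(0.25, 0.33, 0.43).
#' @return Object of class `eval_report`: `auc`, `metrics` (one row per
#'   cut-off), `n_pos`, `n_neg`.
#' @export
eval_report <- function(scores, labels, cutoffs = c(0.25, 0.33, 0.43)) {
  labels <- as.integer(labels)
  metrics <- do.call(rbind, lapply(cutoffs, function(ct)
    confusion_metrics(scores, labels, ct)))
  structure(list(
    auc = roc_auc(scores, labels),
    metrics = metrics,
    n_pos = sum(labels == 1L),
    n_neg = sum(labels == 0L)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC = %.4f  (n_pos = %d, n_neg = %d)\n",
              x$auc, x$n_pos, x$n_neg))
  print(x$metrics[, c("cutoff", "sensitivity", "specificity", "ppv", "npv")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' ROC curve coordinates
#'
#' Sensitivity and 1 - specificity at every distinct score threshold,
#' suitable for plotting or export as a table.
#'
#' @param scores Numeric risk scores or probabilities.
#' @param labels Binary labels; 1 = positive.
#' @return Data frame with `threshold`, `sensitivity`, `fpr`, ordered by
#'   decreasing threshold (curve runs from (0,0) to (1,1)).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(t) {
    m <- confusion_metrics(scores, labels, t)
    data.frame(threshold = t, sensitivity = m$sensitivity,
               fpr = 1 - m$specificity)
  }))
}
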