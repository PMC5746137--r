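test_that("AUC matches hand-worked examples including the tie convention", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(roc_auc(c(0.4, 0.6), c(1, 1)), "single class")
  expect_error(roc_auc(numeric(0), integer(0)), "non-empty")
})

test_that("AUC equals the brute-force pairwise concordance oracle", {
  set.seed(314)
  for (i in 1:40) {
    n <- sample(5:200, 1)
    scores <- sample(round(runif(n), 2))   # rounded to force ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels), brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(11)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.5)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(qlogis(scores), labels), a)
  expect_equal(roc_auc(exp(3 * scores), labels), a)
  expect_equal(roc_auc(rank(scores), labels), a)
})

test_that("confusion metrics match direct 2x2 counts", {
  m <- confusion_metrics(c(0.6, 0.5, 0.4, 0.3), c(1, 0, 1, 0), 0.45)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$npv, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(1, 1, 1, 1))
})

test_that("degenerate cut-offs give the boundary metrics with undefined flags", {
  scores <- c(0.2, 0.4, 0.6, 0.8)
  labels <- c(0, 1, 0, 1)
  lo <- confusion_metrics(scores, labels, 0)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  hi <- confusion_metrics(scores, labels, 1.01)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  expect_true(is.nan(hi$ppv))
  expect_false(hi$ppv_defined)
  expect_error(confusion_metrics(numeric(0), integer(0), 0.5), "non-empty")
})

test_that("metrics agree with independently accumulated confusion counts", {
  set.seed(77)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.35)
  for (ct in c(0.25, 0.33, 0.43, 0.7)) {
    m <- confusion_metrics(scores, labels, ct)
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(scores)) {        # independent accumulation
      pos <- scores[i] >= ct
      if (pos && labels[i] == 1) tp <- tp + 1
      if (pos && labels[i] == 0) fp <- fp + 1
      if (!pos && labels[i] == 1) fn <- fn + 1
      if (!pos && labels[i] == 0) tn <- tn + 1
    }
    expect_equal(m$sensitivity, tp / (tp + fn), tolerance = 1e-12)
    expect_equal(m$specificity, tn / (tn + fp), tolerance = 1e-12)
    expect_equal(m$ppv, tp / (tp + fp), tolerance = 1e-12)
    expect_equal(m$npv, tn / (tn + fn), tolerance = 1e-12)
  }
})

test_that("sensitivity decreases and specificity increases along the cut-off grid", {
  set.seed(8)
  scores <- runif(120)
  labels <- rbinom(120, 1, 0.4)
  grid <- seq(0.01, 0.99, by = 0.01)
  sens <- vapply(grid, function(ct)
    confusion_metrics(scores, labels, ct)$sensitivity, numeric(1))
  spec <- vapply(grid, function(ct)
    confusion_metrics(scores, labels, ct)$specificity, numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("optimal cut-off maximises the Youden-type sum with ties toward specificity", {
  # exhaustive grid evaluation: cut-offs 0.15 and 0.85 tie at sum 1.5
  # (sens 1 + spec 0.5 versus sens 0.5 + spec 1); the tie breaks toward
  # the larger cut-off, favouring specificity
  got <- optimal_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0),
                        grid = c(0.15, 0.5, 0.85))
  expect_equal(as.numeric(got), 0.85)
  expect_true(attr(got, "tied"))
  expect_equal(attr(got, "youden_sum"), 1.5)

  # perfectly separated: the grid point in the gap wins
  sep <- optimal_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                        grid = c(0.05, 0.5, 0.95))
  expect_equal(as.numeric(sep), 0.5)
  expect_equal(attr(sep, "youden_sum"), 2)

  single <- optimal_cutoff(c(0.9, 0.1), c(1, 0), grid = 0.4)
  expect_equal(as.numeric(single), 0.4)
  expect_error(optimal_cutoff(c(0.9, 0.1), c(1, 0), grid = numeric(0)),
               "empty")
  expect_error(optimal_cutoff(c(0.9, 0.1), c(1, 1)), "both classes")
})

test_that("spearman_rho matches hand-ranked values and the stats oracle", {
  expect_equal(spearman_rho(1:3, c(2, 4, 6)), 1.0)
  expect_equal(spearman_rho(1:3, c(6, 4, 2)), -1.0)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  set.seed(3)
  x <- rnorm(60)
  y <- x + rnorm(60)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  # with ties: midrank convention must still agree with the stats oracle
  xt <- round(runif(60), 1)
  yt <- round(runif(60), 1)
  expect_equal(spearman_rho(xt, yt), cor(xt, yt, method = "spearman"),
               tolerance = 1e-12)
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- runif(40)
  y <- runif(40)
  r <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), r)
  expect_equal(spearman_rho(x, y^3 + 2), r)
})

test_that("spearman_rho flags constant vectors and short input", {
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
})

test_that("percentile uses the linear-interpolation convention", {
  expect_equal(percentile(1:100, 95), 95.05)
  expect_equal(percentile(1:20, 95), 19.05)
  expect_equal(percentile(7, 42), 7)
  expect_error(percentile(numeric(0), 95), "non-empty")
  expect_error(percentile(1:10, 150), "\\[0, 100\\]")
})

test_that("eval_report bundles AUC with per-cutoff metrics", {
  set.seed(21)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.4)
  rep <- eval_report(scores, labels)
  expect_equal(rep$auc, roc_auc(scores, labels))
  expect_equal(nrow(rep$metrics), 3)
  expect_equal(rep$metrics$cutoff, c(0.25, 0.33, 0.43))
  expect_equal(rep$n_pos + rep$n_neg, 200)
  expect_true(all(rep$metrics$sensitivity >= 0 & rep$metrics$sensitivity <= 1))
})

test_that("roc_auc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- round(runif(150), 2)
  labels <- rbinom(150, 1, 0.45)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})
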