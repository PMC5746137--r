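# Shared fixture builders.  All fixtures are generated in code; nothing is
# read from disk.

# Noise-free control cohort: constant baseline HE4 inflated below the knot
# by the package's renal mechanism. Recovery of the slope from these rows
# must be exact.
noise_free_controls <- function(n = 66, baseline = 40,
                                slope = he4ren::HE4REN_SLOPE,
                                egfr = seq(20, 120, length.out = n)) {
  data.frame(
    egfr = egfr,
    he4 = baseline * exp(-slope * 1e-2 * pmin(egfr - 90, 0))
  )
}

# Brute-force AUC oracle: explicit loop over all (case, control) pairs,
# ties counted one half.  Kept independent of the package's midrank path.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Simulate a G1-or-G2 cancer cohort directly from the printed continuous
# model (independent of the package's generator): used for parameter
# recovery with a known truth.
simulate_from_printed_model <- function(n, seed) {
  set.seed(seed)
  age <- pmin(pmax(rnorm(n, 65, 8), 40), 90)
  he4ren_val <- exp(rnorm(n, log(45), 0.35))
  grade <- sample(1:2, n, replace = TRUE)
  lp <- -15.2 + 0.1 * age + 2.1 * log(he4ren_val) + 0.9 * (grade - 1)
  data.frame(
    age = age, he4ren = he4ren_val, grade = grade,
    log_he4ren = log(he4ren_val), grade_num = grade - 1,
    dmi = runif(n) < plogis(lp)
  )
}
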