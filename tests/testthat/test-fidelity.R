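two_num_schema <- function() {
  cohort_schema(col_numeric("u", -100, 100), col_numeric("v", -100, 100))
}

test_that("identical cohorts score 100 on every component", {
  co <- toy_table(n = 50)
  sch <- toy_schema()
  rep_ <- audit_fidelity(co, co, sch)
  expect_equal(rep_$numerical_stability, 100)
  expect_equal(rep_$categorical_stability, 100)
  expect_equal(rep_$correlation_stability, 100)
  expect_equal(rep_$fidelity_score, 100)
})

test_that("a 5-SD location shift is rejected while a same-law draw is kept", {
  set.seed(31)
  real <- validate_cohort(
    data.frame(u = rnorm(500), v = rnorm(500)), two_num_schema())
  art <- validate_cohort(
    data.frame(u = rnorm(500), v = rnorm(500) + 5), two_num_schema())
  ns <- numerical_stability(real, art, two_num_schema())
  # sanity-check the oracle at this seed: same-law var not rejected, shift rejected
  expect_gt(ns$detail$p_value[ns$detail$variable == "u"], 0.05)
  expect_lt(ns$detail$p_value[ns$detail$variable == "v"], 1e-10)
  expect_equal(ns$score, 50)
})

test_that("categorical stability is 100 minus mean total variation distance", {
  sch <- cohort_schema(col_numeric("x", 0, 1), col_binary("b"),
                       col_binary("c"))
  # b: real 50/50 vs artificial 100/0 -> TVD 0.5, score 50; c identical -> 100
  real <- validate_cohort(
    data.frame(x = runif(4), b = c("0", "0", "1", "1"),
               c = c("0", "1", "0", "1")), sch)
  art <- validate_cohort(
    data.frame(x = runif(4), b = c("0", "0", "0", "0"),
               c = c("1", "0", "1", "0")), sch)
  cs <- categorical_stability(real, art, sch)
  expect_equal(cs$detail$stability[cs$detail$variable == "b"], 50)
  expect_equal(cs$detail$stability[cs$detail$variable == "c"], 100)
  expect_equal(cs$score, 75)
})

test_that("correlation stability reflects the mean off-diagonal difference", {
  # exact pair construction: r_real = 0.5, r_art = 0.1 -> 100 * (1 - 0.4) = 60
  make_pair <- function(r, seed) {
    set.seed(seed)
    n <- 2000
    u <- rnorm(n)
    v <- r * u + sqrt(1 - r^2) * rnorm(n)
    # enforce the sample correlation exactly via whitening + recoloring
    M <- cbind(u, v)
    M <- scale(M) %*% solve(chol(cov(scale(M))))
    M <- M %*% chol(matrix(c(1, r, r, 1), 2))
    validate_cohort(data.frame(u = M[, 1], v = M[, 2]), two_num_schema())
  }
  real <- make_pair(0.5, 41)
  art <- make_pair(0.1, 42)
  cs <- correlation_stability(real, art, two_num_schema())
  expect_equal(cs$score, 60, tolerance = 1e-10)
  expect_equal(cs$difference[1, 2], 0.4, tolerance = 1e-10)
  # a mean absolute off-diagonal difference of 0.074 reads back as 92.6
  expect_equal(100 * (1 - mean(abs(cs$difference[upper.tri(cs$difference)]))),
               cs$score)
})

test_that("constant columns get zero correlations with a warning", {
  real <- validate_cohort(data.frame(u = c(1, 2, 3), v = c(2, 2, 2)),
                          two_num_schema())
  art <- validate_cohort(data.frame(u = c(1, 3, 2), v = c(1, 2, 3)),
                         two_num_schema())
  expect_warning(cs <- correlation_stability(real, art, two_num_schema()),
                 "constant")
  expect_equal(cs$real[1, 2], 0)
})

test_that("the composite score is the rounded arithmetic mean", {
  expect_equal(fidelity_score(100, 96.4, 97.1), 97.8)
  expect_equal(fidelity_score(100, 91.2, 92.6), 94.6)
  expect_equal(fidelity_score(0, 0, 0), 0)
  # idempotence of the mean across the scale
  for (a in c(0, 12.3, 50, 77.7, 100)) {
    expect_equal(fidelity_score(a, a, a), a)
  }
  expect_warning(m <- fidelity_score(NA, 80, 90), "dropped")
  expect_equal(m, 85)
})

test_that("components are invariant to row order of either cohort", {
  co <- toy_table(n = 40, seed = 3)
  art <- toy_table(n = 60, seed = 4)
  sch <- toy_schema()
  g1 <- glance(audit_fidelity(co, art, sch))
  set.seed(5)
  g2 <- glance(audit_fidelity(co[sample(40), ], art[sample(60), ], sch))
  expect_equal(g1, g2)
})

test_that("fidelity self-audit of same-law resamples is calibrated above 90", {
  # Per-seed, the numerical component is a KS false-rejection count
  # (Binomial(19, alpha)), so single draws legitimately dip to 89.5 with one
  # extra rejection; calibration is therefore checked across seeds: the
  # categorical and correlation components clear 90 every time, and the
  # numerical component clears 90 on average (its expectation is ~95).
  cfg <- fixture_config(seed = 1)
  num <- numeric(5)
  for (i in 1:5) {
    re <- resample_cohort(cfg, n = 5000, seed = 76 + i)
    rep_ <- audit_fidelity(fixture_cohort(), re, fixture_schema())
    num[i] <- rep_$numerical_stability
    expect_gt(rep_$categorical_stability, 90)
    expect_gt(rep_$correlation_stability, 90)
  }
  expect_gt(mean(num), 90)
})
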