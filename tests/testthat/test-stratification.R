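test_that("median split honours the at-or-below rule", {
  set.seed(1)
  sc <- rnorm(231)
  g <- median_split(sc)
  expect_equal(sum(g == "lower"), 116)
  expect_equal(sum(g == "higher"), 115)
  expect_true(all(median_split(rep(2, 10)) == "lower"))
  g2 <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(g2), c("lower", "lower", "higher", "higher"))
  # invariant under strictly increasing transforms
  expect_identical(median_split(exp(sc)), g)
})

test_that("Kaplan-Meier steps, medians and degenerate cases are right", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)       # first time S <= 0.5
  # no censoring: KM equals the empirical survival function
  set.seed(2)
  tm <- rexp(400, 1 / 300)
  km2 <- kaplan_meier(tm, rep(1, 400))
  emp <- vapply(km2$time, function(t) mean(tm > t), numeric(1))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
  # exponential sample: median near ln2 / lambda
  tm3 <- rexp(5000, 1 / 500)
  km3 <- kaplan_meier(tm3, rep(1, 5000))
  expect_lt(abs(km3$median - 500 * log(2)) / (500 * log(2)), 0.05)
  expect_true(km3$median_lcl <= km3$median && km3$median <= km3$median_ucl)
  # all censored: flat curve, median not reached
  km4 <- kaplan_meier(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km4$surv == 1))
  expect_true(is.na(km4$median))
})

test_that("log-rank behaves at its null and under real separation", {
  tm <- c(3, 5, 8, 11, 14, 20); ev <- c(1, 1, 0, 1, 1, 1)
  lr0 <- logrank_test(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # matches survdiff on a hand-sized fixture and is label-symmetric
  g <- c("a", "b", "a", "b", "a", "b")
  lr1 <- logrank_test(tm, ev, g)
  lr2 <- logrank_test(tm, ev, rev(g))
  expect_equal(lr1$chisq, lr2$chisq)
  expect_error(logrank_test(tm, ev, rep("a", 6)), "two groups")
  # power at hazard ratio 3 with 200 per arm
  ps <- vapply(1:5, function(sd) {
    set.seed(sd)
    t1 <- rexp(200, 1 / 600); t2 <- rexp(200, 3 / 600)
    logrank_test(c(t1, t2), rep(1, 400), rep(1:2, each = 200))$p_value
  }, numeric(1))
  expect_true(all(ps < 0.001))
})

test_that("log-rank statistic matches a hand-computed observed-minus-expected table", {
  tm <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 1, 1, 1, 1)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  # hand computation over the 6 event times (no ties, no censoring)
  at_risk <- 6:1
  in_a <- c(3, 2, 1, 0, 0, 0)
  d_a <- c(1, 1, 1, 0, 0, 0)
  E <- in_a / at_risk
  V <- (in_a / at_risk) * (1 - in_a / at_risk) * 1  # single event per time
  chisq_hand <- sum(d_a - E)^2 / sum(V)
  lr <- logrank_test(tm, ev, g)
  expect_equal(lr$chisq, chisq_hand, tolerance = 1e-12)
})

test_that("the continuous-score hazard ratio is estimated and scales correctly", {
  set.seed(4)
  n <- 2000
  x <- rnorm(n)
  u <- runif(n)
  tm <- 900 * (-log(u) / exp(log(1.913) * x))^(1 / 1.1)
  ev <- as.integer(tm <= 3650)
  tm <- pmin(tm, 3650)
  hr <- score_hazard_ratio(x, tm, ev)
  expect_lt(abs(hr$hr - 1.913) / 1.913, 0.10)
  expect_lt(hr$p_value, 1e-6)
  # halving the scale doubles the per-unit log hazard
  hr2 <- score_hazard_ratio(2 * x, tm, ev)
  expect_equal(hr2$beta, hr$beta / 2, tolerance = 1e-6)
  expect_error(score_hazard_ratio(rep(1, n), tm, ev), "zero variance")
})

test_that("the null score's HR interval covers 1 at the nominal rate", {
  cover <- vapply(1:100, function(sd) {
    set.seed(sd)
    x <- rnorm(120)
    tm <- rexp(120, 1 / 500); ev <- rbinom(120, 1, 0.7)
    h <- score_hazard_ratio(x, tm, ev)
    h$lcl <= 1 && 1 <= h$ucl
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lte(mean(cover), 1)
})

test_that("stratification orders the risk groups as the truth dictates", {
  ch <- generate_cohort(cohort_sim_params(
    n_patients = 2000, true_beta = c(gene05 = 1.2), seed = 6))
  st <- stratify_cohort(ch$linpred, ch$time, ch$event)
  expect_equal(st$n_lower + st$n_higher, 2000)
  expect_lte(abs(st$n_lower - st$n_higher), 1)
  expect_lt(st$logrank$p_value, 1e-10)
  expect_gt(st$hr$hr, 1)
  expect_lt(st$km$higher$median, st$km$lower$median)
  # KM curves ordered at every event time of the higher-risk group
  lo <- stats::stepfun(st$km$lower$time, c(1, st$km$lower$surv))
  expect_true(all(st$km$higher$surv <= lo(st$km$higher$time) + 1e-9))
})
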