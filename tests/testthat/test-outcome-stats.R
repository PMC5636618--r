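test_that("summary-statistics t-test agrees with a raw-data t-test", {
  # raw triples constructed to have exactly the requested mean and SD
  raw <- function(m, s) c(m - s, m, m + s)
  a <- group_summary("a", 10.47, 1.86, 3)
  b <- group_summary("b", 3.57, 1.57, 3)
  got <- t_test_from_summary(a, b)
  ht <- t.test(raw(10.47, 1.86), raw(3.57, 1.57), var.equal = TRUE)
  expect_equal(got$t, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ht$p.value, tolerance = 1e-10)
  # welch variant
  gw <- t_test_from_summary(a, b, variant = "welch")
  hw <- t.test(raw(10.47, 1.86), raw(3.57, 1.57))
  expect_equal(gw$t, unname(hw$statistic), tolerance = 1e-10)
  expect_equal(gw$df, unname(hw$parameter), tolerance = 1e-10)
  # equal groups: t = 0, p = 1
  same <- t_test_from_summary(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # degenerate zero-SD conventions
  z1 <- t_test_from_summary(group_summary("x", 5, 0, 3),
                            group_summary("y", 5, 0, 3))
  expect_equal(z1$p_value, 1)
  z2 <- t_test_from_summary(group_summary("x", 5, 0, 3),
                            group_summary("y", 4, 0, 3))
  expect_equal(z2$p_value, 0)
})

test_that("t-test p-value agrees with direct integration of the t density", {
  got <- t_test_from_summary(group_summary("a", 6.73, 0.43, 3),
                             group_summary("b", 1.36, 0.36, 3))
  expect_equal(got$p_value, t_pvalue_by_integration(got$t, got$df),
               tolerance = 1e-8)
  expect_equal(got$p_value, 7.7e-5, tolerance = 0.02)
})

test_that("one-way ANOVA matches brute-force sums of squares", {
  set.seed(8)
  g <- rep(c("a", "b", "c"), times = c(5, 7, 6))
  y <- rnorm(length(g), mean = c(a = 0, b = 0.5, c = 1)[g])
  got <- anova_oneway(y, g)
  gm <- mean(y)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ss_b / 2) / (ss_w / (length(y) - 3))
  expect_equal(got$F, f_oracle, tolerance = 1e-10)
  expect_equal(got$df_between, 2)
  expect_equal(got$df_within, length(y) - 3)
  # identical observations across groups: F = 0
  expect_equal(anova_oneway(rep(c(1, 2, 3), 2),
                            rep(c("a", "b"), each = 3))$F, 0,
               tolerance = 1e-12)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "at least two")
})

test_that("Kaplan-Meier estimator reproduces hand-computed product-limit tables", {
  # the five-animal structure with one long-term survivor: plateau 1/5
  km <- km_estimate(c(10, 15, 20, 30, 53), c(1, 1, 1, 1, 0))
  expect_equal(min(km$surv), 0.2, tolerance = 1e-12)
  expect_equal(km_survival_at(km, c(9, 12, 53)), c(1, 0.8, 0.2))
  # six animals, two survivors: plateau 1/3
  km6 <- km_estimate(c(13, 13, 17, 27, 53, 53), c(1, 1, 1, 1, 0, 0))
  expect_equal(min(km6$surv), 1 / 3, tolerance = 1e-12)
  # no censoring: empirical survival function
  kme <- km_estimate(c(2, 5, 9), c(1, 1, 1))
  expect_equal(kme$surv, c(2 / 3, 1 / 3, 0))
  # mixed tie/censor worked example against the manual table
  tm <- c(5, 5, 5, 8, 8, 10, 12, 15)
  ev <- c(1, 1, 0, 1, 0, 1, 0, 1)
  km8 <- km_estimate(tm, ev)
  oracle <- manual_km(tm, ev)
  expect_equal(km_survival_at(km8, oracle$time), oracle$surv,
               tolerance = 1e-12)
  expect_equal(oracle$surv, c(0.75, 0.6, 0.4, 0), tolerance = 1e-12)
  expect_error(km_estimate(c(0, 3), c(1, 1)), "> 0")
})

test_that("KM estimate is order-invariant and unaffected by late censoring", {
  tm <- c(5, 5, 5, 8, 8, 10, 12, 15)
  ev <- c(1, 1, 0, 1, 0, 1, 0, 1)
  set.seed(4)
  ord <- sample(seq_along(tm))
  a <- km_estimate(tm, ev)
  b <- km_estimate(tm[ord], ev[ord])
  expect_equal(a$surv, b$surv)
  # moving a censoring time between two adjacent event times leaves the
  # estimate unchanged (at-risk sets at event times are identical)
  # the original censoring at 12 sits between the events at 10 and 15;
  # moving it to 13.5 keeps every at-risk set identical
  c2 <- km_estimate(c(tm[-7], 13.5), c(ev[-7], 0))
  expect_equal(km_survival_at(c2, c(5, 8, 10, 15)),
               km_survival_at(a, c(5, 8, 10, 15)))
})

test_that("Weibull fit reduces to the closed-form exponential MLE", {
  tm <- c(3, 7, 11, 20, 25, 40)
  ev <- c(1, 1, 1, 0, 1, 0)
  fit <- weibull_fit(tm, ev, fix_shape_one = TRUE)
  expect_equal(fit$shape, 1)
  expect_equal(fit$scale, sum(tm) / sum(ev), tolerance = 1e-8)
  expect_error(weibull_fit(tm, rep(0, 6)), "events")
})

test_that("Weibull log-likelihood is locally optimal at the fit", {
  set.seed(31)
  tm <- rweibull(60, shape = 2, scale = 20)
  ev <- as.integer(tm < 35)
  tm <- pmin(tm, 35)
  fit <- weibull_fit(tm, ev)
  ll_hat <- weibull_loglik(fit$shape, fit$scale, time_days = tm, event = ev)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  for (i in 1:100) {
    ll_p <- weibull_loglik(fit$shape * exp(rnorm(1, 0, 0.05)),
                           fit$scale * exp(rnorm(1, 0, 0.05)),
                           time_days = tm, event = ev)
    expect_lte(ll_p, ll_hat + 1e-8)
  }
})

test_that("Weibull parameter recovery improves with sample size", {
  bias <- vapply(c(50, 200, 800), function(n) {
    shapes <- vapply(1:20, function(s) {
      set.seed(1000 + n + s)
      weibull_fit(rweibull(n, 2, 20), rep(1, n))$shape
    }, numeric(1))
    abs(median(shapes) - 2) / 2
  }, numeric(1))
  expect_lt(bias[2], 0.10)
  expect_lt(bias[3], bias[1])
})

test_that("pairwise Weibull contrast detects a known time shift", {
  set.seed(17)
  t1 <- rweibull(30, 3, 15)
  t2 <- rweibull(30, 3, 30)
  tm <- c(t1, t2)
  ev <- rep(1, 60)
  gr <- rep(c("a", "b"), each = 30)
  ct <- weibull_contrast(tm, ev, gr, "a", "b")
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p_value, 0.001)
  expect_equal(ct$estimate, log(2), tolerance = 0.25)
  # no effect under the null (same scale)
  set.seed(18)
  ct0 <- weibull_contrast(rweibull(60, 3, 15), rep(1, 60), gr, "a", "b")
  expect_gt(ct0$p_value, 0.05)
})
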