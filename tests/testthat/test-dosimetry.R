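sc <- load_i131_scheme()

test_that("uptake converts to physical activity under both decay conventions", {
  tac <- time_activity_curve(2, 10, injected_mbq = 20)
  expect_equal(to_physical_activity(tac, sc)$activity_mbq_g, 2.0)
  # decay-corrected value at one half-life halves
  tac2 <- time_activity_curve(sc$half_life_h, 10, 20, decay_corrected = TRUE)
  expect_equal(to_physical_activity(tac2, sc)$activity_mbq_g, 1.0,
               tolerance = 1e-12)
  # worked value from the shipped curves: 10.89 %ID/g of 20 MBq
  tac3 <- time_activity_curve(2, 10.89, 20)
  expect_equal(to_physical_activity(tac3, sc)$activity_mbq_g, 2.178)
  expect_error(time_activity_curve(c(2, 2), c(1, 1), 20), "increasing")
})

test_that("cumulated activity integrates trapezoids plus the decay tail", {
  lambda <- decay_constant(sc)
  # single point, 1 MBq/g at t = 0: tail only, A/lambda ~ 277.9 MBq h/g
  ca <- cumulated_activity(time_activity_curve(0, 5, 20), sc)
  expect_equal(ca$value, 1 / lambda, tolerance = 1e-12)
  expect_equal(ca$value, 277.87, tolerance = 1e-3)
  # constant curve, tail disabled: plain trapezoid
  tac <- time_activity_curve(c(0, 10), c(5, 5), 20)  # 1 MBq/g at both times
  ca2 <- cumulated_activity(tac, sc, tail = FALSE)
  expect_equal(ca2$value, 10, tolerance = 1e-12)
  # segments always sum to the value and are nonnegative
  expect_equal(sum(ca2$segments), ca2$value)
  expect_true(all(ca2$segments >= 0))
})

test_that("integration matches a fine-grid quadrature oracle to 1e-6", {
  lambda <- decay_constant(sc)
  for (grp in shipped_tacs()) {
    act <- to_physical_activity(grp, sc)$activity_mbq_g
    for (start in c("zero", "flat")) {
      ca <- cumulated_activity(grp, sc, start = start)
      oracle <- quad_tac_oracle(grp$time_h, act, lambda, start = start)
      expect_equal(ca$value, oracle, tolerance = 1e-6)
    }
  }
})

test_that("cumulated activity is invariant to interpolated points and the tail never increases when disabled", {
  tac <- shipped_tacs()[["MRT"]]
  ca <- cumulated_activity(tac, sc)
  # insert midpoints on the linear segments
  t2 <- sort(c(tac$time_h, (tac$time_h[-1] + tac$time_h[-5]) / 2))
  a2 <- approx(tac$time_h, tac$pct_id_g, xout = t2)$y
  ca2 <- cumulated_activity(time_activity_curve(t2, a2, 20), sc)
  expect_equal(ca$value, ca2$value, tolerance = 1e-9)
  # tail contribution is exactly A_last / lambda; dropping it lowers the value
  a_last <- to_physical_activity(tac, sc)$activity_mbq_g[5]
  expect_equal(unname(ca$segments["tail"]), a_last / decay_constant(sc),
               tolerance = 1e-12)
  expect_lt(cumulated_activity(tac, sc, tail = FALSE)$value, ca$value)
})

test_that("absorbed dose is cumulated activity times mass times S", {
  cum <- structure(list(value = 100, segments = c(all = 100),
                        assumptions = list(decay_corrected = FALSE,
                                           start = "zero", tail = TRUE),
                        label = "x"), class = "cumulated_activity")
  rep <- absorbed_dose(cum, 0.5, 5e-11)
  expect_equal(rep$dose_gy, 100 * 0.5 * 3.6e9 * 5e-11, tolerance = 1e-12)
  expect_equal(rep$dose_gy, 9.0, tolerance = 1e-12)
  cum0 <- cum; cum0$value <- 0
  expect_equal(absorbed_dose(cum0, 0.5, 5e-11)$dose_gy, 0)
  expect_error(absorbed_dose(cum, 0, 5e-11), "mass")
})

test_that("the EBRT-primed to MRT dose ratio exceeds 2 under every convention", {
  for (dc in c(FALSE, TRUE)) {
    tacs <- shipped_tacs(decay_corrected = dc)
    for (start in c("zero", "flat")) {
      for (tail in c(TRUE, FALSE)) {
        reps <- lapply(tacs, function(tc)
          absorbed_dose(cumulated_activity(tc, sc, start = start,
                                           tail = tail), 0.5, 5.9e-11))
        r <- dose_ratio(reps[["EBRT+MRT"]], reps[["MRT"]])
        expect_gte(r, 2)
        # S-value cancels: ratio equals the cumulated-activity ratio
        ca <- vapply(tacs, function(tc)
          cumulated_activity(tc, sc, start = start, tail = tail)$value,
          numeric(1))
        expect_equal(r, unname(ca["EBRT+MRT"] / ca["MRT"]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("dose ratio guards conventions and degenerate input", {
  tacs <- shipped_tacs()
  r1 <- absorbed_dose(cumulated_activity(tacs[[1]], sc), 0.5, 5e-11)
  r2 <- absorbed_dose(cumulated_activity(tacs[[2]], sc, start = "flat"),
                      0.5, 5e-11)
  expect_equal(dose_ratio(r1, r1), 1)
  expect_error(dose_ratio(r1, r2), "convention")
})
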