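# Independent oracles used across the suite.  These deliberately avoid the
# package's own integration code paths.

# fine-grid quadrature of a piecewise-linear activity curve with an
# exponential tail: trapezoid sum on a 0.005 h grid, tail truncated at 30
# half-lives (truncation error ~ 1e-13 relative)
quad_tac_oracle <- function(time_h, act, lambda_h, start = "zero",
                            tail = TRUE, grid_h = 0.005) {
  t0 <- if (start == "zero") c(0, time_h) else c(0, time_h)
  a0 <- if (start == "zero") c(0, act) else c(act[1], act)
  tt <- seq(0, max(time_h), by = grid_h)
  aa <- approx(t0, a0, xout = tt)$y
  core <- sum((aa[-1] + aa[-length(aa)]) / 2) * grid_h
  tail_part <- 0
  if (tail) {
    tl <- seq(0, 30 * log(2) / lambda_h, by = grid_h)
    av <- act[length(act)] * exp(-lambda_h * tl)
    tail_part <- sum((av[-1] + av[-length(av)]) / 2) * grid_h
  }
  core + tail_part
}

# manual product-limit table: events processed before censorings at ties
manual_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# closed-form paired t-test
paired_t_oracle <- function(x, y) {
  d <- y - x
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t, df = length(d) - 1,
       p = 2 * pt(-abs(t), length(d) - 1))
}

# two-sided p from the t distribution by numerical integration of the
# density (independent of pt())
t_pvalue_by_integration <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}

# the two shipped group-mean uptake curves as time_activity_curve objects
shipped_tacs <- function(decay_corrected = FALSE) {
  su <- uptake_summaries()
  lapply(split(su, su$group), function(g) {
    g <- g[order(g$time_h), ]
    time_activity_curve(g$time_h, g$mean_pct_id_g, injected_mbq = 20,
                        decay_corrected = decay_corrected,
                        label = g$group[1])
  })[c("EBRT+MRT", "MRT")]
}
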