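# Synthetic cohort generator.
#
# The generator emulates the three-study design: cross-sectional tumour
# biodistribution (%ID/g at 2/4/24/48/72 h, terminal sampling), five-arm
# longitudinal tumour growth with an 800 mm^3 endpoint and day-53
# censoring, and longitudinal DCE imaging of three animals at baseline,
# 24 h and 72 h after external-beam irradiation.  All generators are pure
# functions of (config, seed); per-generator substreams are derived from
# one global seed by fixed offsets.

# location parameter of a zero-truncated normal whose mean equals `target`
.truncnorm_location <- function(target, sd) {
  if (sd == 0) return(target)
  f <- function(mu) mu + sd * dnorm(mu / sd) / pnorm(mu / sd) - target
  uniroot(f, c(target - 6 * sd, target + sd), tol = 1e-12)$root
}

.rtruncnorm0 <- function(n, mean_target, sd) {
  if (sd == 0) return(rep(mean_target, n))
  mu <- .truncnorm_location(mean_target, sd)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- rnorm(length(todo), mu, sd)
    ok <- x > 0
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

.rnorm_trunc_low <- function(n, mean, sd, lower) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- rnorm(length(todo), mean, sd)
    ok <- x >= lower
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the study conditions the package emulates: group sizes
#' (control 3, EBRT 5, MRT 6, EBRTt1+MRT 5, MRT+EBRTt2 6), biodistribution
#' group means/SDs per timepoint (the shipped [uptake_summaries()]),
#' baseline tumour volume 500 mm^3 (SD 26), the 800 mm^3 endpoint with
#' imaging at days 0/6/7/13/17/20 then weekly and censoring at day 53, and
#' DCE enhancement elevated 24 h after irradiation.
#'
#' Growth trajectories use a response-anchored model
#' `V(t) = V0 * exp(log(rho) w(t)) * exp(gamma (t - delay)+) * noise` where
#' `rho` is the per-animal day-6 volume ratio (lognormal around the group
#' anchor, so the expected day-6 percent change equals the anchor exactly),
#' `w(t)` is a saturating response shape equal to 1 at day 6, and regrowth
#' at rate `gamma` starts after a random `delay`; a per-animal cure
#' probability yields censored long-term survivors.  The sequential
#' combination arm applies a second anchored response from day 6 (its EBRT
#' day).  Controls grow exponentially at 0.10/day, set by the requirement
#' that control tumours reach the endpoint by day 7.
#'
#' @param ... replacements for any default element (checked by name).
#' @return An object of class `synth_config` (a nested list).
#' @export
synth_config <- function(...) {
  cfg <- list(
    biodistribution = list(
      targets = uptake_summaries(),      # group/time mean, SD, n
      injected_mbq = 20
    ),
    growth = list(
      baseline_mean_mm3 = 500,
      baseline_sd_mm3 = 26,
      endpoint_mm3 = 800,
      censor_day = 53,
      imaging_days = c(0, 6, 7, 13, 17, 20, 27, 34, 41, 48, 53),
      measurement_sdlog = 0.03,          # volumetry noise (lognormal)
      groups = list(
        control = list(n = 3, ratio_day6 = NA, sd_pct_day6 = NA,
                       growth_rate = 0.10, growth_rate_sd = 0.006,
                       delay_mean = 0, delay_sd = 0, regrow_rate = 0.10,
                       p_cure = 0, ratio2_day13 = NA, sd2_pct_day13 = NA),
        EBRT = list(n = 5, ratio_day6 = 0.35, sd_pct_day6 = 16.67,
                    growth_rate = NA, growth_rate_sd = NA,
                    delay_mean = 10, delay_sd = 2.5, regrow_rate = 0.12,
                    p_cure = 0, ratio2_day13 = NA, sd2_pct_day13 = NA),
        MRT = list(n = 6, ratio_day6 = 1.0745, sd_pct_day6 = 4.82,
                   growth_rate = NA, growth_rate_sd = NA,
                   delay_mean = 7, delay_sd = 1.5, regrow_rate = 0.10,
                   p_cure = 0, ratio2_day13 = NA, sd2_pct_day13 = NA),
        `EBRTt1+MRT` = list(n = 5, ratio_day6 = 0.0896, sd_pct_day6 = 2.94,
                            growth_rate = NA, growth_rate_sd = NA,
                            delay_mean = 17, delay_sd = 3, regrow_rate = 0.18,
                            p_cure = 0.2, ratio2_day13 = NA,
                            sd2_pct_day13 = NA),
        `MRT+EBRTt2` = list(n = 6, ratio_day6 = 0.9785, sd_pct_day6 = 4.35,
                            growth_rate = NA, growth_rate_sd = NA,
                            delay_mean = 17, delay_sd = 3, regrow_rate = 0.18,
                            p_cure = 1 / 3, ratio2_day13 = 0.10,
                            sd2_pct_day13 = 3)
      ),
      response_tau = 2.5                  # days, clearance of killed volume
    ),
    dce = list(
      n_animals = 3,
      n_repeats = 60, dt_s = 9, injection_index = 12,
      sessions = c("baseline", "24h", "72h"),
      tumour_multiplier = c(baseline = 1, `24h` = 2.0, `72h` = 1.7),
      muscle_multiplier = c(baseline = 1, `24h` = 1, `72h` = 1),
      baseline_signal = 100,
      amplitude = c(tumour = 40, muscle = 12),
      bolus_alpha = 1.5, bolus_tp_s = 90,
      session_sdlog = 0.08,               # per animal-session response jitter
      noise_sd = 2
    ),
    seed_offsets = c(biodistribution = 0L, growth = 1000L, dce = 2000L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config element: ", nm)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  }
  structure(cfg, class = "synth_config")
}

#' Synthetic tumour biodistribution table
#'
#' Per-animal %ID/g values, one terminal measurement per animal (the
#' excision design): for each group and timepoint `n` animals drawn from a
#' zero-truncated normal whose mean is calibrated to equal the configured
#' group mean exactly.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return Data frame with columns `group`, `animal_id`, `time_h`,
#'   `pct_id_per_g`.
#' @export
#' @examples
#' head(gen_biodistribution(synth_config(), seed = 1))
gen_biodistribution <- function(config = synth_config(), seed = 1L) {
  set.seed(seed + config$seed_offsets[["biodistribution"]])
  tg <- config$biodistribution$targets
  out <- lapply(seq_len(nrow(tg)), function(i) {
    v <- .rtruncnorm0(tg$n[i], tg$mean_pct_id_g[i], tg$sd_pct_id_g[i])
    data.frame(group = tg$group[i],
               animal_id = sprintf("%s_t%g_%d", tg$group[i], tg$time_h[i],
                                   seq_len(tg$n[i])),
               time_h = tg$time_h[i], pct_id_per_g = v)
  })
  do.call(rbind, out)
}

# deterministic trajectory factor for one animal at times t (days)
.growth_factor <- function(t, rho1, rho2, delay, regrow, cured, tau) {
  w1 <- (1 - exp(-t / tau)) / (1 - exp(-6 / tau))
  f <- exp(log(rho1) * w1)
  if (!is.na(rho2)) {
    t2 <- pmax(t - 6, 0)
    w2 <- (1 - exp(-t2 / tau)) / (1 - exp(-7 / tau))
    f <- f * exp(log(rho2) * w2)
  }
  if (!cured) f <- f * exp(regrow * pmax(t - delay, 0))
  f
}

#' Synthetic tumour growth cohort with time-to-endpoint records
#'
#' Generates per-animal volume trajectories at the imaging days and derives
#' survival records: the event time is the first imaging day at which the
#' measured volume reaches the endpoint; animals never reaching it are
#' censored at the censoring day.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return A list with data frames `volumes` (`group`, `animal_id`, `day`,
#'   `volume_mm3`) and `survival` (`group`, `animal_id`, `time_days`,
#'   `event`).
#' @export
#' @examples
#' coh <- gen_growth_cohort(synth_config(), seed = 1)
#' table(coh$survival$group, coh$survival$event)
gen_growth_cohort <- function(config = synth_config(), seed = 1L) {
  set.seed(seed + config$seed_offsets[["growth"]])
  g <- config$growth
  days <- g$imaging_days
  sdm <- g$measurement_sdlog
  vols <- list()
  surv <- list()
  for (gname in names(g$groups)) {
    p <- g$groups[[gname]]
    for (i in seq_len(p$n)) {
      v0 <- rnorm(1, g$baseline_mean_mm3, g$baseline_sd_mm3)
      if (is.na(p$ratio_day6)) {
        # control: exponential growth
        rate <- rnorm(1, p$growth_rate, p$growth_rate_sd)
        f <- exp(rate * days)
      } else {
        # anchored response; lognormal rho with expected measured day-6
        # ratio equal to the anchor (corrects for the two measurement
        # noises entering the ratio)
        sd_ratio <- p$sd_pct_day6 / 100
        s2tot <- log(1 + (sd_ratio / p$ratio_day6)^2)
        s2xi <- max(s2tot - 2 * sdm^2, 0)
        rho1 <- p$ratio_day6 *
          exp(rnorm(1, 0, sqrt(s2xi)) - s2xi / 2 - sdm^2)
        rho2 <- NA
        if (!is.na(p$ratio2_day13)) {
          sd2 <- p$sd2_pct_day13 / 100
          s2b <- log(1 + (sd2 / p$ratio2_day13)^2)
          rho2 <- p$ratio2_day13 * exp(rnorm(1, 0, sqrt(s2b)) - s2b / 2)
        }
        cured <- runif(1) < p$p_cure
        delay <- .rnorm_trunc_low(1, p$delay_mean, p$delay_sd, 6)
        f <- .growth_factor(days, rho1, rho2, delay, p$regrow_rate, cured,
                            g$response_tau)
      }
      v <- v0 * f * exp(rnorm(length(days), 0, sdm))
      id <- sprintf("%s_%d", gname, i)
      hit <- which(v >= g$endpoint_mm3)
      # animals are removed once the endpoint volume is reached
      last <- if (length(hit)) hit[1] else length(days)
      vols[[id]] <- data.frame(group = gname, animal_id = id,
                               day = days[seq_len(last)],
                               volume_mm3 = v[seq_len(last)])
      surv[[id]] <- data.frame(
        group = gname, animal_id = id,
        time_days = if (length(hit)) days[hit[1]] else g$censor_day,
        event = length(hit) > 0)
    }
  }
  list(volumes = do.call(rbind, c(vols, list(make.row.names = FALSE))),
       survival = do.call(rbind, c(surv, list(make.row.names = FALSE))))
}

#' Synthetic DCE-MRI enhancement curves
#'
#' Signal model: baseline level plus an amplitude-scaled gamma-variate
#' bolus response (tumour amplitude multiplied by the session permeability
#' multiplier; muscle fixed at 1 across sessions) plus Gaussian noise, at
#' the acquisition timing of the emulated protocol (9 s repeats, 60
#' frames).
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return Data frame with columns `animal_id`, `session`, `region`,
#'   `time_s`, `signal`, plus attribute `injection_index`.
#' @export
gen_dce <- function(config = synth_config(), seed = 1L) {
  set.seed(seed + config$seed_offsets[["dce"]])
  d <- config$dce
  times <- (seq_len(d$n_repeats) - 1) * d$dt_s
  t_inj <- times[d$injection_index]
  bolus <- function(t) {
    x <- pmax(t - t_inj, 0) / d$bolus_tp_s
    (x^d$bolus_alpha) * exp(d$bolus_alpha * (1 - x))
  }
  rows <- list()
  for (a in seq_len(d$n_animals)) {
    for (s in d$sessions) {
      for (reg in c("tumour", "muscle")) {
        mult <- if (reg == "tumour") d$tumour_multiplier[[s]]
                else d$muscle_multiplier[[s]]
        amp <- d$amplitude[[reg]] * mult *
          exp(rnorm(1, 0, d$session_sdlog) - d$session_sdlog^2 / 2)
        sig <- d$baseline_signal + amp * bolus(times) +
          rnorm(length(times), 0, d$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("m%d", a), session = s, region = reg,
          time_s = times, signal = pmax(sig, 0))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "injection_index") <- d$injection_index
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `tac.csv`, `volumes.csv`, `survival.csv` and `dce.csv` generated
#' from one config and seed; byte-identical for identical inputs.
#'
#' @param dir output directory (created if needed).
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return Invisibly, the vector of file paths written.
#' @export
write_synthetic_dataset <- function(dir, config = synth_config(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("tac.csv", "volumes.csv", "survival.csv",
                            "dce.csv"))
  tac <- gen_biodistribution(config, seed)
  coh <- gen_growth_cohort(config, seed)
  dce <- gen_dce(config, seed)
  write.csv(tac, paths[1], row.names = FALSE)
  write.csv(coh$volumes, paths[2], row.names = FALSE)
  write.csv(coh$survival, paths[3], row.names = FALSE)
  write.csv(dce, paths[4], row.names = FALSE)
  invisible(paths)
}
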