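# Electron and photon interaction data for liquid water (rho = 1 g/cm^3).
#
# Electrons: Berger-Seltzer collision stopping power (Moller cross section,
# Z/A = 0.55509, mean excitation energy I = 75 eV, density effect neglected,
# adequate below ~1 MeV), integrated to CSDA ranges measured down to the
# 10 keV transport cutoff.  Radiative losses are ignored (radiative yield in
# water < 1 % at these energies).
#
# Photons: incoherent scattering from the analytic Klein-Nishina cross
# section; photoelectric and mass energy-absorption coefficients from the
# shipped table (log-log interpolation); Rayleigh scattering ignored.

.ZA_WATER <- 0.55509
.I_WATER_KEV <- 75e-3
.E_CUT_KEV <- 10        # electron transport cutoff (residual deposited locally)
.PHOTON_CUT_KEV <- 1    # photon cutoff (deposited locally)

#' Collision stopping power of water for electrons
#'
#' Berger-Seltzer formula (I = 75 eV, no density-effect correction).
#'
#' @param energy_kev electron kinetic energy in keV; vectorised.
#' @return Mass collision stopping power in MeV cm^2/g.
#' @export
#' @examples
#' water_stopping_power(c(10, 100, 1000))  # ~22.6, ~4.12, ~1.85
water_stopping_power <- function(energy_kev) {
  tau <- energy_kev / .ELECTRON_REST_KEV
  gamma <- 1 + tau
  beta2 <- 1 - 1 / gamma^2
  i_ratio <- .I_WATER_KEV / .ELECTRON_REST_KEV
  lterm <- log(tau^2 * (tau + 2) / (2 * i_ratio^2))
  f <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / gamma^2
  0.153536 * .ZA_WATER / beta2 * (lterm + f)
}

# CSDA range table from the cutoff upward, built once and cached.
.range_table <- function() {
  if (!is.null(.radmibg_cache$range_table)) return(.radmibg_cache$range_table)
  e <- exp(seq(log(.E_CUT_KEV), log(2000), length.out = 4000))
  s_kev_cm <- water_stopping_power(e) * 1000  # keV/cm at unit density
  inv <- 1 / s_kev_cm
  r <- c(0, cumsum((inv[-1] + inv[-length(inv)]) / 2 * diff(e)))
  tab <- list(e = e, r = r,
              r_of_e = approxfun(e, r, rule = 2),
              e_of_r = approxfun(r, e, rule = 2))
  .radmibg_cache$range_table <- tab
  tab
}

#' CSDA range of electrons in water
#'
#' Path length in unit-density water over which an electron slows from the
#' given energy down to the 10 keV transport cutoff.
#'
#' @param energy_kev electron kinetic energy in keV; vectorised.
#' @return Range in cm (0 at and below the cutoff).
#' @export
csda_range <- function(energy_kev) {
  tab <- .range_table()
  out <- tab$r_of_e(pmax(energy_kev, .E_CUT_KEV))
  out[energy_kev <= .E_CUT_KEV] <- 0
  out
}

# energy whose residual range (to cutoff) is r; >= cutoff
.energy_at_range <- function(r_cm) {
  tab <- .range_table()
  pmax(tab$e_of_r(pmax(r_cm, 0)), .E_CUT_KEV)
}

# --- photon cross sections ------------------------------------------------

.photon_table <- function() {
  if (!is.null(.radmibg_cache$photon_table)) return(.radmibg_cache$photon_table)
  tab <- read.delim(.extdata("water_photon_xs.tsv"), comment.char = "#")
  pt <- list(
    pe = approxfun(log(tab$energy_kev), log(tab$photoelectric_cm2_g), rule = 2),
    muen = approxfun(log(tab$energy_kev), log(tab$mu_en_cm2_g), rule = 2)
  )
  .radmibg_cache$photon_table <- pt
  pt
}

# total Klein-Nishina cross section per electron (cm^2), k = E/mc^2
.kn_sigma <- function(k) {
  two_pi_re2 <- 4.98938e-25
  t1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  t2 <- log(1 + 2 * k) / (2 * k)
  t3 <- (1 + 3 * k) / (1 + 2 * k)^2
  two_pi_re2 * (t1 + t2 - t3)
}

#' Photon interaction coefficients of water
#'
#' Linear attenuation coefficients at unit density: analytic Klein-Nishina
#' incoherent scattering plus tabulated photoelectric absorption (Rayleigh
#' scattering ignored), and the tabulated mass energy-absorption
#' coefficient.
#'
#' @param energy_kev photon energy in keV; vectorised.
#' @return A list of vectors `total`, `photoelectric`, `incoherent`,
#'   `mu_en`, all in 1/cm at unit density.
#' @export
photon_mu <- function(energy_kev) {
  pt <- .photon_table()
  n_el_per_g <- 6.02214076e23 * .ZA_WATER
  inc <- n_el_per_g * .kn_sigma(energy_kev / .ELECTRON_REST_KEV)
  pe <- exp(pt$pe(log(energy_kev)))
  list(total = inc + pe, photoelectric = pe, incoherent = inc,
       mu_en = exp(pt$muen(log(energy_kev))))
}
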