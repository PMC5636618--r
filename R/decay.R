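#' Radionuclide decay scheme
#'
#' A decay scheme holds the physical half-life together with the emission
#' inventory used as the Monte Carlo source term: beta branches (endpoint
#' energy, intensity per decay, daughter atomic number for the Fermi
#' function) and discrete photon and electron lines (energy, expected yield
#' per decay).
#'
#' @param half_life_h physical half-life in hours.
#' @param beta data frame with columns `endpoint_kev`, `intensity`,
#'   `z_daughter`.
#' @param discrete data frame with columns `kind` (`"photon"` or
#'   `"electron"`), `energy_kev`, `yield`.
#' @return An object of class `decay_scheme`.
#' @seealso [load_i131_scheme()]
#' @export
decay_scheme <- function(half_life_h, beta, discrete) {
  stopifnot(is.numeric(half_life_h), length(half_life_h) == 1L,
            half_life_h > 0)
  beta <- as.data.frame(beta)
  discrete <- as.data.frame(discrete)
  stopifnot(all(c("endpoint_kev", "intensity", "z_daughter") %in% names(beta)),
            all(c("kind", "energy_kev", "yield") %in% names(discrete)))
  if (nrow(beta) < 1L) stop("at least one beta branch is required")
  if (any(beta$endpoint_kev <= 0)) stop("beta endpoint energies must be > 0")
  if (any(beta$intensity <= 0 | beta$intensity > 1))
    stop("beta intensities must lie in (0, 1]")
  if (sum(beta$intensity) > 1 + 1e-2)
    stop("beta intensities sum to more than 1")
  if (any(discrete$energy_kev <= 0)) stop("line energies must be > 0")
  if (any(discrete$yield < 0)) stop("line yields must be >= 0")
  if (!all(discrete$kind %in% c("photon", "electron")))
    stop("discrete emission kind must be 'photon' or 'electron'")
  structure(list(half_life_h = half_life_h, beta = beta, discrete = discrete),
            class = "decay_scheme")
}

#' Load a decay scheme from a structured text file
#'
#' The file format is tab-separated with comment lines starting with `#` and
#' columns `record` (`half_life`, `beta`, `photon`, `electron`),
#' `energy_kev` and `value` (hours for `half_life`, intensity for `beta`,
#' yield for lines).  Only iodine-131 data ship with the package, but any
#' radionuclide can be supplied in the same format.
#'
#' @param path path to a decay data file.
#' @param z_daughter atomic number of the beta-decay daughter, used in the
#'   Fermi spectrum shape (54 for the shipped iodine-131 data).
#' @return A [decay_scheme()].
#' @export
load_decay_scheme <- function(path, z_daughter = 54L) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  hl <- tab$value[tab$record == "half_life"]
  if (length(hl) != 1L) stop("decay file must contain exactly one half_life record")
  b <- tab[tab$record == "beta", , drop = FALSE]
  d <- tab[tab$record %in% c("photon", "electron"), , drop = FALSE]
  decay_scheme(
    half_life_h = hl,
    beta = data.frame(endpoint_kev = b$energy_kev, intensity = b$value,
                      z_daughter = z_daughter),
    discrete = data.frame(kind = d$record, energy_kev = d$energy_kev,
                          yield = d$value)
  )
}

#' Load the shipped iodine-131 decay scheme
#'
#' Compiled inventory (half-life 8.0252 d; five beta branches; gamma and
#' X-ray lines with yield at least 0.5 %; K-conversion electrons of the
#' 364.5 and 80.2 keV transitions; Auger and sub-10 keV conversion electrons
#' lumped into a single locally deposited 3.4 keV line).
#'
#' @return A [decay_scheme()] for iodine-131.
#' @export
#' @examples
#' sc <- load_i131_scheme()
#' sc$half_life_h            # 192.6 h
#' decay_constant(sc)        # per hour
load_i131_scheme <- function() {
  load_decay_scheme(.extdata("i131_decay.tsv"), z_daughter = 54L)
}

#' Decay constant of a scheme
#'
#' @param scheme a [decay_scheme()].
#' @return lambda = ln(2) / half-life, in 1/hour.
#' @export
decay_constant <- function(scheme) log(2) / scheme$half_life_h

#' @export
print.decay_scheme <- function(x, ...) {
  cat(sprintf("<decay_scheme> T1/2 = %.4f h (%.4f d)\n",
              x$half_life_h, x$half_life_h / 24))
  cat(sprintf("  %d beta branches (sum intensity %.4f), %d discrete lines\n",
              nrow(x$beta), sum(x$beta$intensity), nrow(x$discrete)))
  me <- scheme_mean_energy(x)
  cat(sprintf("  mean energy per decay [keV]: beta %.1f, discrete e- %.1f, photon %.1f\n",
              me["beta"], me["electron"], me["photon"]))
  invisible(x)
}

# --- allowed-shape Fermi beta spectrum ------------------------------------

# unnormalised allowed spectrum shape at kinetic energy E (keV):
# p * W * (Q - E)^2 * F(Z, E), with the nonrelativistic Fermi function
# F = 2 pi eta / (1 - exp(-2 pi eta)), eta = + Z alpha / beta (beta-minus).
.beta_shape <- function(energy_kev, endpoint_kev, z_daughter) {
  w <- 1 + energy_kev / .ELECTRON_REST_KEV        # total energy, mc^2 units
  p <- sqrt(pmax(w^2 - 1, 0))                     # momentum, mc units
  beta_v <- p / w
  eta <- z_daughter / 137.035999 / pmax(beta_v, 1e-12)
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  out <- p * w * (endpoint_kev - energy_kev)^2 * fermi
  out[energy_kev <= 0 | energy_kev >= endpoint_kev] <- 0
  out
}

# 1 keV evaluation grid and normalisation constant for one branch
.beta_grid <- function(endpoint_kev, z_daughter) {
  e <- seq(0.5, endpoint_kev - 0.5, by = 1)
  if (length(e) < 2L) e <- seq(endpoint_kev / 20, endpoint_kev, length.out = 20)
  f <- .beta_shape(e, endpoint_kev, z_daughter)
  norm <- sum(f) * diff(e[1:2])
  list(e = e, f = f, norm = norm)
}

#' Allowed-shape beta spectrum density
#'
#' Probability density (per keV) of the beta-particle kinetic energy for a
#' single branch, using the allowed shape with a nonrelativistic Fermi
#' function approximation, normalised numerically on a 1 keV grid.
#'
#' @param branch one row of `scheme$beta` (or any list with
#'   `endpoint_kev`, `intensity`, `z_daughter`).
#' @param energy_kev kinetic energies at which to evaluate, in
#'   `(0, endpoint)`; vectorised.
#' @return density values, per keV, integrating to 1 over the branch.
#' @export
#' @examples
#' sc <- load_i131_scheme()
#' main <- sc$beta[which.max(sc$beta$intensity), ]
#' beta_spectrum_density(main, c(100, 300, 500))
beta_spectrum_density <- function(branch, energy_kev) {
  ep <- branch$endpoint_kev
  if (any(energy_kev <= 0 | energy_kev >= ep))
    stop("energy must lie strictly inside (0, endpoint)")
  g <- .beta_grid(ep, branch$z_daughter)
  .beta_shape(energy_kev, ep, branch$z_daughter) / g$norm
}

#' Mean emitted energy per decay, by component
#'
#' Beta means are obtained by numerical integration of the branch spectra;
#' discrete components are yield-weighted sums.
#'
#' @param scheme a [decay_scheme()].
#' @return Named numeric vector with components `beta`, `electron`,
#'   `photon` and `total`, in keV per decay.
#' @export
scheme_mean_energy <- function(scheme) {
  bmean <- vapply(seq_len(nrow(scheme$beta)), function(i) {
    b <- scheme$beta[i, ]
    g <- .beta_grid(b$endpoint_kev, b$z_daughter)
    sum(g$e * g$f) / sum(g$f)
  }, numeric(1))
  beta <- sum(bmean * scheme$beta$intensity)
  d <- scheme$discrete
  el <- sum(d$energy_kev[d$kind == "electron"] * d$yield[d$kind == "electron"])
  ph <- sum(d$energy_kev[d$kind == "photon"] * d$yield[d$kind == "photon"])
  c(beta = beta, electron = el, photon = ph, total = beta + el + ph)
}

# per-branch inverse CDF samplers on the 1 keV grid, cached per scheme
.beta_samplers <- function(scheme) {
  key <- paste0("beta_samplers_", digest_scheme(scheme))
  if (!is.null(.radmibg_cache[[key]])) return(.radmibg_cache[[key]])
  samplers <- lapply(seq_len(nrow(scheme$beta)), function(i) {
    b <- scheme$beta[i, ]
    g <- .beta_grid(b$endpoint_kev, b$z_daughter)
    cdf <- cumsum(g$f)
    cdf <- cdf / cdf[length(cdf)]
    # strictly increasing knots for inverse interpolation
    keep <- c(TRUE, diff(cdf) > 0)
    approxfun(c(0, cdf[keep]), c(0, g$e[keep]), rule = 2)
  })
  .radmibg_cache[[key]] <- samplers
  samplers
}

#' Stable digest of a decay scheme
#'
#' Short text key identifying the emission inventory; used for caching and
#' recorded in reports so that any result can be traced to the decay data
#' that produced it.
#'
#' @param scheme a [decay_scheme()].
#' @return A character scalar.
#' @export
digest_scheme <- function(scheme) {
  txt <- paste(c(format(scheme$half_life_h, digits = 10),
                 format(unlist(scheme$beta), digits = 10),
                 format(unlist(scheme$discrete), digits = 10)),
               collapse = "|")
  # small FNV-style rolling hash; stable across sessions
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x-%d", h, nchar(txt))
}

#' Sample the emissions of radioactive decays
#'
#' For each decay one beta electron is drawn from the branch-weighted
#' allowed spectrum (inverse CDF on a 1 keV grid) and each discrete line is
#' emitted as a Bernoulli trial with probability equal to its yield (all
#' shipped iodine-131 yields are below 1).  Sampling uses R's global random
#' number generator, so results are a pure function of the seed.
#'
#' @param scheme a [decay_scheme()].
#' @param n number of decays.
#' @return A data frame with columns `history`, `kind`
#'   (`"beta"`, `"electron"`, `"photon"`) and `energy_kev`, one row per
#'   emitted particle.
#' @export
#' @examples
#' set.seed(1)
#' head(sample_decays(load_i131_scheme(), 5))
sample_decays <- function(scheme, n) {
  stopifnot(n >= 1)
  samplers <- .beta_samplers(scheme)
  branch <- sample.int(nrow(scheme$beta), n, replace = TRUE,
                       prob = scheme$beta$intensity)
  eb <- numeric(n)
  for (i in seq_along(samplers)) {
    idx <- which(branch == i)
    if (length(idx)) eb[idx] <- samplers[[i]](runif(length(idx)))
  }
  out <- list(data.frame(history = seq_len(n), kind = "beta", energy_kev = eb))
  d <- scheme$discrete
  for (i in seq_len(nrow(d))) {
    emitted <- which(runif(n) < d$yield[i])
    if (length(emitted))
      out[[length(out) + 1L]] <- data.frame(history = emitted,
                                            kind = d$kind[i],
                                            energy_kev = d$energy_kev[i])
  }
  res <- do.call(rbind, out)
  res[order(res$history), , drop = FALSE]
}

#' @rdname sample_decays
#' @export
sample_decay <- function(scheme) sample_decays(scheme, 1L)
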