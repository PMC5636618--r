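#' Unit-density water sphere
#'
#' Geometry for self-dose sphere dosimetry: a homogeneous sphere of water
#' containing the activity uniformly (source region = target region).
#'
#' @param mass_g sphere mass in grams.
#' @param density_g_cm3 mass density, g/cm^3 (default 1, water).
#' @return An object of class `sphere` with fields `mass_g`,
#'   `density_g_cm3` and derived `radius_cm`.
#' @export
#' @examples
#' sphere(0.5)$radius_cm  # ~0.492 cm
sphere <- function(mass_g, density_g_cm3 = 1) {
  stopifnot(mass_g > 0, density_g_cm3 > 0)
  structure(list(mass_g = mass_g, density_g_cm3 = density_g_cm3,
                 radius_cm = (3 * mass_g / (4 * pi * density_g_cm3))^(1 / 3)),
            class = "sphere")
}

#' @export
print.sphere <- function(x, ...) {
  cat(sprintf("<sphere> mass %.4g g, density %.3g g/cm3, radius %.4g cm\n",
              x$mass_g, x$density_g_cm3, x$radius_cm))
  invisible(x)
}

# distance along unit direction u from point p (n x 3) to the sphere surface
.dist_to_boundary <- function(p, u, radius) {
  pu <- rowSums(p * u)
  d2 <- rowSums(p * p)
  disc <- pmax(pu^2 + radius^2 - d2, 0)
  -pu + sqrt(disc)
}

# n isotropic unit vectors
.iso_dirs <- function(n) {
  mu <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - mu^2)
  cbind(s * cos(phi), s * sin(phi), mu)
}

# n points uniform in a sphere of given radius
.uniform_points <- function(n, radius) {
  r <- radius * runif(n)^(1 / 3)
  .iso_dirs(n) * r
}

#' Transport electrons through a sphere
#'
#' Continuous slowing-down approximation along a straight track: the
#' electron deposits energy according to the collision stopping power of
#' water until it either slows below the 10 keV cutoff (the residue is
#' deposited locally) or crosses the sphere surface (the residual energy is
#' scored as escaped).  All arguments are vectorised; the computation is a
#' closed form in the CSDA range tables, so it is deterministic.
#'
#' @param energy_kev electron kinetic energies, keV.
#' @param origin numeric matrix `n x 3` of starting points (cm, sphere
#'   centred at the origin), or a length-3 vector recycled to all electrons.
#' @param direction unit direction vectors, same shape rules as `origin`.
#' @param sph a [sphere()].
#' @return A list with vectors `deposited_kev` and `escaped_kev`
#'   (`deposited + escaped == energy` exactly).
#' @export
#' @examples
#' sph <- sphere(0.5)
#' transport_electron(10, c(0, 0, 0), c(0, 0, 1), sph)$deposited_kev  # all 10 keV
transport_electron <- function(energy_kev, origin, direction, sph) {
  n <- length(energy_kev)
  p <- matrix(as.numeric(origin), ncol = 3,
              nrow = n, byrow = is.null(dim(origin)))
  u <- matrix(as.numeric(direction), ncol = 3,
              nrow = n, byrow = is.null(dim(direction)))
  if (any(energy_kev < 0)) stop("electron energy must be >= 0")
  if (any(rowSums(p * p) > sph$radius_cm^2 * (1 + 1e-9)))
    stop("electron origin lies outside the sphere")
  s_b <- .dist_to_boundary(p, u, sph$radius_cm)
  rng <- csda_range(energy_kev)
  dep <- energy_kev
  out <- which(rng > s_b)
  if (length(out)) {
    e_exit <- .energy_at_range(rng[out] - s_b[out])
    dep[out] <- energy_kev[out] - e_exit
  }
  # zero-length in-sphere path: nothing deposited
  dep[energy_kev <= 0] <- 0
  list(deposited_kev = dep, escaped_kev = energy_kev - dep)
}

# Klein-Nishina sampling of the scattered-photon energy fraction eps = E'/E.
# Standard two-branch mixture (1/eps and eps densities) with rejection.
.sample_kn_eps <- function(k) {
  n <- length(k)
  eps <- numeric(n)
  todo <- seq_len(n)
  emin <- 1 / (1 + 2 * k)
  a1 <- log(1 + 2 * k)
  a2 <- (1 - emin^2) / 2
  it <- 0L
  while (length(todo)) {
    it <- it + 1L
    if (it > 1000L) stop("Klein-Nishina sampling failed to converge")
    m <- length(todo)
    km <- k[todo]
    use1 <- runif(m) < a1[todo] / (a1[todo] + a2[todo])
    e <- numeric(m)
    e[use1] <- emin[todo][use1]^runif(sum(use1))
    e[!use1] <- sqrt(emin[todo][!use1]^2 +
                       runif(sum(!use1)) * (1 - emin[todo][!use1]^2))
    t <- (1 - e) / (km * e)
    sin2 <- t * (2 - t)
    acc <- runif(m) < 1 - e * sin2 / (1 + e^2)
    eps[todo[acc]] <- e[acc]
    todo <- todo[!acc]
  }
  eps
}

# rotate unit vectors u by polar angle with cosine c and uniform azimuth
.rotate_dirs <- function(u, cos_t) {
  n <- nrow(u)
  sin_t <- sqrt(pmax(1 - cos_t^2, 0))
  phi <- runif(n, 0, 2 * pi)
  # orthonormal frame (a, b, u); pick helper axis least aligned with u
  hx <- abs(u[, 1]) < 0.9
  h <- cbind(ifelse(hx, 1, 0), ifelse(hx, 0, 1), 0)
  a <- cbind(h[, 2] * u[, 3] - h[, 3] * u[, 2],
             h[, 3] * u[, 1] - h[, 1] * u[, 3],
             h[, 1] * u[, 2] - h[, 2] * u[, 1])
  a <- a / sqrt(rowSums(a * a))
  b <- cbind(u[, 2] * a[, 3] - u[, 3] * a[, 2],
             u[, 3] * a[, 1] - u[, 1] * a[, 3],
             u[, 1] * a[, 2] - u[, 2] * a[, 1])
  u * cos_t + (a * cos(phi) + b * sin(phi)) * sin_t
}

#' Transport photons through a sphere
#'
#' Analog event-by-event transport: free paths sampled from the total
#' attenuation coefficient; interactions are photoelectric absorption (the
#' photoelectron is handed to [transport_electron()]) or incoherent Compton
#' scattering (Klein-Nishina energy sampling; the recoil electron is
#' transported, the scattered photon is tracked further).  Photons below
#' 1 keV are deposited locally.  Energy deposited by all secondaries is
#' attributed to the initiating photon.
#'
#' @inheritParams transport_electron
#' @param energy_kev photon energies, keV.
#' @return A list with vectors `deposited_kev` and `escaped_kev` per input
#'   photon (`deposited + escaped == energy` exactly).
#' @export
transport_photon <- function(energy_kev, origin, direction, sph) {
  n <- length(energy_kev)
  p <- matrix(as.numeric(origin), ncol = 3,
              nrow = n, byrow = is.null(dim(origin)))
  u <- matrix(as.numeric(direction), ncol = 3,
              nrow = n, byrow = is.null(dim(direction)))
  if (any(rowSums(p * p) > sph$radius_cm^2 * (1 + 1e-9)))
    stop("photon origin lies outside the sphere")
  dep <- numeric(n)
  esc <- numeric(n)
  idx <- seq_len(n)          # map from active rows to original photons
  e <- energy_kev
  it <- 0L
  while (length(idx)) {
    it <- it + 1L
    if (it > 500L) {         # never reached in practice; conserve energy
      dep[idx] <- dep[idx] + e
      break
    }
    mu <- photon_mu(e)
    path <- rexp(length(idx)) / mu$total
    s_b <- .dist_to_boundary(p, u, sph$radius_cm)
    out <- path >= s_b
    esc[idx[out]] <- esc[idx[out]] + e[out]
    keep <- which(!out)
    if (!length(keep)) break
    idx <- idx[keep]
    e <- e[keep]
    p <- p[keep, , drop = FALSE] + path[keep] * u[keep, , drop = FALSE]
    u <- u[keep, , drop = FALSE]
    pe <- runif(length(idx)) < mu$photoelectric[keep] / mu$total[keep]
    # photoelectric: full transfer to a photoelectron along the photon path
    if (any(pe)) {
      te <- transport_electron(e[pe], p[pe, , drop = FALSE],
                               u[pe, , drop = FALSE], sph)
      dep[idx[pe]] <- dep[idx[pe]] + te$deposited_kev
      esc[idx[pe]] <- esc[idx[pe]] + te$escaped_kev
    }
    co <- which(!pe)
    if (!length(co)) { idx <- integer(0); break }
    idx <- idx[co]
    e <- e[co]
    p <- p[co, , drop = FALSE]
    u <- u[co, , drop = FALSE]
    k <- e / .ELECTRON_REST_KEV
    eps <- .sample_kn_eps(k)
    e_recoil <- e * (1 - eps)
    te <- transport_electron(e_recoil, p, u, sph)   # recoil ~ forward
    dep[idx] <- dep[idx] + te$deposited_kev
    esc[idx] <- esc[idx] + te$escaped_kev
    cos_t <- 1 - (1 - eps) / (k * eps)
    u <- .rotate_dirs(u, pmin(pmax(cos_t, -1), 1))
    e <- e * eps
    # low-energy photon cutoff: deposit locally
    cut <- e < .PHOTON_CUT_KEV
    if (any(cut)) {
      dep[idx[cut]] <- dep[idx[cut]] + e[cut]
      keep <- which(!cut)
      idx <- idx[keep]; e <- e[keep]
      p <- p[keep, , drop = FALSE]; u <- u[keep, , drop = FALSE]
    }
  }
  list(deposited_kev = dep, escaped_kev = esc)
}

# accumulate values into a length-n vector by (possibly duplicated) index
.acc <- function(vec, idx, val) {
  if (!length(idx)) return(vec)
  s <- rowsum(val, idx)
  at <- as.integer(rownames(s))
  vec[at] <- vec[at] + s[, 1]
  vec
}

#' Simulate the self-irradiation of a sphere
#'
#' Event-by-event Monte Carlo: decay sites sampled uniformly in the sphere
#' volume, isotropic emission directions, every emission of every decay
#' transported ([transport_electron()] for betas and discrete electrons,
#' [transport_photon()] for photons).  Per-component absorbed fractions and
#' their Monte Carlo standard errors are estimated from the per-history
#' deposits (ratio estimator, since the emitted energy varies per history).
#'
#' @param scheme a [decay_scheme()].
#' @param sph a [sphere()].
#' @param n_histories number of decays to simulate (>= 1).
#' @param seed integer seed; the simulation is a pure function of it.
#' @return An object of class `transport_result`: counts, per-component
#'   emitted/deposited/escaped energy totals, absorbed fractions with Monte
#'   Carlo standard errors, and the per-history energy ledgers (used by the
#'   energy-conservation checks).
#' @export
#' @examples
#' \donttest{
#' res <- simulate_sphere(load_i131_scheme(), sphere(0.5), 2e4, seed = 1)
#' res$absorbed_fraction
#' }
simulate_sphere <- function(scheme, sph, n_histories, seed = 1L) {
  if (n_histories < 1) stop("n_histories must be >= 1")
  n <- as.integer(n_histories)
  set.seed(seed)
  pos <- .uniform_points(n, sph$radius_cm)
  em <- sample_decays(scheme, n)

  comp <- c("beta", "electron", "photon")
  emit <- dep <- esc <- matrix(0, n, 3, dimnames = list(NULL, comp))

  for (ci in seq_along(comp)) {
    rows <- em[em$kind == comp[ci], , drop = FALSE]
    if (!nrow(rows)) next
    h <- rows$history
    e <- rows$energy_kev
    org <- pos[h, , drop = FALSE]
    dirs <- .iso_dirs(nrow(rows))
    tr <- if (comp[ci] == "photon") {
      transport_photon(e, org, dirs, sph)
    } else {
      transport_electron(e, org, dirs, sph)
    }
    emit[, ci] <- .acc(emit[, ci], h, e)
    dep[, ci] <- .acc(dep[, ci], h, tr$deposited_kev)
    esc[, ci] <- .acc(esc[, ci], h, tr$escaped_kev)
  }

  af <- colSums(dep) / pmax(colSums(emit), .Machine$double.xmin)
  # ratio-estimator standard error of sum(dep)/sum(emit)
  se <- vapply(seq_along(comp), function(ci) {
    if (colSums(emit)[ci] == 0) return(0)
    resid <- dep[, ci] - af[ci] * emit[, ci]
    sqrt(var(resid) / n) / mean(emit[, ci])
  }, numeric(1))
  tot_emit <- rowSums(emit)
  tot_dep <- rowSums(dep)
  af_tot <- sum(tot_dep) / sum(tot_emit)
  se_tot <- sqrt(var(tot_dep - af_tot * tot_emit) / n) / mean(tot_emit)

  structure(list(
    n_histories = n,
    seed = seed,
    scheme_digest = digest_scheme(scheme),
    sphere = sph,
    energy_emitted_kev = sum(tot_emit),
    energy_deposited_kev = sum(tot_dep),
    emitted_by_component = colSums(emit),
    deposited_by_component = colSums(dep),
    absorbed_fraction = c(setNames(af, comp), total = af_tot),
    mc_standard_error = c(setNames(se, comp), total = se_tot),
    per_history = list(emitted = emit, deposited = dep, escaped = esc)
  ), class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("<transport_result> %d histories, sphere %.4g g (seed %d)\n",
              x$n_histories, x$sphere$mass_g, x$seed))
  af <- x$absorbed_fraction
  se <- x$mc_standard_error
  for (k in names(af))
    cat(sprintf("  phi_%-8s = %.4f +/- %.4f\n", k, af[k], se[k]))
  invisible(x)
}

#' S-value of a simulated sphere
#'
#' Mean energy deposited per decay divided by the sphere mass, converted to
#' Gy per Bq s; the uncertainty is propagated from the Monte Carlo standard
#' error of the per-history deposit.
#'
#' @param result a `transport_result` from [simulate_sphere()].
#' @param sph the [sphere()] the result was computed for (defaults to the
#'   one recorded in the result).
#' @return An object of class `s_value` with fields `value` and
#'   `uncertainty` (Gy per Bq s) and the sphere.
#' @export
s_value <- function(result, sph = result$sphere) {
  if (result$n_histories < 1) stop("result contains no histories")
  if (!isTRUE(all.equal(sph$mass_g, result$sphere$mass_g)))
    stop("sphere does not match the one the result was computed for")
  dep_hist <- rowSums(result$per_history$deposited)
  mean_dep <- mean(dep_hist)
  conv <- .J_PER_KEV / (sph$mass_g / 1000)
  structure(list(
    value = mean_dep * conv,
    uncertainty = sd(dep_hist) / sqrt(result$n_histories) * conv,
    sphere = sph,
    n_histories = result$n_histories,
    seed = result$seed
  ), class = "s_value")
}

#' @export
print.s_value <- function(x, ...) {
  cat(sprintf("<s_value> %.4e +/- %.1e Gy/(Bq s), sphere %.4g g\n",
              x$value, x$uncertainty, x$sphere$mass_g))
  invisible(x)
}

#' Monte Carlo S-values for a set of sphere masses
#'
#' @param masses_g sphere masses in grams.
#' @param scheme a [decay_scheme()].
#' @param n_histories histories per sphere.
#' @param seed base seed; sphere `i` uses `seed + i - 1`.
#' @return A list of `s_value` objects, one per mass.
#' @export
sweep_s_values <- function(masses_g, scheme, n_histories = 1e5, seed = 1L) {
  lapply(seq_along(masses_g), function(i) {
    sph <- sphere(masses_g[i])
    s_value(simulate_sphere(scheme, sph, n_histories, seed = seed + i - 1L))
  })
}

# --- deterministic reference route ---------------------------------------

# mean over uniform source position and isotropic direction of f(s) where s
# is the distance to the sphere surface; midpoint product quadrature
.sphere_chord_mean <- function(radius, f, n_u = 160, n_mu = 160) {
  uu <- (seq_len(n_u) - 0.5) / n_u       # d/R with density 3u^2
  mu <- -1 + (2 * (seq_len(n_mu) - 0.5)) / n_mu
  g <- expand.grid(u = uu, mu = mu)
  s <- radius * (-g$u * g$mu + sqrt(g$u^2 * g$mu^2 + 1 - g$u^2))
  w <- 3 * g$u^2
  sum(w * f(s)) / sum(w)
}

#' Deterministic electron absorbed fraction
#'
#' Quadrature companion to the Monte Carlo: averages the CSDA closed-form
#' energy deposit over uniform source positions and isotropic directions.
#' Shares the physics model (stopping powers, straight tracks, 10 keV
#' cutoff) with [transport_electron()] but none of its sampling, so it
#' serves as an independent check of the Monte Carlo machinery.
#'
#' @param energy_kev electron energy, keV (scalar).
#' @param sph a [sphere()].
#' @return Absorbed fraction in `[0, 1]`.
#' @export
electron_absorbed_fraction <- function(energy_kev, sph) {
  if (energy_kev <= .E_CUT_KEV) return(1)
  rng <- csda_range(energy_kev)
  .sphere_chord_mean(sph$radius_cm, function(s) {
    dep <- rep(energy_kev, length(s))
    out <- rng > s
    if (any(out)) dep[out] <- energy_kev - .energy_at_range(rng - s[out])
    dep / energy_kev
  })
}

#' First-flight photon absorbed fraction
#'
#' Analytic estimate using the mass energy-absorption coefficient: each
#' photon deposits `1 - exp(-mu_en * s)` of its energy along its in-sphere
#' path, averaged over uniform source positions and isotropic directions.
#' Accurate for spheres much smaller than the photon mean free path, where
#' scattered photons overwhelmingly escape.
#'
#' @inheritParams electron_absorbed_fraction
#' @param energy_kev photon energy, keV (scalar).
#' @return Absorbed fraction in `[0, 1]`.
#' @export
photon_absorbed_fraction_ff <- function(energy_kev, sph) {
  muen <- photon_mu(energy_kev)$mu_en
  .sphere_chord_mean(sph$radius_cm, function(s) 1 - exp(-muen * s))
}

#' Deterministic S-value
#'
#' Quadrature route to the sphere S-value: beta spectra integrated over
#' [electron_absorbed_fraction()], discrete electron lines likewise, photon
#' lines through [photon_absorbed_fraction_ff()].  Used to generate the
#' shipped synthetic reference table and as an independent oracle for the
#' Monte Carlo.
#'
#' @param scheme a [decay_scheme()].
#' @param sph a [sphere()].
#' @return S-value in Gy per Bq s.
#' @export
deterministic_s_value <- function(scheme, sph) {
  dep <- 0
  for (i in seq_len(nrow(scheme$beta))) {
    b <- scheme$beta[i, ]
    g <- .beta_grid(b$endpoint_kev, b$z_daughter)
    w <- g$f / sum(g$f)
    # absorbed fraction on a coarse energy grid, interpolated over spectrum
    egrid <- exp(seq(log(max(min(g$e), 1)), log(b$endpoint_kev),
                     length.out = 40))
    af <- vapply(egrid, electron_absorbed_fraction, numeric(1), sph = sph)
    af_s <- approx(egrid, af, xout = pmax(g$e, egrid[1]), rule = 2)$y
    dep <- dep + b$intensity * sum(w * g$e * af_s)
  }
  d <- scheme$discrete
  for (i in seq_len(nrow(d))) {
    af <- if (d$kind[i] == "electron") {
      electron_absorbed_fraction(d$energy_kev[i], sph)
    } else {
      photon_absorbed_fraction_ff(d$energy_kev[i], sph)
    }
    dep <- dep + d$yield[i] * d$energy_kev[i] * af
  }
  dep * .J_PER_KEV / (sph$mass_g / 1000)
}

#' Load the shipped sphere S-value reference table
#'
#' Synthetic reference (see the table header): S-values for unit-density
#' spheres computed by the deterministic quadrature route of
#' [deterministic_s_value()], frozen at package build time.  Columns
#' `mass_g`, `s_gy_per_bq_s`, `provenance`.
#'
#' @param path file to read; defaults to the shipped synthetic table.
#' @return A data frame.
#' @export
load_sphere_reference <- function(path = .extdata("i131_sphere_svalues_synthetic.csv")) {
  read.csv(path, comment.char = "#")
}

#' Compare Monte Carlo S-values with a reference table
#'
#' @param svalues list of `s_value` objects (see [sweep_s_values()]).
#' @param reference data frame with columns `mass_g` and `s_gy_per_bq_s`;
#'   every sphere mass in `svalues` must be present.
#' @return Maximum over spheres of `|S_mc - S_ref| / S_ref`.
#' @export
compare_to_reference <- function(svalues, reference) {
  devs <- vapply(svalues, function(s) {
    i <- which(abs(reference$mass_g - s$sphere$mass_g) <
                 1e-9 * pmax(reference$mass_g, 1))
    if (!length(i)) stop("no reference entry for mass ", s$sphere$mass_g, " g")
    abs(s$value - reference$s_gy_per_bq_s[i[1]]) / reference$s_gy_per_bq_s[i[1]]
  }, numeric(1))
  max(devs)
}
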