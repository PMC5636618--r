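test_that("sphere geometry follows from mass and density", {
  sph <- sphere(0.5)
  expect_equal(4 / 3 * pi * sph$radius_cm^3, 0.5, tolerance = 1e-12)
  expect_error(sphere(0), "mass")
})

test_that("electron transport obeys the CSDA limits", {
  sph <- sphere(0.5)
  # range << radius: everything is deposited
  tr <- transport_electron(10, c(0, 0, 0), c(0, 0, 1), sph)
  expect_equal(tr$deposited_kev, 10)
  expect_equal(tr$escaped_kev, 0)
  # zero energy deposits nothing
  expect_equal(transport_electron(0, c(0, 0, 0), c(0, 0, 1),
                                  sph)$deposited_kev, 0)
  # boundary start, outward direction: infinitesimal path, nothing deposited
  r <- sph$radius_cm
  tr <- transport_electron(600, c(0, 0, r), c(0, 0, 1), sph)
  expect_lt(tr$deposited_kev, 1e-6)
  expect_equal(tr$deposited_kev + tr$escaped_kev, 600)
  # origin outside the sphere is a domain error
  expect_error(transport_electron(100, c(0, 0, 2 * r), c(0, 0, 1), sph),
               "outside")
  # partial escape conserves energy exactly
  set.seed(5)
  n <- 1000
  e <- runif(n, 20, 600)
  org <- matrix(runif(3 * n, -r / 2, r / 2), ncol = 3)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  tr <- transport_electron(e, org, dir, sph)
  expect_true(all(tr$deposited_kev >= 0 & tr$deposited_kev <= e))
  expect_equal(tr$deposited_kev + tr$escaped_kev, e, tolerance = 1e-12)
})

test_that("photon transport matches the first-flight analytic estimate", {
  sph <- sphere(0.5)   # ~0.5 cm3 at unit density
  n <- 2e4
  set.seed(21)
  mu <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  dirs <- cbind(sqrt(1 - mu^2) * cos(phi), sqrt(1 - mu^2) * sin(phi), mu)
  tr <- transport_photon(rep(364.489, n), c(0, 0, 0), dirs, sph)
  af <- sum(tr$deposited_kev) / (364.489 * n)
  expect_gt(af, 0.01)
  expect_lt(af, 0.06)
  expect_equal(tr$deposited_kev + tr$escaped_kev, rep(364.489, n),
               tolerance = 1e-12)
  # vanishing sphere: absorbed fraction goes to zero
  tiny <- sphere(1e-6)
  tr2 <- transport_photon(rep(364.489, 2000), c(0, 0, 0),
                          dirs[1:2000, ], tiny)
  expect_lt(sum(tr2$deposited_kev) / (364.489 * 2000), 1e-3)
  # determinism under fixed seed
  set.seed(7)
  a <- transport_photon(rep(364.489, 100), c(0, 0, 0), dirs[1:100, ], sph)
  set.seed(7)
  b <- transport_photon(rep(364.489, 100), c(0, 0, 0), dirs[1:100, ], sph)
  expect_identical(a, b)
})

test_that("sphere simulation satisfies the transport-result invariants", {
  sc <- load_i131_scheme()
  res <- simulate_sphere(sc, sphere(0.5), 2e4, seed = 3)
  af <- res$absorbed_fraction
  expect_true(all(af >= 0 & af <= 1))
  expect_lte(res$energy_deposited_kev, res$energy_emitted_kev)
  expect_equal(sum(res$deposited_by_component), res$energy_deposited_kev,
               tolerance = 1e-12)
  # electron component dominated by the betas: absorbed fraction 0.80-0.99
  el <- (res$deposited_by_component[["beta"]] +
           res$deposited_by_component[["electron"]]) /
    (res$emitted_by_component[["beta"]] +
       res$emitted_by_component[["electron"]])
  expect_gt(el, 0.80)
  expect_lt(el, 0.99)
  # per-history conservation, exact to floating tolerance
  ph <- res$per_history
  expect_lt(max(abs(ph$deposited + ph$escaped - ph$emitted)), 1e-9)
  # reproducibility
  res2 <- simulate_sphere(sc, sphere(0.5), 2e4, seed = 3)
  expect_identical(res$absorbed_fraction, res2$absorbed_fraction)
  expect_error(simulate_sphere(sc, sphere(0.5), 0), "histories")
})

test_that("s_value performs the MIRD unit conversion", {
  # synthetic transport result: exactly 100 keV deposited per decay
  sph <- sphere(0.5)
  fake <- structure(list(
    n_histories = 10L, seed = 1L, sphere = sph,
    per_history = list(deposited = matrix(100, 10, 1))
  ), class = "transport_result")
  sv <- s_value(fake, sph)
  expect_equal(sv$value, 100 * 1.602176634e-16 / 5e-4, tolerance = 1e-12)
  expect_equal(sv$uncertainty, 0)
  # zero deposit gives zero S
  fake$per_history$deposited[] <- 0
  expect_equal(s_value(fake, sph)$value, 0)
})

test_that("comparison against a reference table is the max relative deviation", {
  sph1 <- sphere(1); sph2 <- sphere(2)
  mk <- function(v, sph) structure(list(value = v, uncertainty = 0,
                                        sphere = sph), class = "s_value")
  ref <- data.frame(mass_g = c(1, 2), s_gy_per_bq_s = c(3e-11, 1.5e-11))
  expect_equal(compare_to_reference(list(mk(3e-11, sph1),
                                         mk(1.5e-11, sph2)), ref), 0)
  expect_equal(compare_to_reference(list(mk(3e-11, sph1),
                                         mk(1.8e-11, sph2)), ref), 0.2,
               tolerance = 1e-12)
  expect_error(compare_to_reference(list(mk(1e-11, sphere(7))), ref),
               "reference")
})

test_that("deterministic quadrature route reproduces physical limits", {
  sc <- load_i131_scheme()
  # electron absorbed fraction rises with sphere size toward 1
  af <- vapply(c(0.1, 0.5, 2, 10), function(m)
    electron_absorbed_fraction(300, sphere(m)), numeric(1))
  expect_true(all(diff(af) > 0))
  expect_gt(electron_absorbed_fraction(300, sphere(1e6)), 0.999)
  # photon absorbed fraction small for sub-cm spheres, grows with radius
  afp <- vapply(c(0.1, 0.5, 2, 10), function(m)
    photon_absorbed_fraction_ff(364.489, sphere(m)), numeric(1))
  expect_true(all(diff(afp) > 0))
  expect_lt(afp[1], 0.05)
  # S falls with mass beyond the electron-dominated regime
  s <- vapply(c(0.1, 0.5, 1, 5, 10), function(m)
    deterministic_s_value(sc, sphere(m)), numeric(1))
  expect_true(all(diff(s) < 0))
})
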