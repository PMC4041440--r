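test_that("scattering vector construction and limits", {
  expect_equal(scattering_vector(1, 4 * pi, 180 - 1e-9), 1,
               tolerance = 1e-6)
  expect_equal(scattering_vector(1.331, 632.8e-9, 90), 1.869e7,
               tolerance = 1e-3)
  expect_lt(scattering_vector(1.331, 632.8e-9, 1e-9),
            1e-9 * scattering_vector(1.331, 632.8e-9, 90))
  expect_error(scattering_vector(1.331, 632.8e-9, 0))
})

test_that("noiseless correlogram fits round-trip the generator to 0.1%", {
  sp <- synth_spec(seed = 4)
  co <- make_correlogram(sp, noise = 0, B = 1.02, beta = 0.85)
  fit <- fit_correlogram(co$correlogram, n_components = 2)
  expect_equal(fit$B, 1.02, tolerance = 1e-3)
  expect_equal(fit$beta, 0.85, tolerance = 1e-3)
  expect_equal(fit$components$gamma_s[1], co$truth$gammas[1],
               tolerance = 1e-3)
  expect_equal(fit$components$rh_m * 1e9, 2.6, tolerance = 1e-3)
  # R_h consistency: generation and fitting share (T, eta), so the
  # radius is exact regardless of the temperature chosen
  co2 <- make_correlogram(sp, temperature_k = 308, noise = 0)
  fit2 <- fit_correlogram(co2$correlogram, 2)
  # a 2-component fit of monodisperse data may split the amplitude
  # between two nearly equal rates; the weighted radius is what matters
  rh2 <- stats::weighted.mean(fit2$components$rh_m,
                              fit2$components$fraction)
  expect_equal(rh2 * 1e9, 2.6, tolerance = 1e-3)
})

test_that("bidisperse mixtures are resolved within 15% radius and 0.1 fraction", {
  sp <- synth_spec(seed = 6,
                   dls_components = data.frame(rh_nm = c(2.6, 50),
                                               fraction = c(0.6, 0.4)))
  co <- make_correlogram(sp, noise = 0.01)
  fit <- fit_correlogram(co$correlogram, n_components = 2)
  rh <- sort(fit$components$rh_m * 1e9)
  expect_equal(rh[1], 2.6, tolerance = 0.15)
  expect_equal(rh[2], 50, tolerance = 0.15)
  fr <- fit$components$fraction[order(fit$components$rh_m)]
  expect_equal(fr, c(0.6, 0.4), tolerance = 0.1)
  expect_equal(sum(fit$components$fraction), 1, tolerance = 1e-9)
})

test_that("flat correlograms error out and vanishing components collapse", {
  tau <- exp(seq(log(1e-7), log(1), length.out = 50))
  expect_error(fit_correlogram(correlogram(tau, rep(1.5, 50))),
               "flat")
  expect_error(fit_correlogram(correlogram(tau[1:10], rep(1, 10))),
               ">= 20")
  sp <- synth_spec(seed = 4)  # monodisperse truth, 2-component request
  co <- make_correlogram(sp, noise = 0)
  fit <- fit_correlogram(co$correlogram, n_components = 2)
  if (nzchar(fit$note)) expect_equal(nrow(fit$components), 1)
})

test_that("the Siegert model curve decays monotonically for positive amplitudes", {
  tau <- exp(seq(log(1e-7), log(1), length.out = 100))
  g2 <- ensdyn:::g2_model(tau, B = 1, beta = 0.9, amps = c(0.3, 0.7),
                          gammas = c(1e4, 1e2))
  expect_true(all(diff(g2) <= 1e-12))
})

test_that("hydrodynamic radius / mass calibration reproduces the dimer values", {
  expect_equal(mw_from_rh(2.6)$mw_kda_2sf, 32)
  expect_equal(mw_from_rh(2.5)$mw_kda_2sf, 29)
  # self-inverse round trip
  expect_equal(rh_from_mw(mw_from_rh(2.6)$mw_kda), 2.6,
               tolerance = 1e-6)
  expect_equal(mw_from_rh(rh_from_mw(32.5))$mw_kda, 32.5,
               tolerance = 1e-6)
  expect_warning(mw_from_rh(50), "regime")
})

test_that("water viscosity is physically sensible over the working range", {
  expect_equal(water_viscosity(293), 1.00e-3, tolerance = 5e-3)
  expect_true(water_viscosity(343) < water_viscosity(293))
  expect_error(water_viscosity(200))
})

test_that("mean residue ellipticity conversion is pointwise and proportional", {
  z <- mean_residue_ellipticity(222, 0, 14791.9, 127, 2e-4, 0.1)
  expect_equal(z$mre, 0)
  # independent hand evaluation of the conversion at one point
  hand <- (10 / 1000) * 14791.9 / (127 * 2e-4 * 0.1)
  m <- mean_residue_ellipticity(222, 10, 14791.9, 127, 2e-4, 0.1)
  expect_equal(m$mre, hand, tolerance = 1e-12)
  # doubling the concentration halves the signal
  m2 <- mean_residue_ellipticity(222, 10, 14791.9, 127, 4e-4, 0.1)
  expect_equal(m2$mre, hand / 2, tolerance = 1e-12)
  expect_error(mean_residue_ellipticity(222, 10, NA, 127, 2e-4, 0.1))
})

test_that("charge-ladder deconvolution is exact on noiseless ladders", {
  set.seed(19)
  for (k in 1:10) {
    mass <- stats::runif(1, 5e3, 1e5)
    z0 <- sample(5:25, 1)
    charges <- z0:(z0 + sample(2:5, 1))
    lad <- make_charge_ladder(mass, charges)
    d <- deconvolve_charge_ladder(lad$mz)
    expect_equal(d$mass_da, mass, tolerance = 1e-9)
    expect_lt(d$mass_sd, 1e-6 * mass)
    expect_equal(d$charges, charges)
  }
  # the reference dimer-subunit ladder
  d <- deconvolve_charge_ladder(make_charge_ladder(14794, 10:13)$mz)
  expect_equal(d$mass_da, 14794, tolerance = 1e-9)
  # single peak with known charge
  expect_equal(deconvolve_charge_ladder(1001.00728, known_z = 1)$mass_da,
               1000, tolerance = 1e-9)
  # two peaks from different ladders are rejected
  mz_bad <- c(make_charge_ladder(14794, 10:10)$mz,
              make_charge_ladder(23456, 7:7)$mz)
  expect_error(deconvolve_charge_ladder(mz_bad), "inconsistent")
  expect_error(deconvolve_charge_ladder(1200.5), "known_z")
})

test_that("size histograms place fit components in the right log bins", {
  sp <- synth_spec(seed = 6,
                   dls_components = data.frame(rh_nm = c(2.6, 50),
                                               fraction = c(0.6, 0.4)))
  fit <- fit_correlogram(make_correlogram(sp, noise = 0)$correlogram, 2)
  h <- dls_size_histogram(fit)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  occupied <- h[h$fraction > 0, ]
  expect_true(any(occupied$rh_nm_lo <= 2.6 & occupied$rh_nm_hi >= 2.6))
  expect_true(any(occupied$rh_nm_lo <= 50 & occupied$rh_nm_hi >= 50))
})
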