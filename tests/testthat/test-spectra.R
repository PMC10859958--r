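test_that("wavelength/wavenumber conversion matches the printed 0-0 values", {
  expect_equal(round(nm_to_wavenumber(715.6)), 13974)
  expect_equal(round(nm_to_wavenumber(718.4)), 13920)
  expect_equal(nm_to_wavenumber(1e7), 1.0)
  expect_error(nm_to_wavenumber(-3), "positive")
  expect_error(nm_to_wavenumber(0), "positive")
  lam <- c(350.25, 646, 715.6, 800)
  expect_equal(wavenumber_to_nm(nm_to_wavenumber(lam)), lam,
               tolerance = 1e-12)
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(steady_spectrum(c(1, 2), c(1, 2)), "3 grid points")
  expect_error(steady_spectrum(c(3, 2, 1), c(1, 1, 1)), "increasing")
  expect_error(steady_spectrum(c(1, 2, 3), c(1, NA, 1)), "non-finite")
  expect_error(steady_spectrum(c(1, 2, 3), c(1, 1, 1), temperature_K = -5),
               "positive")
})

test_that("spectrum text files round-trip with metadata", {
  s <- steady_spectrum(seq(630, 800, 0.5),
                       runif(length(seq(630, 800, 0.5))),
                       kind = "emission", temperature_K = 77, label = "fix")
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_equal(r$wavelengths_nm, s$wavelengths_nm)
  expect_equal(r$values, s$values)
  expect_identical(r$kind, "emission")
  expect_equal(r$temperature_K, 77)
  expect_identical(r$label, "fix")
})

test_that("Qy-area normalization hits the weighted chlorophyll content", {
  wl <- seq(600, 820, by = 1)
  osc <- c(chl_a = 1.0, chl_b = 0.67, chl_d = 1.20, chl_f = 1.34)
  flat <- steady_spectrum(wl, rep(1, length(wl)))
  out <- normalize_qy_area(flat, c(chl_a = 170), c(chl_a = 1))
  expect_equal(out$values, flat$values, tolerance = 1e-12)

  spec <- steady_spectrum(wl, gauss_band_nm(wl, 680, 30) +
                            gauss_band_nm(wl, 710, 25, 0.4))
  st <- stoichiometry(c(chl_a = 8, chl_b = 4))
  out <- normalize_qy_area(spec, st, osc)
  g <- seq(630, 800, by = 0.05)
  expect_equal(pracma::trapz(g, approx(out$wavelengths_nm, out$values, g)$y),
               8 * 1.0 + 4 * 0.67, tolerance = 1e-6)

  # scale invariance and idempotence
  spec5 <- steady_spectrum(wl, 5 * spec$values)
  expect_equal(normalize_qy_area(spec5, st, osc)$values, out$values,
               tolerance = 1e-12)
  expect_equal(normalize_qy_area(out, st, osc)$values, out$values,
               tolerance = 1e-12)
  expect_error(normalize_qy_area(spec, st, osc, window = c(500, 700)),
               "outside")
})

test_that("difference spectra subtract on the overlap grid", {
  wl <- seq(630, 800, by = 0.5)
  a <- steady_spectrum(wl, gauss_band_nm(wl, 690, 25))
  expect_true(all(difference_spectrum(a, a)$values == 0))
  z <- steady_spectrum(wl, rep(0, length(wl)))
  expect_equal(difference_spectrum(a, z)$values, a$values)
  # two offset Gaussians: signed band equals the analytic difference
  b <- steady_spectrum(wl, gauss_band_nm(wl, 700, 30, 0.8))
  d <- difference_spectrum(a, b)
  expect_equal(d$values,
               gauss_band_nm(wl, 690, 25) - gauss_band_nm(wl, 700, 30, 0.8),
               tolerance = 1e-12)
  far <- steady_spectrum(seq(900, 950, 1), rep(1, 51))
  expect_error(difference_spectrum(a, far), "overlap")
})

test_that("symmetric Gaussian pair crosses at the midpoint", {
  wl <- seq(650, 780, by = 0.2)
  a <- steady_spectrum(wl, gauss_band_nm(wl, 700, 20))
  e <- steady_spectrum(wl, gauss_band_nm(wl, 730, 20), kind = "emission")
  est <- estimate_00_transition(a, e)
  expect_equal(est$lambda00_nm, 715, tolerance = 1e-6)
  expect_equal(est$energy00_cm1, 1e7 / est$lambda00_nm, tolerance = 1e-9)
  expect_identical(est$method, "abs-emi intersection")
  expect_error(estimate_00_transition(a, a), "maximum")
})

test_that("0-0 crossing matches a 0.001 nm brute-force scan on random pairs", {
  set.seed(42)
  wl <- seq(640, 800, by = 0.2)
  for (i in 1:200) {
    c_abs <- runif(1, 680, 710)
    c_emi <- c_abs + runif(1, 12, 40)
    w_abs <- runif(1, 10, 30)
    w_emi <- runif(1, 10, 30)
    a <- steady_spectrum(wl, gauss_band_nm(wl, c_abs, w_abs))
    e <- steady_spectrum(wl, gauss_band_nm(wl, c_emi, w_emi),
                         kind = "emission")
    est <- suppressWarnings(estimate_00_transition(a, e))
    expect_equal(est$lambda00_nm,
                 brute_crossing(c_abs, w_abs, c_emi, w_emi),
                 tolerance = 0.01 / est$lambda00_nm)
  }
})

test_that("Stokes shift is the emission-absorption maximum offset", {
  expect_equal(stokes_shift(700, 729.5), 29.5)
  expect_equal(stokes_shift(721, 721), 0)
  expect_error(stokes_shift(720, 700), "blue")
  # maxima extracted from a simulated pair with a known 25 nm offset
  wl <- seq(650, 780, by = 0.1)
  a <- wl[which.max(gauss_band_nm(wl, 701.3, 22))]
  e <- wl[which.max(gauss_band_nm(wl, 726.3, 28))]
  expect_equal(stokes_shift(a, e), 25, tolerance = 0.2 / 25)
})

test_that("thermal gap reproduces the printed 0.26 kBT and hand values", {
  expect_equal(round(thermal_gap(nm_to_wavenumber(715.6),
                                 nm_to_wavenumber(718.4), 298), 2), 0.26)
  expect_equal(thermal_gap(13500, 13500, 77), 0)
  expect_equal(thermal_gap(14000, 13900, 100), 100 / 69.50, tolerance = 1e-12)
  expect_error(thermal_gap(14000, 13900, 0), "positive")
})

test_that("excitation density follows N_Chl x 1/2 x dOD/OD", {
  expect_equal(excitation_density(12, 0.01, 1.0), 0.06)
  expect_equal(excitation_density(12, 0, 0.3), 0)
  expect_equal(excitation_density(12, 0.005, 0.6), 0.05)
  expect_error(excitation_density(12, 0.01, 0), "positive")
  expect_error(excitation_density(12, 0.01, -1), "positive")
})
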