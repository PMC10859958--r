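test_that("exp-Gaussian convolution is causal, stable and matches quadrature", {
  # delta-IRF limit
  t <- seq(0.001, 5, by = 0.01)
  expect_equal(conv_exp_gauss(t, 1, 0, 1e-6), exp(-t), tolerance = 1e-6)
  # causality: vanishes far before time zero
  expect_equal(conv_exp_gauss(c(-50, -10, -5), 1, 0, 0.1), c(0, 0, 0))
  # no overflow anywhere on a wide range
  expect_true(all(is.finite(conv_exp_gauss(seq(-1e4, 1e4, length.out = 999),
                                           0.5, 0, 0.1))))
  # numeric-quadrature oracle
  t <- seq(-1, 5, by = 0.05)
  expect_equal(conv_exp_gauss(t, 1, 0, 0.1),
               numconv_exp_gauss(t, 1, 0, 0.1, step = 1e-4),
               tolerance = 1e-7)
  expect_error(conv_exp_gauss(1, -1, 0, 0.1), "tau")
  expect_error(conv_exp_gauss(1, 1, 0, 0), "fwhm")
})

test_that("variable-projection amplitudes match a dense least-squares oracle", {
  set.seed(31)
  C <- matrix(rnorm(200 * 5), 200)
  A_true <- matrix(rnorm(5 * 40), 5)
  Y <- C %*% A_true
  # data in the model span: exact recovery, zero residual
  A <- variable_projection_amplitudes(Y, C)
  expect_equal(A, A_true, tolerance = 1e-10)
  # orthonormal basis: amplitudes are inner products
  Q <- qr.Q(qr(C))
  Yq <- Q %*% A_true + matrix(rnorm(200 * 40, sd = 0.1), 200)
  expect_equal(variable_projection_amplitudes(Yq, Q), crossprod(Q, Yq),
               tolerance = 1e-10)
  # weighted random problem vs per-column lm.wfit
  W <- matrix(runif(200 * 40, 0.5, 2), 200)
  Yn <- Y + matrix(rnorm(200 * 40, sd = 0.3), 200)
  A_w <- variable_projection_amplitudes(Yn, C, W)
  for (j in c(1, 17, 40)) {
    ref <- stats::lm.wfit(C, Yn[, j], W[, j]^2)$coefficients
    expect_equal(A_w[, j], unname(ref), tolerance = 1e-10)
  }
  expect_error(variable_projection_amplitudes(Y, cbind(C[, 1], C[, 1])),
               "rank")
})

test_that("a noiseless single component is fit to machine precision", {
  wl <- seq(700, 740, 10)
  das <- das_set(100, matrix(seq(1, 2, length.out = 5), 1), wl)
  surf <- simulate_das_surface(das, irf_gaussian(0, 0.1),
                               seq(-1, 1000, length.out = 300),
                               modality = "ta_delta_od")
  fit <- fit_global(surf, 1, irf_gaussian(0, 0.1), tau_init = 60)
  expect_equal(fit$das$lifetimes_ps, 100, tolerance = 1e-6)
  expect_equal(fit$das$spectra, das$spectra, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(fit$residual_matrix)) / max(surf$signal), 1e-6)
})

test_that("TCSPC fixture lifetimes are recovered within ten percent", {
  fx <- make_fixture("lhca4_ab_tcspc", seed = 7)
  fit <- fit_global(fx$surface, 5, fx$irf,
                    tau_init = c(8, 150, 700, 2500, 5000))
  truth <- fx$truth$das$lifetimes_ps
  expect_true(all(abs(fit$das$lifetimes_ps - truth) / truth < 0.10))
})

test_that("six TA components and their transfer sign structure are recovered", {
  fx <- make_fixture("lhca4_ab_ta", seed = 5)
  fit <- fit_global(fx$surface, 6, "fit-gaussian",
                    tau_init = c(0.3, 1.5, 10, 60, 400, 2000),
                    irf_init = c(0.01, 0.11))
  truth <- fx$truth$das$lifetimes_ps
  expect_true(all(abs(fit$das$lifetimes_ps - truth) / truth < 0.10))
  expect_gte(fit$irf_fit$fwhm, 0.087)
  expect_lte(fit$irf_fit$fwhm, 0.125)
  wl <- fit$das$wavelengths_nm
  d1 <- fit$das$spectra[1, ]
  # energy-transfer component: negative donor (Chl b) / positive acceptor
  expect_lt(d1[which.min(abs(wl - 646))], 0)
  expect_gt(d1[which.min(abs(wl - 677))], 0)
})

test_that("fit cost is invariant under wavelength permutation", {
  fx <- make_fixture("lhca4_ab_ta", seed = 2)
  perm <- rev(seq_along(fx$surface$wavelengths_nm))
  # reversal keeps the grid ascending after re-sorting labels; permute data
  surf_p <- trsurface(fx$surface$times, fx$surface$wavelengths_nm,
                      fx$surface$signal[, perm], "ta_delta_od")
  f1 <- fit_global(fx$surface, 2, fx$irf, tau_init = c(1, 300))
  f2 <- fit_global(surf_p, 2, fx$irf, tau_init = c(1, 300))
  expect_equal(f1$cost, f2$cost, tolerance = 1e-9)
})

test_that("variable projection attains the full joint least-squares optimum", {
  wl <- seq(690, 735, 5)
  times <- seq(-0.5, 50, by = 0.25)
  irf <- irf_gaussian(0, 0.1)
  das <- das_set(c(2, 20),
                 rbind(gauss_band_nm(wl, 700, 15), gauss_band_nm(wl, 720, 18)),
                 wl)
  noiseless <- simulate_das_surface(das, irf, times, modality = "ta_delta_od")
  set.seed(13)
  surf <- trsurface(times, wl,
                    noiseless$signal + rnorm(length(noiseless$signal),
                                             sd = 0.01), "ta_delta_od")
  vp <- fit_global(surf, 2, irf, tau_init = c(1.5, 25))
  # joint fit over lifetimes and all amplitudes simultaneously
  nl <- length(wl)
  joint_resid <- function(p) {
    C <- cbind(conv_exp_gauss(times, exp(p[1]), 0, 0.1),
               conv_exp_gauss(times, exp(p[2]), 0, 0.1))
    A <- matrix(p[-(1:2)], 2)
    as.numeric(surf$signal - C %*% A)
  }
  p0 <- c(log(c(1.5, 25)), as.numeric(das$spectra))
  joint <- minpack.lm::nls.lm(p0, fn = joint_resid,
                              control = minpack.lm::nls.lm.control(maxiter = 500))
  expect_equal(vp$cost, joint$deviance, tolerance = 1e-8)
})

test_that("DAS/EADS conversion is exact, invertible and resimulates", {
  wl <- seq(660, 740, 4)
  das1 <- das_set(5, matrix(gauss_band_nm(wl, 700, 20), 1), wl)
  e1 <- das_to_eads(das1)
  expect_equal(e1$spectra, das1$spectra, ignore_attr = TRUE)
  das <- das_set(c(0.5, 5, 50),
                 rbind(-gauss_band_nm(wl, 670, 15) + gauss_band_nm(wl, 700, 15),
                       -gauss_band_nm(wl, 700, 18, 0.6),
                       -gauss_band_nm(wl, 715, 22, 0.8)), wl)
  eads <- das_to_eads(das)
  expect_true(all(diff(eads$rates) < 0))
  # resimulation: sequential scheme with the EADS reproduces the parallel surface
  times <- c(seq(0, 2, 0.02), exp(seq(log(2.1), log(500), length.out = 60)))
  par_surf <- simulate_das_surface(das, irf_delta(0), times,
                                   modality = "ta_delta_od")
  seq_surf <- simulate_compartmental(sequential_scheme(eads$rates),
                                     eads$spectra, irf_delta(0), times, wl)
  expect_lt(max(abs(par_surf$signal - seq_surf$signal)) /
              max(abs(par_surf$signal)), 1e-9)
  # inverse pair round trip
  back <- eads_to_das(eads)
  expect_equal(back$spectra, das$spectra, tolerance = 1e-10,
               ignore_attr = TRUE)
  das_bad <- das_set(c(1, 1 + 1e-12), matrix(1, 2, length(wl)), wl)
  expect_error(das_to_eads(das_bad), "repeated")
})

test_that("component-count scan finds the generating number", {
  wl <- seq(660, 740, by = 4)
  das <- das_set(c(5, 50, 500),
                 rbind(gauss_band_nm(wl, 680, 15), gauss_band_nm(wl, 700, 18),
                       gauss_band_nm(wl, 715, 20)), wl)
  times <- c(seq(-0.5, 1, 0.05), exp(seq(log(1.1), log(2000), length.out = 80)))
  irf <- irf_gaussian(0, 0.1)
  clean <- simulate_das_surface(das, irf, times, modality = "ta_delta_od")
  surf <- simulate_das_surface(das, irf, times,
                               noise = list(type = "gaussian",
                                            sd = max(abs(clean$signal)) / 200),
                               modality = "ta_delta_od", seed = 4)
  sel <- suppressWarnings(select_n_components(surf, 1, 5, irf))
  expect_identical(sel$recommended, 3L)
  # pure noise: smallest n, flagged shapeless
  set.seed(9)
  noise <- trsurface(times, wl,
                     matrix(rnorm(length(times) * length(wl)), length(times)),
                     "ta_delta_od")
  sel_noise <- select_n_components(noise, 1, 3, irf)
  expect_identical(sel_noise$recommended, 1L)
  expect_true(all(unlist(sel_noise$shapeless[[1]])))
})
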