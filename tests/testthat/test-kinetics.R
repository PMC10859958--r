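test_that("delta-IRF simulation reduces to plain exponentials", {
  wl <- seq(680, 720, by = 10)
  times <- seq(0, 10, by = 0.1)
  spec <- matrix(c(1, 2, 3, 2, 1), 1)
  das <- das_set(2, spec, wl)
  surf <- simulate_das_surface(das, irf_delta(0), times,
                               modality = "ta_delta_od")
  expect_equal(surf$signal, outer(exp(-times / 2), spec[1, ]),
               tolerance = 1e-12)
  # all-zero DAS gives an all-zero surface
  das0 <- das_set(2, matrix(0, 1, 5), wl)
  expect_true(all(simulate_das_surface(das0, irf_delta(0), times,
                                       modality = "ta_delta_od")$signal == 0))
})

test_that("analytic exp(x)Gaussian matches fine-grid numeric convolution", {
  # 1 ns decay under the 92 ps TCSPC response
  t <- seq(-300, 3000, by = 10)
  a <- conv_exp_gauss(t, tau = 1000, t0 = 0, fwhm = 92)
  n <- numconv_exp_gauss(t, tau = 1000, t0 = 0, fwhm = 92, step = 0.001)
  expect_equal(a, n, tolerance = 1e-6)
})

test_that("compartment populations follow the closed-form Bateman solution", {
  expect_equal(
    as.numeric(concentrations(sequential_scheme(0.7), irf_delta(0),
                              seq(0, 8, 0.25))),
    exp(-0.7 * seq(0, 8, 0.25)), tolerance = 1e-12)
  k1 <- 2; k2 <- 0.5
  tt <- seq(0, 12, by = 0.1)
  cc <- concentrations(sequential_scheme(c(k1, k2)), irf_delta(0), tt)
  expect_equal(cc[2, ], k1 / (k1 - k2) * (exp(-k2 * tt) - exp(-k1 * tt)),
               tolerance = 1e-12)
})

test_that("eigen propagation agrees with the matrix exponential", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    K <- matrix(runif(n * n, 0, 1.5), n)
    diag(K) <- 0
    diag(K) <- -colSums(K) - runif(n, 0.05, 0.4)   # transfer + loss
    x <- runif(n); x <- x / sum(x)
    scheme <- kinetic_scheme(K, x)
    times <- sort(runif(100, 0, 10))
    got <- concentrations(scheme, irf_delta(0), times)
    want <- expm_concentrations(K, x, times)
    expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("loss-free schemes conserve population after the IRF has passed", {
  K <- matrix(0, 3, 3)
  K[2, 1] <- 1.2; K[3, 2] <- 0.4
  diag(K) <- -colSums(K)                  # column sums zero: no loss
  scheme <- kinetic_scheme(K)
  cc <- concentrations(scheme, irf_gaussian(0, 0.1), seq(2, 50, 1))
  expect_equal(colSums(cc), rep(1, ncol(cc)), tolerance = 1e-10)
})

test_that("compartmental simulation is linear in the SADS and mixes by weight", {
  wl <- seq(640, 760, by = 10)
  times <- c(seq(-0.5, 1, 0.05), exp(seq(log(1.1), log(900), length.out = 40)))
  irf <- irf_gaussian(0, 0.1)
  s1 <- sequential_scheme(1 / c(0.6, 4))
  s2 <- sequential_scheme(1 / c(2, 30))
  sads1 <- rbind(gauss_band_nm(wl, 680, 20), gauss_band_nm(wl, 700, 25))
  sads2 <- rbind(-gauss_band_nm(wl, 670, 15), -gauss_band_nm(wl, 715, 25))
  f <- 0.3
  a <- simulate_compartmental(s1, sads1, irf, times, wl)
  b <- simulate_compartmental(s2, sads2, irf, times, wl)
  mix <- (1 - f) * a$signal + f * b$signal
  am <- simulate_compartmental(s1, (1 - f) * sads1, irf, times, wl)
  bm <- simulate_compartmental(s2, f * sads2, irf, times, wl)
  expect_equal(am$signal + bm$signal, mix, tolerance = 1e-12)
  expect_true(all(simulate_compartmental(s1, 0 * sads1, irf, times, wl)$signal == 0))
  expect_error(simulate_compartmental(s1, sads1[1, , drop = FALSE], irf,
                                      times, wl), "row per compartment")
})

test_that("four-compartment sequential kinetics agree with brute-force ODE", {
  rates <- 1 / c(0.6, 4, 15, 800)
  scheme <- sequential_scheme(rates)
  irf <- irf_gaussian(0, 0.1)
  times <- c(seq(-0.5, 2, 0.05), exp(seq(log(2.2), log(3000), length.out = 50)))
  got <- concentrations(scheme, irf, times)
  s <- 0.1 / (2 * sqrt(2 * log(2)))
  forcing <- function(t) exp(-t^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  rhs <- function(t, y, p) list(scheme$rate_matrix %*% y +
                                  forcing(t) * scheme$input_vector)
  grid <- sort(unique(c(-1, times)))
  sol <- deSolve::lsoda(numeric(4), grid, rhs, NULL, rtol = 1e-11, atol = 1e-13)
  want <- t(sol[match(times, grid), -1])
  expect_lt(max(abs(got - want)) / max(got), 1e-6)
})

test_that("Poisson surfaces are seeded, reproducible and unbiased", {
  wl <- c(690, 700, 710)
  times <- c(0, 1, 2)
  das <- das_set(1000, matrix(c(1, 1, 1), 1), wl)
  one <- function(seed) simulate_das_surface(
    das, irf_delta(-50), times,
    noise = list(type = "poisson", peak_counts = 100),
    modality = "tcspc_counts", seed = seed)
  expect_identical(one(7)$signal, one(7)$signal)
  expect_false(identical(one(7)$signal, one(8)$signal))
  vals <- vapply(1:1000, function(s) one(s)$signal[1, 1], numeric(1))
  expect_gte(mean(vals), 97)
  expect_lte(mean(vals), 103)
  # negative DAS is rejected for counting data
  das_neg <- das_set(1000, matrix(c(-1, 1, 1), 1), wl)
  expect_error(simulate_das_surface(das_neg, irf_delta(-50), times,
                                    noise = list(type = "poisson"),
                                    modality = "tcspc_counts"),
               "negative expected counts")
})

test_that("surface text files round-trip bit-exactly", {
  surf <- trsurface(c(0, 0.5, 1.25), c(640.5, 650, 660.25),
                    matrix(c(0.1, -0.25, 3, 4e-6, 5, 6, 7, 8, 9.75), 3),
                    "ta_delta_od")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_surface(surf, path)
  r <- read_surface(path)
  expect_identical(r$signal, surf$signal)
  expect_identical(r$times, surf$times)
  expect_identical(r$wavelengths_nm, surf$wavelengths_nm)
  expect_identical(r$modality, "ta_delta_od")
})

test_that("fixtures carry the published generation truths", {
  fx <- make_fixture("lhca4_ab_tcspc", seed = 1)
  expect_equal(fx$truth$das$lifetimes_ps, c(12, 190, 870, 2100, 3800))
  expect_equal(fx$irf$fwhm, 92)
  # main-decay DAS areas in the printed 48:34:18 proportion
  wl <- fx$truth$das$wavelengths_nm
  areas <- apply(fx$truth$das$spectra[2:4, ], 1,
                 function(s) pracma::trapz(wl, abs(s)))
  expect_equal(areas / sum(areas), c(48, 34, 18) / 100, tolerance = 1e-9)
  fx_mix <- make_fixture("lhca4_abf_ta_mixture", noiseless = TRUE)
  expect_equal(fx_mix$truth$fraction_f, 0.67)
  expect_equal(fx_mix$truth$free_branch$scheme$n_compartments, 4)
  expect_error(make_fixture("no_such_fixture"), "arg")
})
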