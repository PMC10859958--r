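# unit-height Gaussian band on a wavelength grid
gauss_nm <- function(wl, center, fwhm, height = 1) {
  s <- fwhm / FWHM_PER_SIGMA
  height * exp(-(wl - center)^2 / (2 * s^2))
}

# scale a spectrum row so its trapezoidal |area| over wl equals `area`
scale_to_area <- function(wl, v, area) v * area / pracma::trapz(wl, abs(v))

#' Synthetic pigment basis in 80% acetone style
#'
#' Builds per-unit-concentration absorption spectra for Chl a/b/d/f and a
#' lumped carotenoid, each a sum of two or three Gaussians with Qy maxima
#' at 663 / 646 / 688 / 707 nm (in-solvent positions). The Qy-window areas
#' are calibrated so the relative oscillator strengths of
#' Chl a : b : d : f come out 1.0 : 0.67 : 1.20 : 1.34.
#'
#' @param wavelengths_nm grid, default 350-800 nm in 1 nm steps.
#' @return A [pigment_basis()].
#' @export
synthetic_pigment_basis <- function(wavelengths_nm = seq(350, 800, by = 1)) {
  wl <- wavelengths_nm
  qy <- c(630, 800)
  mk <- function(v, qy_area) {
    keep <- wl >= qy[1] & wl <= qy[2]
    a <- pracma::trapz(wl[keep], v[keep])
    steady_spectrum(wl, v * qy_area / a, kind = "absorption",
                    label = "synthetic basis")
  }
  # Qy band + vibronic shoulder + Soret band per chlorophyll
  chl_a <- gauss_nm(wl, 663, 22) + gauss_nm(wl, 618, 28, 0.12) +
    gauss_nm(wl, 430, 34, 1.1)
  chl_b <- gauss_nm(wl, 646, 24) + gauss_nm(wl, 600, 30, 0.10) +
    gauss_nm(wl, 455, 36, 1.5)
  chl_d <- gauss_nm(wl, 688, 23) + gauss_nm(wl, 640, 30, 0.10) +
    gauss_nm(wl, 445, 34, 0.9)
  chl_f <- gauss_nm(wl, 707, 24) + gauss_nm(wl, 655, 32, 0.10) +
    gauss_nm(wl, 440, 34, 0.8)
  car <- gauss_nm(wl, 450, 30) + gauss_nm(wl, 478, 26, 0.85) +
    gauss_nm(wl, 425, 24, 0.7)
  osc <- c(chl_a = 1.0, chl_b = 0.67, chl_d = 1.20, chl_f = 1.34)
  pigment_basis(list(
    chl_a = mk(chl_a, osc[["chl_a"]]),
    chl_b = mk(chl_b, osc[["chl_b"]]),
    chl_d = mk(chl_d, osc[["chl_d"]]),
    chl_f = mk(chl_f, osc[["chl_f"]]),
    car = steady_spectrum(wl, car, kind = "absorption",
                          label = "synthetic basis")))
}

# TCSPC DAS fixture: emission bands (nm grid 670-780 by 5) for five
# components; the three main decay components carry |area| ratio close to
# the printed 48:34:18
tcspc_das_truth <- function(kind = c("ab", "abd", "abf")) {
  kind <- match.arg(kind)
  wl <- seq(670, 780, by = 5)
  p <- switch(kind,
    ab  = list(tau = c(12, 190, 870, 2100, 3800),
               main_centers = c(700, 715, 733), areas = c(48, 34, 18)),
    abd = list(tau = c(11, 200, 900, 2100, 3500),
               main_centers = c(705, 725, 750), areas = c(50, 33, 17)),
    abf = list(tau = c(12, 195, 880, 2100, 3600),
               main_centers = c(700, 718, 728), areas = c(47, 34, 18)))
  # energy-transfer component: +/- donor/acceptor pattern, modest area
  das1 <- scale_to_area(wl, gauss_nm(wl, 685, 18) - gauss_nm(wl, 735, 24, 0.8),
                        12)
  main <- Map(function(c0, a) scale_to_area(wl, gauss_nm(wl, c0, 26), a),
              p$main_centers, p$areas)
  das5 <- scale_to_area(wl, gauss_nm(wl, 685, 20), 3)  # disconnected Chls
  spectra <- do.call(rbind, c(list(das1), main, list(das5)))
  das_set(p$tau, spectra, wl)
}

# six-component TA DADS fixture mirroring the Lhca4-ab transient-absorption
# analysis: three energy-transfer components with -/+ structure and three
# negative decay components
ta_dads_truth <- function() {
  wl <- seq(630, 780, by = 2)
  tau <- c(0.525, 2.19, 6.67, 43.4, 671, 2530)
  d1 <- -gauss_nm(wl, 646, 14) + gauss_nm(wl, 677, 14, 0.9)
  d2 <- -gauss_nm(wl, 652, 14, 0.5) - gauss_nm(wl, 672, 12, 0.5) +
    gauss_nm(wl, 694, 18, 0.8)
  d3 <- -gauss_nm(wl, 644, 14, 0.3) - gauss_nm(wl, 675, 12, 0.4) +
    gauss_nm(wl, 705, 20, 0.55)
  d4 <- -gauss_nm(wl, 680, 16, 0.5) - gauss_nm(wl, 700, 24, 0.25)
  d5 <- -gauss_nm(wl, 682, 16, 0.45) - gauss_nm(wl, 710, 26, 0.35)
  d6 <- -gauss_nm(wl, 684, 16, 0.3) - gauss_nm(wl, 715, 28, 0.35)
  das_set(tau, rbind(d1, d2, d3, d4, d5, d6), wl)
}

# four-compartment sequential SADS for the Chl-f-containing population:
# bleach migrating from bulk Chls towards the 724 nm Chl f forms
ta_f_branch_truth <- function(wl) {
  s1 <- -gauss_nm(wl, 646, 14, 0.8) - gauss_nm(wl, 677, 14, 0.6)
  s2 <- -gauss_nm(wl, 678, 14, 0.9) - gauss_nm(wl, 724, 18, 0.35)
  s3 <- -gauss_nm(wl, 680, 14, 0.45) - gauss_nm(wl, 724, 18, 0.75)
  s4 <- -gauss_nm(wl, 724, 20, 0.95) - gauss_nm(wl, 700, 26, 0.15)
  rates <- 1 / c(0.605, 4.17, 18.7, 700)
  list(scheme = sequential_scheme(rates), sads = rbind(s1, s2, s3, s4))
}

ta_time_grid <- function(t_max = 3500) {
  c(seq(-1, 1, by = 0.025), exp(seq(log(1.05), log(t_max), length.out = 90)))
}

#' Paper-style synthetic fixtures with generation truth
#'
#' Builds ready-made time-resolved surfaces whose generation parameters
#' mirror the printed results of the study this package models: TCSPC DAS
#' lifetimes {12, 190, 870, 2100, 3800} ps with main-decay areas in ratio
#' 48:34:18 and a 92 ps IRF; six-component transient-absorption kinetics
#' (0.525 ps ... 2.53 ns) with a ~0.1 ps Gaussian IRF; and a two-population
#' TA ensemble in which a fraction (default 0.67) of the complexes carry
#' chlorophyll f. The truth record accompanies every surface for recovery
#' tests.
#'
#' @param name one of `"lhca4_ab_tcspc"`, `"lhca4_abd_tcspc"`,
#'   `"lhca4_abf_tcspc"`, `"lhca4_ab_ta"`, `"lhca4_abf_ta_mixture"`.
#' @param seed RNG seed for the noise draw.
#' @param peak_counts TCSPC peak counts (default 2e4).
#' @param noise_sd TA Gaussian noise, as a fraction of the signal maximum
#'   absolute value (default 0.003).
#' @param fraction_f Chl-f population fraction of the mixture fixture
#'   (default 0.67).
#' @param noiseless set `TRUE` to skip the noise draw.
#' @return List with `surface`, `irf` and a `truth` record (generation
#'   parameters).
#' @export
make_fixture <- function(name = c("lhca4_ab_tcspc", "lhca4_abd_tcspc",
                                  "lhca4_abf_tcspc", "lhca4_ab_ta",
                                  "lhca4_abf_ta_mixture"),
                         seed = 1, peak_counts = 2e4, noise_sd = 0.003,
                         fraction_f = 0.67, noiseless = FALSE) {
  name <- match.arg(name)
  if (grepl("tcspc", name)) {
    das <- tcspc_das_truth(sub("lhca4_(\\w+)_tcspc", "\\1", name))
    times <- seq(0, 25000, length.out = 4096)    # 25 ns window, ~6.1 ps/channel
    irf <- irf_gaussian(t0 = 300, fwhm = 92)
    noise <- if (noiseless) NULL else
      list(type = "poisson", peak_counts = peak_counts)
    surf <- simulate_das_surface(das, irf, times, noise,
                                 modality = "tcspc_counts", seed = seed)
    return(list(surface = surf, irf = irf,
                truth = list(das = das, irf = irf,
                             main_area_ratio = c(48, 34, 18))))
  }
  if (name == "lhca4_ab_ta") {
    das <- ta_dads_truth()
    times <- ta_time_grid()
    irf <- irf_gaussian(t0 = 0, fwhm = 0.1)
    expected <- simulate_das_surface(das, irf, times, NULL,
                                     modality = "ta_delta_od")
    noise <- if (noiseless) NULL else
      list(type = "gaussian", sd = noise_sd * max(abs(expected$signal)))
    surf <- simulate_das_surface(das, irf, times, noise,
                                 modality = "ta_delta_od", seed = seed)
    return(list(surface = surf, irf = irf, truth = list(das = das, irf = irf)))
  }
  # two-population TA mixture: fraction_f of the complexes carry Chl f
  dads_ab <- ta_dads_truth()
  wl <- dads_ab$wavelengths_nm
  eads_ab <- das_to_eads(dads_ab)
  fixed <- list(scheme = sequential_scheme(eads_ab$rates),
                sads = eads_ab$spectra)
  free <- ta_f_branch_truth(wl)
  # equal time-zero SADS areas make the amplitude split a population split
  w <- trapz_weights(wl)
  a_fix <- sum(w * abs(fixed$sads[1, ]))
  a_free <- sum(w * abs(free$sads[1, ]))
  free$sads <- free$sads * a_fix / a_free
  times <- ta_time_grid()
  irf <- irf_gaussian(t0 = 0, fwhm = 0.1)
  sig <- (1 - fraction_f) *
    t(concentrations(fixed$scheme, irf, times)) %*% fixed$sads +
    fraction_f * t(concentrations(free$scheme, irf, times)) %*% free$sads
  noise <- if (noiseless) NULL else
    list(type = "gaussian", sd = noise_sd * max(abs(sig)))
  surf <- trsurface(times, wl, apply_noise(sig, noise, "ta_delta_od", seed),
                    "ta_delta_od")
  list(surface = surf, irf = irf,
       truth = list(fraction_f = fraction_f, fixed_branch = fixed,
                    free_branch = free, irf = irf))
}
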