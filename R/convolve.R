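# log of the complementary error function, accurate on the whole real
# line (erfc(x) = 2*pnorm(-x*sqrt(2)); log.p keeps the tail from
# underflowing for large x)
log_erfc <- function(x) log(2) + stats::pnorm(x * sqrt(2), lower.tail = FALSE,
                                              log.p = TRUE)

#' Analytic convolution of an exponential decay with a Gaussian IRF
#'
#' Evaluates the convolution of the causal decay exp(-(t - t0)/tau) with a
#' unit-area Gaussian instrument response of the given fwhm centered at
#' `t0`. The closed form is
#' 0.5 * exp(k(t0 - t) + (k sigma)^2/2) * erfc((t0 - t + k sigma^2)/(sigma sqrt(2)))
#' with k = 1/tau; it is computed through log(erfc) so that neither factor
#' overflows at any `t`.
#'
#' @param t time(s), same units as `tau`.
#' @param tau decay lifetime (> 0).
#' @param t0 IRF center.
#' @param fwhm IRF full width at half maximum (> 0).
#' @return Convolution value(s); tends to exp(-(t - t0)/tau) for
#'   t - t0 >> fwhm and to 0 for t << t0.
#' @export
conv_exp_gauss <- function(t, tau, t0 = 0, fwhm) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  conv_rate_gauss(t, 1 / tau, t0, fwhm)
}

# same, parameterized by rate k >= 0 (k = 0 gives the IRF-blurred step)
conv_rate_gauss <- function(t, k, t0, fwhm) {
  sigma <- fwhm / FWHM_PER_SIGMA
  x <- (t0 - t + k * sigma^2) / (sigma * sqrt(2))
  0.5 * exp(k * (t0 - t) + (k * sigma)^2 / 2 + log_erfc(x))
}

# exponential decay under a delta IRF at t0
conv_rate_delta <- function(t, k, t0) ifelse(t >= t0, exp(-k * (t - t0)), 0)

# numeric convolution of exp(-k t) with a measured IRF trace given on the
# (uniform) time grid of the surface; irf trace must integrate to 1
conv_rate_measured <- function(times, k, irf_trace) {
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("measured-IRF convolution requires a uniform time grid")
  dt <- mean(dt)
  n <- length(times)
  dec <- exp(-k * (times - times[1]))
  full <- stats::convolve(irf_trace, rev(dec), type = "open") * dt
  full[seq_len(n)]
}
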