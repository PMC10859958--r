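FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

#' Construct a Gaussian band description
#'
#' @param center_cm1 band center, cm^-1.
#' @param fwhm_cm1 full width at half maximum, cm^-1 (> 0).
#' @param area band area (>= 0) in value x cm^-1 units.
#' @return A `gaussian_band` list.
#' @export
gaussian_band <- function(center_cm1, fwhm_cm1, area) {
  if (fwhm_cm1 <= 0) stop("fwhm must be positive")
  if (area < 0) stop("area must be non-negative")
  structure(list(center_cm1 = center_cm1, fwhm_cm1 = fwhm_cm1, area = area),
            class = "gaussian_band")
}

# evaluate a sum of area-normalized Gaussians on a wavenumber grid;
# par = c(center1, log_sigma1, log_area1, center2, ...)
gauss_sum <- function(par, nu) {
  n <- length(par) / 3L
  out <- numeric(length(nu))
  for (i in seq_len(n)) {
    c0 <- par[3 * i - 2]
    s <- exp(par[3 * i - 1])
    a <- exp(par[3 * i])
    out <- out + a / (s * sqrt(2 * pi)) * exp(-(nu - c0)^2 / (2 * s^2))
  }
  out
}

#' Multi-Gaussian deconvolution of an absorption spectrum
#'
#' Decomposes a (typically 77 K) absorption band into a sum of Gaussians.
#' The fit is performed in the wavenumber domain, where Gaussian line
#' shapes are conventional; centers and widths can be converted back to nm
#' with [band_fwhm_nm()] and [wavenumber_to_nm()]. Widths and areas are
#' optimized in log space; five jittered restarts (deterministic given
#' `seed`) guard against local minima.
#'
#' @param spec a [steady_spectrum()] (wavelength domain; converted
#'   internally).
#' @param n_bands number of Gaussians (>= 1).
#' @param init optional list of [gaussian_band()] initial values; default is
#'   equally spaced centers across the fitted window.
#' @param window optional wavelength window (nm) restricting the fit.
#' @param fwhm_bounds_cm1 allowed fwhm interval, default `c(20, 800)` cm^-1.
#' @param n_starts number of jittered restarts (default 5).
#' @param seed seed for the restart jitter (default 1).
#' @return List of class `deconv_result`: `bands` (ascending center),
#'   `residual_rms`, `converged`, `fitted`, `nu_cm1`.
#' @export
fit_gaussians <- function(spec, n_bands, init = NULL, window = NULL,
                          fwhm_bounds_cm1 = c(20, 800), n_starts = 5, seed = 1) {
  stopifnot(n_bands >= 1)
  w <- spec$wavelengths_nm
  v <- spec$values
  if (!is.null(window)) {
    keep <- w >= window[1] & w <= window[2]
    w <- w[keep]; v <- v[keep]
  }
  nu <- rev(nm_to_wavenumber(w))   # ascending wavenumber grid
  y <- rev(v)
  if (3 * n_bands > length(nu))
    warning("more Gaussian parameters than data points; fit is underdetermined")
  sig_lo <- fwhm_bounds_cm1[1] / FWHM_PER_SIGMA
  sig_hi <- fwhm_bounds_cm1[2] / FWHM_PER_SIGMA
  span <- range(nu)
  tot_area <- pracma::trapz(nu, y)
  if (is.null(init)) {
    # greedy peak-pick: put each band at the running residual maximum with
    # a local half-maximum width estimate, then subtract and repeat
    yw <- y
    par0 <- numeric(0)
    for (i in seq_len(n_bands)) {
      j <- which.max(yw)
      h <- yw[j]
      half <- which(yw < h / 2)
      rgt <- half[half > j]; lft <- half[half < j]
      hw_r <- if (length(rgt)) nu[min(rgt)] - nu[j] else diff(span) / 4
      hw_l <- if (length(lft)) nu[j] - nu[max(lft)] else diff(span) / 4
      sig <- max(sig_lo, min(sig_hi, (hw_r + hw_l) / FWHM_PER_SIGMA))
      a <- max(h, 1e-12) * sig * sqrt(2 * pi)
      par0 <- c(par0, nu[j], log(sig), log(a))
      yw <- yw - h * exp(-(nu - nu[j])^2 / (2 * sig^2))
    }
  } else {
    par0 <- as.numeric(vapply(init, function(b) {
      c(b$center_cm1, log(b$fwhm_cm1 / FWHM_PER_SIGMA), log(max(b$area, 1e-12)))
    }, numeric(3)))
  }
  lower <- rep(c(span[1], log(sig_lo), -50), n_bands)
  upper <- rep(c(span[2], log(sig_hi), 50), n_bands)
  par0 <- pmin(pmax(par0, lower), upper)

  resid_fn <- function(p) gauss_sum(p, nu) - y
  best <- NULL
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (s in seq_len(n_starts)) {
    p <- par0
    if (s > 1L) {
      jitter <- stats::rnorm(length(p), sd = rep(c(diff(span) / 20, 0.2, 0.3),
                                                 n_bands))
      p <- pmin(pmax(par0 + jitter, lower), upper)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(p, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all restarts of the Gaussian fit failed")
  p <- best$par
  centers <- p[seq(1, length(p), 3)]
  if (n_bands > 1L && min(dist(centers)) < 1)
    warning("two fitted band centers coincide; model is ill-conditioned")
  ord <- order(centers)
  bands <- lapply(ord, function(i) {
    gaussian_band(p[3 * i - 2], exp(p[3 * i - 1]) * FWHM_PER_SIGMA,
                  exp(p[3 * i]))
  })
  converged <- best$info %in% 1:4
  if (!converged) warning("Gaussian fit did not converge within iteration cap")
  structure(list(bands = bands,
                 residual_rms = sqrt(best$deviance / length(y)),
                 converged = converged,
                 fitted = gauss_sum(p, nu), nu_cm1 = nu),
            class = "deconv_result")
}

#' Band width in nm at the band center
#'
#' First-order conversion of a fwhm from the wavenumber to the wavelength
#' domain: d(lambda) = lambda^2 d(nu) / 1e7 evaluated at the band center.
#'
#' @param band a [gaussian_band()].
#' @return fwhm in nm.
#' @export
band_fwhm_nm <- function(band) {
  if (band$center_cm1 <= 0) stop("band center must be positive")
  lam <- wavenumber_to_nm(band$center_cm1)
  lam^2 * band$fwhm_cm1 / 1e7
}

#' Tabulate a deconvolution result
#'
#' @param x a `deconv_result`.
#' @param ... unused.
#' @return data.frame with centers (cm^-1 and nm), fwhm (cm^-1 and nm),
#'   area and fractional area per band.
#' @export
as.data.frame.deconv_result <- function(x, ...) {
  areas <- vapply(x$bands, `[[`, numeric(1), "area")
  data.frame(
    center_cm1 = vapply(x$bands, `[[`, numeric(1), "center_cm1"),
    center_nm = wavenumber_to_nm(vapply(x$bands, `[[`, numeric(1), "center_cm1")),
    fwhm_cm1 = vapply(x$bands, `[[`, numeric(1), "fwhm_cm1"),
    fwhm_nm = vapply(x$bands, band_fwhm_nm, numeric(1)),
    area = areas,
    frac_area = areas / sum(areas)
  )
}
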