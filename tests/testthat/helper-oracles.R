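# Independent oracles and small generators used across the suite.

# numeric convolution of a causal exponential with a unit-area Gaussian,
# by trapezoid quadrature on a fine grid split at the causality kink
numconv_exp_gauss <- function(t, tau, t0, fwhm, step = 1e-4) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  vapply(t, function(tt) {
    lo <- max(0, tt - t0 - 12 * s)
    hi <- tt - t0 + 12 * s
    if (hi <= lo) return(0)
    u <- seq(lo, hi, by = step)
    f <- exp(-u / tau) *
      exp(-(tt - t0 - u)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
    pracma::trapz(u, f)
  }, numeric(1))
}

# matrix-exponential propagation of dc/dt = K c from c(0) = x (delta IRF)
expm_concentrations <- function(K, x, times) {
  vapply(times, function(tt) {
    if (tt < 0) return(numeric(length(x)))
    as.numeric(Matrix::expm(K * tt) %*% x)
  }, numeric(length(x)))
}

# unit-height Gaussian band in the wavelength domain
gauss_band_nm <- function(wl, center, fwhm, height = 1) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  height * exp(-(wl - center)^2 / (2 * s^2))
}

# brute-force 0-0 crossing: evaluate the two analytic unit-max Gaussians on
# a 0.001 nm grid between the maxima and take the first sign change
brute_crossing <- function(c_abs, w_abs, c_emi, w_emi, step = 0.001) {
  g <- seq(c_abs, c_emi, by = step)
  d <- gauss_band_nm(g, c_abs, w_abs) - gauss_band_nm(g, c_emi, w_emi)
  i <- which(d[-1] * d[-length(d)] < 0)[1]
  g[i] - d[i] * step / (d[i + 1] - d[i])
}

# penalty-method solution of the area-constrained SADS problem: one big
# least-squares stack (per-wavelength blocks) plus a sqrt(penalty)-scaled
# row enforcing the area, solved by QR
penalty_sads_solve <- function(Y, C, w, a_target, penalty = 1e12) {
  nc <- ncol(C)
  nl <- ncol(Y)
  nt <- nrow(C)
  A <- matrix(0, nt * nl + 1, nc * nl)
  b <- numeric(nt * nl + 1)
  for (j in seq_len(nl)) {
    A[(j - 1) * nt + seq_len(nt), (j - 1) * nc + seq_len(nc)] <- C
    b[(j - 1) * nt + seq_len(nt)] <- Y[, j]
  }
  cvec <- as.numeric(vapply(seq_len(nl), function(j) {
    v <- numeric(nc); v[1] <- w[j]; v
  }, numeric(nc)))
  A[nt * nl + 1, ] <- sqrt(penalty) * cvec
  b[nt * nl + 1] <- sqrt(penalty) * a_target
  matrix(qr.coef(qr(A), b), nrow = nc)
}

# evaluate a sum of Gaussians defined by (center, sigma, amplitude) rows
eval_gauss_mixture <- function(nu, pars) {
  y <- numeric(length(nu))
  for (p in pars) y <- y + p[3] * exp(-(nu - p[1])^2 / (2 * p[2]^2))
  y
}

make_wavenumber_spectrum <- function(nu, y) {
  steady_spectrum(rev(1e7 / nu), rev(y), kind = "absorption")
}
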