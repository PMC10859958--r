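# trapezoid quadrature weights: sum(w * v) == trapz(x, v)
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# default fit weights by modality: Poisson (1/sqrt(counts)) for TCSPC,
# uniform for TA
default_weights <- function(surface) {
  if (surface$modality == "tcspc_counts")
    1 / sqrt(pmax(surface$signal, 1))
  else
    matrix(1, nrow(surface$signal), ncol(surface$signal))
}

#' Conditionally linear amplitudes of a time-resolved fit
#'
#' The linear stage of variable projection: given the concentration (model
#' basis) matrix, solves the per-wavelength weighted least-squares problem
#' for the associated spectra.
#'
#' @param signal data matrix, times x wavelengths (or a [trsurface()]).
#' @param concentration_matrix times x components model basis, full column
#'   rank.
#' @param weights optional times x wavelengths weight matrix (multiplies
#'   the residuals).
#' @param strict error on a rank-deficient basis (default). With
#'   `strict = FALSE` redundant columns get zero amplitude instead, which
#'   keeps iterative fits alive while two lifetimes cross.
#' @return Matrix components x wavelengths of amplitudes.
#' @export
variable_projection_amplitudes <- function(signal, concentration_matrix,
                                           weights = NULL, strict = TRUE) {
  if (inherits(signal, "trsurface")) signal <- signal$signal
  C <- concentration_matrix
  if (strict && qr(C)$rank < ncol(C))
    stop("concentration matrix is rank deficient")
  nl <- ncol(signal)
  amps <- matrix(0, ncol(C), nl)
  if (is.null(weights)) {
    amps <- qr.coef(qr(C), signal)
  } else {
    for (j in seq_len(nl)) {
      wj <- weights[, j]
      amps[, j] <- qr.coef(qr(C * wj), signal[, j] * wj)
    }
  }
  amps[is.na(amps)] <- 0
  amps
}

# model basis of IRF-convolved exponentials for given lifetimes
exp_basis <- function(times, taus, irf) {
  vapply(taus, function(tau) irf_convolve(times, 1 / tau, irf),
         numeric(length(times)))
}

#' Global analysis of a time-resolved surface
#'
#' Fits the surface to a sum of `n_components` IRF-convolved exponential
#' decays by variable projection: the lifetimes (and optionally the
#' Gaussian IRF position and width) are optimized by Levenberg-Marquardt
#' while the decay-associated spectra are eliminated at every step by
#' conditional weighted linear least squares. Lifetimes are optimized in
#' log space and reported ascending. Weighting is Poisson
#' (1/sqrt(max(counts, 1))) for TCSPC surfaces and uniform for TA.
#'
#' @param surface a [trsurface()].
#' @param n_components number of exponentials (>= 1).
#' @param irf an `irf_model`, or `"fit-gaussian"` to fit the Gaussian IRF
#'   position and width along with the lifetimes.
#' @param tau_init initial lifetimes, ps (length `n_components`).
#' @param weights optional weight matrix overriding the modality default.
#' @param irf_init initial `c(t0, fwhm)` when `irf = "fit-gaussian"`.
#' @param fwhm_bounds allowed fwhm interval when the IRF is fitted;
#'   default `c(0.087, 0.125)` ps, the usual range for this TA setup.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return List of class `global_fit`: `das` (a [das_set()]), `irf_fit`,
#'   `residual_matrix`, `cost` (weighted SSQ), `n_iterations`,
#'   `degenerate` flag.
#' @export
fit_global <- function(surface, n_components, irf = "fit-gaussian",
                       tau_init, weights = NULL, irf_init = c(0, 0.1),
                       fwhm_bounds = c(0.087, 0.125), max_iter = 500) {
  stopifnot(n_components >= 1, length(tau_init) == n_components,
            all(tau_init > 0))
  fit_irf <- identical(irf, "fit-gaussian")
  if (is.null(weights)) weights <- default_weights(surface)
  Y <- surface$signal
  times <- surface$times

  build <- function(par) {
    taus <- exp(par[seq_len(n_components)])
    this_irf <- if (fit_irf)
      irf_gaussian(t0 = par[n_components + 1], fwhm = par[n_components + 2])
    else irf
    exp_basis(times, taus, this_irf)
  }
  resid_fn <- function(par) {
    C <- build(par)
    A <- variable_projection_amplitudes(Y, C, weights, strict = FALSE)
    as.numeric((Y - C %*% A) * weights)
  }
  par0 <- log(tau_init)
  lower <- rep(-Inf, n_components)
  upper <- rep(Inf, n_components)
  if (fit_irf) {
    par0 <- c(par0, irf_init)
    lower <- c(lower, -Inf, fwhm_bounds[1])
    upper <- c(upper, Inf, fwhm_bounds[2])
  }
  fit <- minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-10, ptol = 1e-10))
  if (fit$info == 5) stop("global fit hit the iteration cap without converging")
  taus <- exp(fit$par[seq_len(n_components)])
  degenerate <- n_components > 1 &&
    min(abs(diff(sort(taus))) / sort(taus)[-1]) < 0.01
  if (degenerate) warning("two lifetimes collapsed within 1%; fit is degenerate")
  irf_fit <- if (fit_irf)
    irf_gaussian(t0 = fit$par[n_components + 1],
                 fwhm = fit$par[n_components + 2])
  else irf
  ord <- order(taus)
  C <- exp_basis(times, taus[ord], irf_fit)
  A <- variable_projection_amplitudes(Y, C, weights, strict = !degenerate)
  resid <- Y - C %*% A
  structure(list(
    das = das_set(taus[ord], A, surface$wavelengths_nm),
    irf_fit = irf_fit,
    residual_matrix = resid,
    cost = sum((resid * weights)^2),
    n_iterations = fit$niter,
    degenerate = degenerate), class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit>", length(x$das$lifetimes_ps), "components, lifetimes (ps):",
      paste(signif(x$das$lifetimes_ps, 4), collapse = ", "),
      sprintf("\n  cost %.6g after %d iterations\n", x$cost, x$n_iterations))
  invisible(x)
}

# amplitude matrix A of a unidirectional sequential scheme under a delta
# IRF: c_j(t) = sum_i A[j, i] exp(-k_i t), rates descending
sequential_amplitudes <- function(rates) {
  scheme <- sequential_scheme(rates)
  eg <- eigen(scheme$rate_matrix)
  V <- Re(eg$vectors)
  amp <- solve(V, scheme$input_vector)
  A <- V * rep(amp, each = nrow(V))
  # columns of A follow eigen() ordering; map to the rate ordering
  idx <- vapply(rates, function(r) which.min(abs(Re(eg$values) + r)),
                integer(1))
  A[, idx, drop = FALSE]
}

#' Convert decay-associated to evolution-associated spectra
#'
#' Finds the spectra (EADS) of the unidirectional sequential scheme with
#' rates 1/tau_i whose summed signal equals the parallel DAS description.
#' With D the DAS matrix and A the Bateman amplitude matrix of the
#' sequential populations, D = A' E, solved exactly for E.
#'
#' @param das a [das_set()] with distinct lifetimes.
#' @return List of class `eads_set`: `rates` (descending), `spectra`,
#'   `wavelengths_nm`.
#' @export
das_to_eads <- function(das) {
  taus <- das$lifetimes_ps
  if (length(taus) > 1 && min(abs(diff(taus)) / taus[-1]) < 1e-9)
    stop("repeated lifetimes; sequential equivalent is degenerate")
  rates <- 1 / taus           # descending, since lifetimes ascend
  A <- sequential_amplitudes(rates)
  E <- solve(t(A), das$spectra)
  structure(list(rates = rates, spectra = E,
                 wavelengths_nm = das$wavelengths_nm), class = "eads_set")
}

#' @rdname das_to_eads
#' @param eads an `eads_set`.
#' @export
eads_to_das <- function(eads) {
  A <- sequential_amplitudes(eads$rates)
  das_set(1 / eads$rates, t(A) %*% eads$spectra, eads$wavelengths_nm)
}

#' Scan the number of exponential components
#'
#' Fits the surface with each candidate number of components and reports
#' the cost sequence, a noise ("shapeless") flag per component spectrum
#' (lag-1 autocorrelation below `shapeless_threshold`), and recommends the
#' smallest n beyond which the cost improves by less than `min_improvement`.
#'
#' @param surface a [trsurface()].
#' @param n_min,n_max candidate range.
#' @param irf IRF model (or `"fit-gaussian"`).
#' @param min_improvement fractional cost-improvement threshold (default
#'   0.02).
#' @param shapeless_threshold lag-1 autocorrelation below which a spectrum
#'   is flagged as noise (default 0.3).
#' @param tau_range lifetimes used to seed each fit (log-spaced across this
#'   interval, ps).
#' @return List with `recommended`, `costs`, `fits`, `shapeless`.
#' @export
select_n_components <- function(surface, n_min, n_max, irf,
                                min_improvement = 0.02,
                                shapeless_threshold = 0.3,
                                tau_range = c(0.3, 3000)) {
  stopifnot(n_min >= 1, n_min <= n_max)
  ns <- n_min:n_max
  fits <- vector("list", length(ns))
  costs <- numeric(length(ns))
  shapeless <- vector("list", length(ns))
  for (i in seq_along(ns)) {
    tau0 <- exp(seq(log(tau_range[1]), log(tau_range[2]),
                    length.out = ns[i] + 2))[2:(ns[i] + 1)]
    fit <- tryCatch(suppressWarnings(
      fit_global(surface, ns[i], irf, tau_init = tau0)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # non-convergence on featureless data: no improvement, pure noise
      costs[i] <- if (i > 1) costs[i - 1] else sum(surface$signal^2)
      shapeless[[i]] <- rep(TRUE, ns[i])
      next
    }
    fits[[i]] <- fit
    costs[i] <- fit$cost
    shapeless[[i]] <- apply(fit$das$spectra, 1, function(s) {
      s <- s - mean(s)
      if (sum(s^2) == 0) return(TRUE)
      sum(s[-1] * s[-length(s)]) / sum(s^2) < shapeless_threshold
    })
  }
  improvement <- -diff(costs) / costs[-length(costs)]
  rec <- ns[length(ns)]
  for (i in seq_along(improvement)) {
    if (improvement[i] < min_improvement) { rec <- ns[i]; break }
  }
  list(recommended = rec, costs = stats::setNames(costs, ns),
       fits = fits, shapeless = shapeless)
}
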