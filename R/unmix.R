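#' Build a pigment basis from per-pigment spectra
#'
#' A pigment basis holds one absorption spectrum per pigment, all on a
#' common wavelength grid and on a per-unit-concentration scale, for use in
#' spectral unmixing of acetone pigment extracts.
#'
#' @param spectra named list of [steady_spectrum()] objects; names identify
#'   the pigments (`chl_a`, `chl_b`, `chl_d`, `chl_f`, `car`).
#' @return An object of class `pigment_basis`.
#' @export
pigment_basis <- function(spectra) {
  nm <- names(spectra)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    stop("spectra must be uniquely named by pigment")
  g <- spectra[[1]]$wavelengths_nm
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wavelengths_nm, g)))
      stop("all basis spectra must share one wavelength grid")
    if (any(s$values < 0)) stop("basis spectra must be non-negative")
  }
  structure(list(names = nm, wavelengths_nm = g,
                 matrix = vapply(spectra, function(s) s$values, numeric(length(g)))),
            class = "pigment_basis")
}

#' Read a pigment basis from a directory of spectrum files
#'
#' Expects two-column files named `<pigment>.txt` (e.g. `chl_a.txt`).
#'
#' @param dir directory path.
#' @return A [pigment_basis()].
#' @export
read_pigment_basis <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no .txt spectra in ", dir)
  specs <- lapply(files, read_spectrum)
  names(specs) <- sub("\\.txt$", "", basename(files))
  pigment_basis(specs)
}

#' Unmix an extract spectrum into per-pigment concentrations
#'
#' Decomposes an 80%-acetone extract absorption spectrum as a non-negative
#' linear combination of the pigment basis spectra over a fit window,
#' by non-negative least squares. Concentrations cannot be negative, so
#' non-negativity is enforced rather than imposed post hoc.
#'
#' @param extract extract absorption spectrum, a [steady_spectrum()].
#' @param basis a [pigment_basis()].
#' @param fit_window_nm wavelength window used in the fit; default
#'   `c(600, 750)` covers the structured Qy region in acetone.
#' @return List with `coefficients` (named, >= 0), `residual_norm`, and
#'   `fitted` values on the window grid.
#' @export
unmix <- function(extract, basis, fit_window_nm = c(600, 750)) {
  g <- basis$wavelengths_nm
  keep <- g >= fit_window_nm[1] & g <= fit_window_nm[2]
  if (sum(keep) < length(basis$names))
    stop("fit window contains fewer points than pigments")
  if (fit_window_nm[1] < min(extract$wavelengths_nm) ||
      fit_window_nm[2] > max(extract$wavelengths_nm))
    stop("extract spectrum does not cover the fit window")
  A <- basis$matrix[keep, , drop = FALSE]
  nrm <- sqrt(colSums(A^2))
  nrm[nrm < 1e-8 * max(nrm)] <- 0
  if (any(nrm == 0))
    stop("basis spectrum of '", paste(basis$names[nrm == 0], collapse = "', '"),
         "' vanishes on the fit window (rank-deficient basis)")
  An <- sweep(A, 2, nrm, "/")
  gram <- crossprod(An)
  off <- abs(gram - diag(ncol(A)))
  if (max(off) > 1 - 1e-10) {
    ij <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("basis spectra '", basis$names[ij[1]], "' and '", basis$names[ij[2]],
         "' are collinear on the fit window")
  }
  y <- stats::approx(extract$wavelengths_nm, extract$values, xout = g[keep])$y
  if (all(y == 0)) {
    coef <- stats::setNames(numeric(ncol(A)), basis$names)
    return(list(coefficients = coef, residual_norm = 0,
                fitted = y, wavelengths_nm = g[keep]))
  }
  fit <- pracma::lsqnonneg(A, y)
  coef <- stats::setNames(as.numeric(fit$x), basis$names)
  list(coefficients = coef,
       residual_norm = sqrt(sum(fit$resid.norm)),
       fitted = as.numeric(A %*% coef),
       wavelengths_nm = g[keep])
}

chl_names <- function(nm) nm[grepl("^chl_", nm)]

#' Normalize unmixing coefficients to a per-complex stoichiometry
#'
#' Scales the chlorophyll coefficients so that they sum to `total_chl`
#' chlorophylls per complex (12 for monomeric Lhca4); the carotenoid
#' coefficient is scaled by the same factor.
#'
#' @param coefficients named non-negative vector from [unmix()].
#' @param total_chl total chlorophylls per complex (default 12).
#' @return An object of class `stoichiometry` with `counts` and `total_chl`.
#' @export
to_stoichiometry <- function(coefficients, total_chl = 12) {
  cn <- chl_names(names(coefficients))
  if (!length(cn) || sum(coefficients[cn]) <= 0)
    stop("no positive chlorophyll coefficients to normalize")
  f <- total_chl / sum(coefficients[cn])
  structure(list(counts = coefficients * f, total_chl = total_chl),
            class = "stoichiometry")
}

#' Construct a stoichiometry from known per-complex counts
#'
#' @param counts named non-negative vector of pigment counts
#'   (`chl_a`, `chl_b`, ..., optionally `car`).
#' @param total_chl normalization constant; defaults to the chlorophyll sum
#'   of `counts`, i.e. the counts are taken as already normalized.
#' @return A `stoichiometry`.
#' @export
stoichiometry <- function(counts, total_chl = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  cn <- chl_names(names(counts))
  if (is.null(total_chl)) total_chl <- sum(counts[cn])
  structure(list(counts = counts, total_chl = total_chl),
            class = "stoichiometry")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat("<stoichiometry>", paste(sprintf("%s=%.2f", names(x$counts), x$counts),
                               collapse = " "),
      sprintf("(total Chl %g)\n", x$total_chl))
  invisible(x)
}

safe_ratio <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_

#' Pigment ratios of a stoichiometry
#'
#' Computes the ratios conventionally reported for chlorophyll extracts:
#' a/b, (a+d)/b, (a+f)/b, a/d, a/f and total Chl/Car. Ratios with a zero
#' denominator are reported as `NA`.
#'
#' @param stoich a [stoichiometry()].
#' @return Named list of class `ratio_report`.
#' @export
ratios <- function(stoich) {
  k <- function(p) if (p %in% names(stoich$counts)) stoich$counts[[p]] else 0
  a <- k("chl_a"); b <- k("chl_b"); d <- k("chl_d"); f <- k("chl_f")
  car <- k("car")
  structure(list(
    a_b = safe_ratio(a, b),
    a_plus_d_b = safe_ratio(a + d, b),
    a_plus_f_b = safe_ratio(a + f, b),
    a_d = safe_ratio(a, d),
    a_f = safe_ratio(a, f),
    chl_car = safe_ratio(a + b + d + f, car)
  ), class = "ratio_report")
}

#' Relative oscillator strengths of the basis pigments in the Qy region
#'
#' Integrates each per-unit-concentration basis spectrum over the Qy window
#' and divides by the reference pigment's integral. With a realistic basis
#' this reproduces the ~1.0 : 0.67 : 1.20 : 1.34 pattern for
#' Chl a : b : d : f.
#'
#' @param basis a [pigment_basis()].
#' @param window integration window, nm; default `c(630, 800)`.
#' @param reference reference pigment name, default `"chl_a"`.
#' @return Named numeric vector of weights (reference = 1).
#' @export
relative_oscillator_strengths <- function(basis, window = c(630, 800),
                                          reference = "chl_a") {
  if (!reference %in% basis$names)
    stop("reference pigment '", reference, "' not in basis")
  g <- basis$wavelengths_nm
  areas <- vapply(seq_along(basis$names), function(j) {
    spectrum_area(steady_spectrum(g, basis$matrix[, j]), window)
  }, numeric(1))
  names(areas) <- basis$names
  areas / areas[[reference]]
}
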