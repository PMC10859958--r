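#' Construct a steady-state spectrum
#'
#' A `steady_spectrum` is the basic container for absorption and emission
#' spectra: a strictly increasing wavelength grid (nm) with one intensity
#' value per grid point (OD for absorption, arbitrary units for emission).
#'
#' @param wavelengths_nm numeric vector, strictly increasing, length >= 3.
#' @param values numeric vector of the same length; no non-finite entries.
#' @param kind `"absorption"` or `"emission"`.
#' @param temperature_K positive scalar, or `NA` when unknown.
#' @param label free-text label.
#'
#' @return An object of class `steady_spectrum`.
#' @export
steady_spectrum <- function(wavelengths_nm, values,
                            kind = c("absorption", "emission"),
                            temperature_K = NA_real_, label = "") {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) < 3L)
    stop("a spectrum needs at least 3 grid points")
  if (length(values) != length(wavelengths_nm))
    stop("wavelengths and values differ in length")
  if (any(!is.finite(wavelengths_nm)) || any(!is.finite(values)))
    stop("non-finite values in spectrum")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (!is.na(temperature_K) && temperature_K <= 0)
    stop("temperature_K must be positive")
  structure(list(wavelengths_nm = wavelengths_nm, values = values,
                 kind = kind, temperature_K = as.numeric(temperature_K),
                 label = as.character(label)),
            class = "steady_spectrum")
}

#' @export
print.steady_spectrum <- function(x, ...) {
  cat(sprintf("<steady_spectrum> %s%s, %d points, %.1f-%.1f nm%s\n",
              x$kind,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              if (is.na(x$temperature_K)) "" else
                sprintf(", %g K", x$temperature_K)))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Files are whitespace- or comma-delimited, two columns (wavelength in nm,
#' value). `#`-prefixed header lines may carry `kind:`, `temperature_K:` and
#' `label:` metadata.
#'
#' @param path file path.
#' @return A [steady_spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  meta <- list(kind = "absorption", temperature_K = NA_real_, label = "")
  for (h in hdr) {
    h <- sub("^\\s*#\\s*", "", h)
    m <- regmatches(h, regexec("^(\\w+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta))
      meta[[m[2]]] <- if (m[2] == "temperature_K") as.numeric(m[3]) else m[3]
  }
  fields <- strsplit(trimws(body), "[ \t,]+")
  mat <- vapply(fields, function(f) as.numeric(f[1:2]), numeric(2))
  steady_spectrum(mat[1, ], mat[2, ], kind = meta$kind,
                  temperature_K = meta$temperature_K, label = meta$label)
}

#' Write a spectrum to a two-column text file
#'
#' @param spec a [steady_spectrum()].
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", spec$kind),
               sprintf("# temperature_K: %s", format(spec$temperature_K)),
               sprintf("# label: %s", spec$label)), con)
  utils::write.table(
    data.frame(format(spec$wavelengths_nm, trim = TRUE, digits = 15),
               format(spec$values, trim = TRUE, digits = 15)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a vacuum wavelength to a wavenumber
#'
#' @param lambda_nm wavelength(s) in nm; must be positive.
#' @return Wavenumber(s) in reciprocal centimetres (1e7 / lambda). Rounding
#'   to integer wavenumbers is left to the caller.
#' @examples
#' round(nm_to_wavenumber(715.6))  # 13974
#' @export
nm_to_wavenumber <- function(lambda_nm) {
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0))
    stop("wavelength must be positive")
  1e7 / lambda_nm
}

#' Convert a wavenumber to a vacuum wavelength
#'
#' @param nu_cm1 wavenumber(s) in cm^-1; must be positive.
#' @return Wavelength(s) in nm.
#' @export
wavenumber_to_nm <- function(nu_cm1) {
  if (any(!is.finite(nu_cm1)) || any(nu_cm1 <= 0))
    stop("wavenumber must be positive")
  1e7 / nu_cm1
}

# trapezoidal integral of a spectrum over a wavelength window
spectrum_area <- function(spec, window = range(spec$wavelengths_nm)) {
  w <- spec$wavelengths_nm
  if (window[1] < min(w) || window[2] > max(w))
    stop("window [", window[1], ", ", window[2], "] outside spectral grid")
  grid <- sort(unique(c(window, w[w >= window[1] & w <= window[2]])))
  v <- stats::approx(w, spec$values, xout = grid)$y
  pracma::trapz(grid, v)
}

#' Normalize a spectrum to its chlorophyll content in the Qy region
#'
#' Rescales the spectrum so that its trapezoidal area over the Qy window
#' equals the oscillator-strength-weighted chlorophyll content of the
#' complex, sum over pigments of count_p x weight_p. This puts spectra of
#' complexes with different pigment stoichiometries on a common
#' per-complex absorption scale.
#'
#' @param spec a [steady_spectrum()].
#' @param stoich a [stoichiometry()] (or a named numeric vector of counts).
#' @param osc named numeric vector of relative oscillator strengths per
#'   pigment (e.g. `c(chl_a = 1, chl_b = 0.67, chl_d = 1.20, chl_f = 1.34)`).
#'   Pigments absent from `osc` get weight 0.
#' @param window Qy integration window in nm, default `c(630, 800)`.
#' @return The rescaled spectrum (shape unchanged up to a scalar).
#' @export
normalize_qy_area <- function(spec, stoich, osc, window = c(630, 800)) {
  counts <- if (inherits(stoich, "stoichiometry")) stoich$counts else stoich
  if (!length(counts) || all(counts <= 0)) stop("stoichiometry totals must be positive")
  w <- osc[names(counts)]
  w[is.na(w)] <- 0
  target <- sum(counts * w)
  a <- spectrum_area(spec, window)
  if (a <= 0) stop("non-positive area over the Qy window")
  out <- spec
  out$values <- spec$values * target / a
  out
}

#' Difference of two spectra on a common grid
#'
#' Interpolates `b` linearly onto `a`'s grid and subtracts over the grid
#' overlap. Intended for area-normalized spectra (e.g. wild type minus
#' red-form-less mutant difference absorption).
#'
#' @param a,b [steady_spectrum()] objects with overlapping grids.
#' @return A [steady_spectrum()] equal to `a - b` on the overlap.
#' @export
difference_spectrum <- function(a, b) {
  lo <- max(min(a$wavelengths_nm), min(b$wavelengths_nm))
  hi <- min(max(a$wavelengths_nm), max(b$wavelengths_nm))
  keep <- a$wavelengths_nm >= lo & a$wavelengths_nm <= hi
  if (sum(keep) < 3L) stop("spectral grids do not overlap")
  g <- a$wavelengths_nm[keep]
  bi <- stats::approx(b$wavelengths_nm, b$values, xout = g)$y
  steady_spectrum(g, a$values[keep] - bi, kind = a$kind,
                  temperature_K = a$temperature_K,
                  label = trimws(paste(a$label, "-", b$label)))
}

#' Estimate the 0-0 transition from the absorption/emission crossing
#'
#' Both spectra are normalized to unit maximum; the 0-0 (zero-phonon)
#' transition wavelength is estimated as the crossing point of the two
#' normalized curves between the absorption maximum and the emission
#' maximum, located by linear interpolation between the grid points
#' bracketing the sign change of (absorption - emission).
#'
#' @param absorption,emission [steady_spectrum()] objects. The absorption
#'   maximum must lie to the blue of the emission maximum.
#' @return A list of class `transition_estimate` with `lambda00_nm`,
#'   `energy00_cm1` and `method`.
#' @export
estimate_00_transition <- function(absorption, emission) {
  lo <- max(min(absorption$wavelengths_nm), min(emission$wavelengths_nm))
  hi <- min(max(absorption$wavelengths_nm), max(emission$wavelengths_nm))
  if (lo >= hi) stop("spectral grids do not overlap")
  grid <- sort(unique(c(absorption$wavelengths_nm, emission$wavelengths_nm)))
  grid <- grid[grid >= lo & grid <= hi]
  av <- stats::approx(absorption$wavelengths_nm,
                      absorption$values / max(absorption$values), grid)$y
  ev <- stats::approx(emission$wavelengths_nm,
                      emission$values / max(emission$values), grid)$y
  amax <- grid[which.max(av)]
  emax <- grid[which.max(ev)]
  if (amax >= emax)
    stop("absorption maximum must be blue of the emission maximum")
  sel <- grid >= amax & grid <= emax
  g <- grid[sel]
  d <- av[sel] - ev[sel]
  s <- sign(d)
  flips <- which(s[-1] * s[-length(s)] < 0 | (s[-length(s)] != 0 & s[-1] == 0))
  exact <- which(d == 0)
  if (!length(flips) && !length(exact))
    stop("no crossing between the absorption and emission maxima")
  crossings <- numeric(0)
  if (length(flips)) {
    i <- flips
    crossings <- g[i] - d[i] * (g[i + 1] - g[i]) / (d[i + 1] - d[i])
  }
  crossings <- sort(unique(c(crossings, g[exact])))
  if (length(crossings) > 1L)
    warning("multiple crossings; returning the bluest")
  lambda00 <- crossings[1]
  structure(list(lambda00_nm = lambda00,
                 energy00_cm1 = nm_to_wavenumber(lambda00),
                 method = "abs-emi intersection"),
            class = "transition_estimate")
}

#' Stokes shift between absorption and emission maxima
#'
#' @param abs_max_nm absorption maximum, nm.
#' @param emi_max_nm emission maximum, nm; must not be blue of the
#'   absorption maximum.
#' @return Shift in nm (`emi_max_nm - abs_max_nm`).
#' @export
stokes_shift <- function(abs_max_nm, emi_max_nm) {
  if (emi_max_nm < abs_max_nm)
    stop("emission maximum is blue of the absorption maximum")
  emi_max_nm - abs_max_nm
}

#' Boltzmann constant in spectroscopic units
#'
#' kB = 0.6950 cm^-1 K^-1.
#' @export
KB_CM1_PER_K <- 0.6950

#' Energy gap in units of the thermal energy kBT
#'
#' @param e1_cm1,e2_cm1 transition energies in cm^-1.
#' @param temperature_K temperature in K (default 298, room temperature).
#' @return `|e1 - e2| / (0.6950 * T)`, dimensionless.
#' @examples
#' thermal_gap(13974, 13920, 298)  # ~0.26
#' @export
thermal_gap <- function(e1_cm1, e2_cm1, temperature_K = 298) {
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature must be positive")
  abs(e1_cm1 - e2_cm1) / (KB_CM1_PER_K * temperature_K)
}

#' Excitation density of a pump-probe measurement
#'
#' Fraction of chlorophylls excited per pulse, estimated as
#' N_Chl x 1/2 x dOD_max / OD_max. Values below ~6% indicate that
#' singlet-singlet annihilation is negligible.
#'
#' @param n_chl number of chlorophylls per monomer (12 for Lhca4).
#' @param delta_od_max maximum pump-induced absorption change (>= 0).
#' @param od_max ground-state optical density at the pump wavelength (> 0).
#' @return Excitation density as a fraction.
#' @export
excitation_density <- function(n_chl, delta_od_max, od_max) {
  if (!is.finite(od_max) || od_max <= 0) stop("od_max must be positive")
  if (delta_od_max < 0) stop("delta_od_max must be non-negative")
  if (n_chl <= 0 || n_chl != round(n_chl)) stop("n_chl must be a positive integer")
  n_chl * 0.5 * delta_od_max / od_max
}
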