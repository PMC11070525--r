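#' Spectral curves on a 1-nm wavelength grid
#'
#' All photophysical inputs of a polychromatic photokinetic calculation --
#' absorptivity spectra \eqn{\epsilon(\lambda)} (M\eqn{^{-1}}cm\eqn{^{-1}}),
#' quantum-yield profiles \eqn{\Phi(\lambda)} (dimensionless, at most 1) and
#' lamp emission profiles \eqn{P_0(\lambda)} (einstein s\eqn{^{-1}} dm\eqn{^{-3}}
#' per 1-nm step) -- are represented as values on a shared, contiguous,
#' integer 1-nm wavelength grid.  Because lamp values are photon counts per
#' grid step, wavelength integrals reduce to plain sums over the grid.
#'
#' @param wavelength integer vector of wavelengths in nm; must be contiguous
#'   with a 1-nm step and contain at least two points.
#' @param value non-negative numeric vector, one value per wavelength.
#' @param kind what the curve represents; quantum-yield curves must not
#'   exceed 1.
#' @return an object of class `spectral_curve`.
#' @examples
#' eps <- spectral_curve(300:400, rep(1e4, 101), "absorptivity")
#' @export
spectral_curve <- function(wavelength, value,
                           kind = c("absorptivity", "quantum_yield",
                                    "lamp_intensity")) {
  kind <- match.arg(kind)
  wavelength <- as.integer(round(wavelength))
  value <- as.numeric(value)
  if (length(wavelength) < 2L)
    stop("a spectral curve needs at least two grid points")
  if (any(diff(wavelength) != 1L))
    stop("wavelengths must form a contiguous 1-nm grid")
  if (length(value) != length(wavelength))
    stop("'value' must have one entry per wavelength")
  if (anyNA(value) || any(value < 0))
    stop("spectral values must be finite and non-negative")
  if (kind == "quantum_yield" && any(value > 1 + 1e-12))
    stop("quantum-yield values must not exceed 1")
  structure(list(wavelength = wavelength, value = value, kind = kind),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve: %s, %d-%d nm, max %.4g>\n",
              x$kind, min(x$wavelength), max(x$wavelength), max(x$value)))
  invisible(x)
}

# shared-grid guard used by every multi-curve operation
check_same_grid <- function(...) {
  curves <- list(...)
  ref <- curves[[1L]]$wavelength
  for (cv in curves[-1L]) {
    if (length(cv$wavelength) != length(ref) || any(cv$wavelength != ref))
      stop("all spectral curves in one computation must share one grid")
  }
  invisible(ref)
}

grid_index <- function(curve, lam) {
  i <- match(as.integer(round(lam)), curve$wavelength)
  if (is.na(i))
    stop(sprintf("wavelength %s nm is off the grid (%d-%d nm)",
                 format(lam), min(curve$wavelength), max(curve$wavelength)))
  i
}

#' Gaussian absorption/emission band
#'
#' Gaussian band on the grid, truncated to exactly zero below a stated
#' fraction of the peak so that the curve has compact support and spectral
#' overlap windows (OSIA) are sharply defined.
#'
#' @param grid integer wavelength vector (1-nm step).
#' @param center,fwhm band centre and full width at half maximum, nm.
#' @param peak peak value in the curve's units.
#' @param kind curve kind, see [spectral_curve()].
#' @param floor_frac values below `floor_frac * peak` are set to zero.
#' @export
sc_gaussian <- function(grid, center, fwhm, peak, kind = "absorptivity",
                        floor_frac = 1e-4) {
  if (center < min(grid) || center > max(grid))
    stop(sprintf("band centre %g nm lies outside the grid", center))
  v <- peak * exp(-4 * log(2) * ((grid - center) / fwhm)^2)
  v[v < floor_frac * peak] <- 0
  spectral_curve(grid, v, kind)
}

#' Constant spectral curve
#' @param grid integer wavelength vector.
#' @param value the constant value.
#' @param kind curve kind.
#' @export
sc_constant <- function(grid, value, kind = "quantum_yield") {
  spectral_curve(grid, rep(value, length(grid)), kind)
}

#' Sigmoid (logistic) quantum-yield profile
#'
#' Smooth plateau-to-zero transition, the shape used for wavelength-dependent
#' quantum yields: `plateau / (1 + exp(sign * (grid - center) / width))`.
#'
#' @param grid integer wavelength vector.
#' @param plateau plateau value (dimensionless, at most 1).
#' @param center,width transition centre (nm) and width (nm).
#' @param falling if `TRUE` (default) the profile falls with wavelength.
#' @param kind curve kind.
#' @export
sc_sigmoid <- function(grid, plateau, center, width, falling = TRUE,
                       kind = "quantum_yield") {
  s <- if (falling) 1 else -1
  v <- plateau / (1 + exp(s * (grid - center) / width))
  spectral_curve(grid, v, kind)
}

#' LED-like lamp profile
#'
#' Gaussian emission band truncated at the grid and rescaled so the summed
#' photon count equals `total` (einstein s^-1 dm^-3).  Equal-`total` LED
#' series therefore deliver the same photon budget.
#'
#' @param grid integer wavelength vector.
#' @param center,fwhm emission centre and FWHM, nm.
#' @param total total photon count over the grid.
#' @export
sc_led <- function(grid, center, fwhm, total) {
  v <- exp(-4 * log(2) * ((grid - center) / fwhm)^2)
  v[v < 1e-4] <- 0
  if (sum(v) == 0) stop("LED band has no support on the grid")
  spectral_curve(grid, v * total / sum(v), "lamp_intensity")
}

#' Flat ("hypothetical") lamp
#'
#' Delivers the same number of photons at each wavelength of its support,
#' the construction used to make the per-wavelength reactivity profile
#' independent of the source.
#'
#' @param grid integer wavelength vector.
#' @param from,to support interval, nm.
#' @param total total photon count over the support.
#' @export
sc_flat_lamp <- function(grid, from = min(grid), to = max(grid), total) {
  sel <- grid >= from & grid <= to
  if (!any(sel)) stop("flat-lamp support does not intersect the grid")
  v <- numeric(length(grid))
  v[sel] <- total / sum(sel)
  spectral_curve(grid, v, "lamp_intensity")
}

#' Rescale a lamp's intensity
#' @param lamp a lamp `spectral_curve`.
#' @param factor non-negative multiplier.
#' @export
scale_lamp <- function(lamp, factor) {
  spectral_curve(lamp$wavelength, lamp$value * factor, "lamp_intensity")
}

#' Total photons delivered by a lamp
#'
#' Sum of the per-wavelength photon counts, optionally restricted to an
#' interval (e.g. an OSIA window).
#'
#' @param lamp a lamp `spectral_curve`.
#' @param interval optional `c(from, to)` nm restriction.
#' @return einstein s^-1 dm^-3.
#' @export
lamp_total <- function(lamp, interval = NULL) {
  v <- lamp$value
  if (!is.null(interval)) {
    sel <- lamp$wavelength >= interval[1] & lamp$wavelength <= interval[2]
    v <- v[sel]
  }
  sum(v)
}

#' Photokinetic factor
#'
#' The dimensionless shape factor of the absorbed-light term,
#' \eqn{(1 - 10^{-A})/A}.  For total absorbances below 1e-6 the analytic
#' series \eqn{\ln 10\,(1 - A\ln 10/2 + (A \ln 10)^2/6)} is used to avoid
#' the 0/0 cancellation; the two branches agree to better than 1e-12
#' relative at the switch.  The factor is continuous, equals \eqn{\ln 10}
#' at \eqn{A = 0}, and decreases strictly with \eqn{A}.
#'
#' @param a_tot non-negative total absorbance (vectorised).
#' @return dimensionless factor, same length as `a_tot`.
#' @export
pkf <- function(a_tot) {
  if (anyNA(a_tot) || any(a_tot < 0))
    stop("total absorbance must be non-negative")
  out <- numeric(length(a_tot))
  L <- log(10)
  small <- a_tot < 1e-6
  if (any(small)) {
    a <- a_tot[small]
    out[small] <- L * (1 - a * L / 2 + (a * L)^2 / 6)
  }
  if (any(!small)) {
    a <- a_tot[!small]
    out[!small] <- -expm1(-a * L) / a  # 1 - 10^-a without cancellation
  }
  out
}

#' Total absorbance of the medium
#'
#' Beer-Lambert sum over the absorbing species plus the constant
#' spectator-molecule (SPM) absorbance:
#' \eqn{A_{tot}(\lambda) = \sum_j \epsilon_j(\lambda)\, l\, C_j + A_{SPM}(\lambda)}.
#'
#' @param epsilons list of absorptivity curves, one per species.
#' @param conc molar concentrations, one per species.
#' @param path optical path length, cm.
#' @param lam single wavelength (nm) at which to evaluate, or `NULL` for the
#'   full grid.
#' @param spm optional spectator absorbance curve (dimensionless), or `NULL`.
#' @return absorbance (scalar for a single `lam`, else vector on the grid).
#' @export
total_absorbance <- function(epsilons, conc, path, lam = NULL, spm = NULL) {
  if (length(conc) != length(epsilons))
    stop("one concentration per species is required")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  args <- epsilons
  if (!is.null(spm)) args <- c(args, list(spm))
  do.call(check_same_grid, args)
  a <- numeric(length(epsilons[[1L]]$wavelength))
  for (j in seq_along(epsilons))
    a <- a + epsilons[[j]]$value * path * conc[j]
  if (!is.null(spm)) a <- a + spm$value
  if (is.null(lam)) return(a)
  a[grid_index(epsilons[[1L]], lam)]
}

#' Light absorbed by one species
#'
#' Per-wavelength photon flux absorbed specifically by species `j` among all
#' absorbers in the medium,
#' \eqn{P_a^{Y_j}(\lambda) = A_{Y_j}(\lambda)\, P_0(\lambda)\, PKF(A_{tot}(\lambda))}.
#' The fluxes of all species plus the spectator share sum exactly to
#' \eqn{P_0 (1 - 10^{-A_{tot}})} (photon bookkeeping).
#'
#' @param j species index (1 = reactant X).
#' @param epsilons list of absorptivity curves.
#' @param conc molar concentrations.
#' @param path irradiation path length, cm.
#' @param lamp lamp curve.
#' @param lam single wavelength (nm), or `NULL` for the full grid.
#' @param spm optional spectator absorbance curve.
#' @return einstein s^-1 dm^-3 absorbed by species `j`.
#' @export
absorbed_fraction <- function(j, epsilons, conc, path, lamp, lam = NULL,
                              spm = NULL) {
  check_same_grid(epsilons[[1L]], lamp)
  atot <- total_absorbance(epsilons, conc, path, lam = NULL, spm = spm)
  aj <- epsilons[[j]]$value * path * conc[j]
  pa <- aj * lamp$value * pkf(atot)
  if (is.null(lam)) return(pa)
  pa[grid_index(lamp, lam)]
}

#' Overlap section of irradiation and absorption (OSIA)
#'
#' The set of grid wavelengths where both the lamp emission and the species
#' absorptivity exceed a threshold (default 0, i.e. strictly positive
#' support), reported as contiguous interval(s).
#'
#' @param lamp lamp curve.
#' @param epsilon absorptivity curve (same grid).
#' @param threshold values must exceed this to count as overlapping.
#' @return list with `wavelengths` (integer vector, possibly empty) and
#'   `intervals` (two-column matrix of interval endpoints, nm).  An empty
#'   overlap is returned (with a warning), not an error.
#' @export
compute_osia <- function(lamp, epsilon, threshold = 0) {
  check_same_grid(lamp, epsilon)
  sel <- lamp$value > threshold & epsilon$value > threshold
  wl <- lamp$wavelength[sel]
  if (length(wl) == 0L) {
    warning("lamp emission and species absorption do not overlap: empty OSIA")
    return(list(wavelengths = integer(0),
                intervals = matrix(numeric(0), ncol = 2,
                                   dimnames = list(NULL, c("from", "to")))))
  }
  brk <- c(0L, which(diff(wl) > 1L), length(wl))
  ints <- t(vapply(seq_len(length(brk) - 1L), function(i) {
    seg <- wl[(brk[i] + 1L):brk[i + 1L]]
    c(from = min(seg), to = max(seg))
  }, numeric(2)))
  list(wavelengths = wl, intervals = ints)
}
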