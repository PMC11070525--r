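#' Standardize an actinometer against a lamp
#'
#' The kinactinometric calibration protocol: irradiate the actinometer
#' system at several intensities of the same lamp, fit each trace with the
#' Phi-order model, extract the initial rates, and regress them through the
#' origin on the delivered photon counts,
#' \eqn{r_{0}^{(i)} = \alpha\, P_0^{(i)}}.  The slope \eqn{\alpha} is
#' dimensionless and carries the sign of the initial rate.
#'
#' Photon counts can be booked over the full lamp emission
#' (`range = "full"`, tag `dl_plus`) or over the lamp/actinometer OSIA only
#' (`range = "osia"`, tag `dl`); the two slopes differ by the factor
#' \eqn{1 + \beta} (see [beta_factor()], [rescale_alpha()]).  Every slope is
#' tagged with its lamp and range, and downstream operations refuse to mix
#' tags: a calibration is specific to its lamp, range and actinometer.
#'
#' The relative disposition of the lamp span, the actinometer OSIA and (if
#' given) the OSIA of a separately investigated species is classified as
#' `sit1` (lamp wider than the actinometer's OSIA: photons counted but
#' unused), `sit2` (all counted photons serve the reaction) or `sit3`
#' (species absorbs beyond the actinometer's OSIA: absorbed photons
#' under-counted, warned about).
#'
#' @param system the actinometer [photo_system()].
#' @param p0_scales at least three multipliers applied to the lamp.
#' @param range `"full"` or `"osia"` photon-counting range.
#' @param what trace used for the rates: `"A"` (total absorbance, default)
#'   or a species label.
#' @param species_epsilon optional absorptivity curve of an investigated
#'   species, for the situation classification.
#' @param dt,t_end optional shared integration settings.
#' @param n_terms,n_starts,seed fitting settings.
#' @param r2_min minimum through-origin r-squared; a calibration below it
#'   signals a broken linearity assumption and is an error.
#' @return object of class `calibration_line`: `alpha`, `r_squared`,
#'   `points` (data.frame of `p0`, `r0`), `lamp_tag`, `range_tag`,
#'   `range_nm`, `osia`, `beta`, `situation`.
#' @export
standardize_actinometer <- function(system, p0_scales = c(0.5, 1, 1.5, 2),
                                    range = c("full", "osia"), what = "A",
                                    species_epsilon = NULL,
                                    dt = NULL, t_end = NULL, n_terms = 2L,
                                    n_starts = 20L, seed = 1234L,
                                    r2_min = 0.999) {
  range <- match.arg(range)
  if (length(p0_scales) < 3L)
    stop("at least three intensity levels are required")
  osia <- system_osia(system)
  if (!length(osia$wavelengths))
    stop("lamp and actinometer do not overlap: nothing to standardize")
  osia_int <- c(min(osia$wavelengths), max(osia$wavelengths))
  support <- range(system$lamp$wavelength[system$lamp$value > 0])
  range_nm <- if (range == "osia") osia_int else support
  range_tag <- if (range == "osia") "dl" else "dl_plus"

  pts <- lapply(p0_scales, function(sc) {
    sys_i <- with_lamp(system, scale_lamp(system$lamp, sc))
    tr <- simulate_kinetics(sys_i, dt = dt, t_end = t_end,
                            warn_absorbance = Inf)
    y <- if (identical(what, "A")) absorbance_trace(tr) else tr$conc[, what]
    fit <- fit_phi_order(tr$times, y, n_terms, n_starts, seed,
                         target = if (identical(what, "A")) "absorbance"
                                  else "concentration")
    p0 <- if (range == "osia") lamp_total(sys_i$lamp, osia_int)
          else lamp_total(sys_i$lamp)
    data.frame(p0 = p0, r0 = fit$r0)
  })
  pts <- do.call(rbind, pts)

  alpha <- sum(pts$p0 * pts$r0) / sum(pts$p0^2)
  r2 <- sum(pts$p0 * pts$r0)^2 / (sum(pts$p0^2) * sum(pts$r0^2))
  if (!is.finite(alpha) || alpha == 0)
    stop("calibration slope is zero: the actinometer does not respond")
  if (r2 < r2_min)
    stop(sprintf(
      "calibration is not linear (r2 = %.6f < %g): check that the medium stays in its linearity range",
      r2, r2_min))

  beta <- beta_factor(system$lamp, osia_int)$beta
  situation <- classify_situation(support, osia_int, species_epsilon,
                                  system$lamp)
  if (identical(situation, "sit3"))
    warning("sit3: the species absorbs beyond the actinometer's OSIA; counted photons under-represent the photons the species absorbs")
  structure(list(alpha = alpha, r_squared = r2, points = pts,
                 lamp_tag = system$lamp_tag, range_tag = range_tag,
                 range_nm = range_nm, osia = osia_int, beta = beta,
                 situation = situation),
            class = "calibration_line")
}

classify_situation <- function(lamp_support, osia_act, species_epsilon,
                               lamp) {
  if (is.null(species_epsilon)) {
    if (lamp_support[1L] < osia_act[1L] || lamp_support[2L] > osia_act[2L])
      return("sit1")
    return("sit2")
  }
  osia_sp <- compute_osia(lamp, species_epsilon)
  if (!length(osia_sp$wavelengths)) return("sit1")
  sp <- c(min(osia_sp$wavelengths), max(osia_sp$wavelengths))
  if (sp[1L] < osia_act[1L] || sp[2L] > osia_act[2L]) return("sit3")
  if (osia_act[1L] < sp[1L] || osia_act[2L] > sp[2L] ||
      lamp_support[1L] < osia_act[1L] || lamp_support[2L] > osia_act[2L])
    return("sit1")
  "sit2"
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(
    "<calibration_line: alpha = %.5g [%s, %s %d-%d nm], r2 = %.6f, beta = %.4g, %s>\n",
    x$alpha, x$lamp_tag, x$range_tag, x$range_nm[1L], x$range_nm[2L],
    x$r_squared, x$beta, x$situation))
  invisible(x)
}

#' Out-of-OSIA photon ratio of a lamp
#'
#' \eqn{\beta = \sum_{\lambda \notin OSIA} P_0(\lambda) \big/
#' \sum_{\lambda \in OSIA} P_0(\lambda)}: the constant, intensity-invariant
#' ratio of counted-but-unused photons to photons available to the
#' reaction.  Zero exactly when the lamp emits only inside the OSIA.
#'
#' @param lamp lamp curve.
#' @param osia OSIA interval `c(from, to)` in nm, or a [compute_osia()]
#'   result.
#' @return list with `beta`, `p0_in`, `p0_out`.
#' @export
beta_factor <- function(lamp, osia) {
  if (is.list(osia)) {
    if (!length(osia$wavelengths)) stop("empty OSIA: no in-range photons")
    sel <- lamp$wavelength %in% osia$wavelengths
  } else {
    sel <- lamp$wavelength >= osia[1L] & lamp$wavelength <= osia[2L]
  }
  p_in <- sum(lamp$value[sel])
  p_out <- sum(lamp$value[!sel])
  if (p_in == 0) stop("lamp delivers no photons inside the OSIA")
  list(beta = p_out / p_in, p0_in = p_in, p0_out = p_out)
}

#' Convert a calibration slope between photon-counting ranges
#'
#' \eqn{\alpha^{\Delta\lambda} = \alpha^{\Delta\lambda^+} (1 + \beta)}:
#' a slope booked against the full lamp output rescales to the OSIA-only
#' slope, and conversely (`inverse = TRUE` divides).
#'
#' @param alpha slope to convert.
#' @param beta out-of-OSIA photon ratio (non-negative).
#' @param inverse if `TRUE`, convert an OSIA-range slope to the full-range
#'   slope.
#' @return converted slope.
#' @export
rescale_alpha <- function(alpha, beta, inverse = FALSE) {
  if (beta < 0) stop("'beta' must be non-negative")
  if (inverse) alpha / (1 + beta) else alpha * (1 + beta)
}

#' Invert a calibration line to price an unknown intensity
#'
#' \eqn{P_0^{unk} = r_0^{unk} / \alpha}.  The initial rate must have been
#' measured under the same lamp and booked over the same wavelength range
#' as the calibration: a line standardized for one lamp cannot price
#' another, so mismatched tags are an error, not a warning.
#'
#' @param r0 initial rate of the unknown-intensity trace (fit-derived).
#' @param line a `calibration_line`.
#' @param lamp_tag,range_tag tags under which `r0` was acquired.
#' @return unknown intensity, einstein s^-1 dm^-3.
#' @export
unknown_intensity <- function(r0, line, lamp_tag, range_tag) {
  if (!inherits(line, "calibration_line"))
    stop("'line' must be a calibration_line")
  if (!identical(lamp_tag, line$lamp_tag))
    stop(sprintf(
      "lamp tag mismatch: rate from '%s', line standardized for '%s'",
      lamp_tag, line$lamp_tag))
  if (!identical(range_tag, line$range_tag))
    stop(sprintf(
      "range tag mismatch: rate booked over '%s', line over '%s'",
      range_tag, line$range_tag))
  r0 / line$alpha
}

#' Photonic yield
#'
#' Converted amount referred to the photons *incident* on the reactor over
#' the booking range, \eqn{PHYD = (C_0 - C(t)) / (P_0\, t)} for the
#' reactant or \eqn{C_{end}(t) / (P_0\, t)} for an end product.  A relative,
#' time-dependent quantity; the photon-counting range (`dl` vs `dl_plus`)
#' must be stated and is stored with the value, and booking the larger
#' full-lamp count necessarily lowers the yield.
#'
#' @param c0 initial concentration of the followed species, M (0 for a
#'   product).
#' @param c_t its concentration at time `t`, M.
#' @param p0_total incident photon count over the booking range,
#'   einstein s^-1 dm^-3 (> 0).
#' @param t irradiation time, s (> 0).
#' @param species `"reactant"` (consumed amount) or `"product"` (formed
#'   amount).
#' @param range_tag photon-counting range of `p0_total`.
#' @return dimensionless yield, with attributes `range_tag` and `time`.
#' @export
photonic_yield <- function(c0, c_t, p0_total, t,
                           species = c("reactant", "product"),
                           range_tag = c("dl", "dl_plus")) {
  species <- match.arg(species)
  range_tag <- match.arg(range_tag)
  if (t <= 0) stop("'t' must be positive")
  if (p0_total <= 0) stop("'p0_total' must be positive")
  val <- if (species == "reactant") (c0 - c_t) / (p0_total * t)
         else c_t / (p0_total * t)
  structure(val, range_tag = range_tag, time = t)
}

#' Photonic efficiency PY
#'
#' Time-independent efficiency of a photoreaction under a given lamp and
#' conditions, \eqn{PY = -r_{0,X} / P_0} (the sign is dropped for an
#' absorbance-trace rate, which may be positive).  Across an intensity
#' scan, PY equals minus the calibration slope \eqn{\alpha}.
#'
#' @param r0 initial rate (reactant or absorbance trace).
#' @param p0_total incident photon count over the stated range (> 0).
#' @param range_tag photon-counting range of `p0_total`.
#' @return dimensionless efficiency with attribute `range_tag`.
#' @export
efficiency_py <- function(r0, p0_total, range_tag = c("dl", "dl_plus")) {
  range_tag <- match.arg(range_tag)
  if (p0_total <= 0) stop("'p0_total' must be positive")
  structure(abs(r0) / p0_total, range_tag = range_tag)
}

#' Quantum yield of a single-step depletion from its fitted initial rate
#'
#' For a reactant that depletes by a single photostep with a
#' wavelength-invariant quantum yield,
#' \deqn{\Phi_{X\to Y_1} = \frac{-Fit\!:r_{0,X}}
#'   {\sum_\lambda P_0(\lambda)\,(1 - 10^{-\epsilon_X(\lambda) l C_{X,0}})}.}
#' The caller asserts the single-step, Phi-invariant premise; the result
#' records it.  A value above 1 (premise likely violated, e.g. the true
#' quantum yield varies with wavelength) triggers a warning.
#'
#' @param fit_r0_x fitted initial reactant rate (negative), M s^-1.
#' @param lamp lamp curve.
#' @param epsilon_x reactant absorptivity curve.
#' @param l_irr irradiation path length, cm.
#' @param c_x0 initial reactant concentration, M.
#' @return dimensionless quantum yield with attribute
#'   `assumes` = "single-step depletion, wavelength-invariant quantum yield".
#' @export
quantum_yield_single_step <- function(fit_r0_x, lamp, epsilon_x, l_irr,
                                      c_x0) {
  check_same_grid(lamp, epsilon_x)
  denom <- sum(lamp$value * (1 - 10^(-epsilon_x$value * l_irr * c_x0)))
  if (denom <= 0) stop("lamp and reactant absorption do not overlap")
  phi <- -fit_r0_x / denom
  if (phi > 1)
    warning(sprintf(
      "quantum yield %.3f exceeds 1: the single-step / wavelength-invariant assumption is likely violated",
      phi))
  structure(phi,
            assumes = "single-step depletion, wavelength-invariant quantum yield")
}

#' General quantum-yield expression for the primary step
#'
#' Calculation-only evaluation of the wavelength-invariant quantum yield of
#' the primary step X -> `to` by solving the full rate law for it at a
#' stated state: the observed reactant rate is corrected for the other
#' forward branches and for the reverse steps feeding X, each of which
#' requires the complete set of quantum-yield profiles and absorbed-light
#' terms -- which is why this expression cannot be evaluated from
#' experimental data alone.
#'
#' @param system a [photo_system()] whose mechanism carries the quantum
#'   yields of every step *other than* the target (the target step's own
#'   curve is ignored).
#' @param conc concentrations at the evaluation state.
#' @param rate_x reactant rate \eqn{dC_X/dt} at that state, M s^-1.
#' @param to species index of the target step's product (default 2 = Y1).
#' @return dimensionless quantum yield of the step X -> `to`.
#' @export
quantum_yield_general <- function(system, conc, rate_x, to = 2L) {
  mech <- system$mechanism
  target <- which(vapply(mech$steps, function(s)
    s$from == 1L && s$to == to, logical(1)))
  if (!length(target))
    stop(sprintf("mechanism has no step X -> %s", mech$labels[to]))
  pa <- lapply(seq_len(mech$n_species), function(j)
    absorbed_fraction(j, system$epsilons, conc, system$l_irr, system$lamp,
                      spm = system$spm))
  pa_x <- sum(pa[[1L]])
  if (pa_x <= 0) stop("the reactant absorbs no photons at this state")
  other_fwd <- 0; rev_in <- 0
  for (s in seq_along(mech$steps)) {
    st <- mech$steps[[s]]
    if (s %in% target) next
    if (st$from == 1L)
      other_fwd <- other_fwd + sum(st$phi$value * pa[[1L]])
    if (st$to == 1L)
      rev_in <- rev_in + sum(st$phi$value * pa[[st$from]])
  }
  (-rate_x - other_fwd + rev_in) / pa_x / length(target)
}
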