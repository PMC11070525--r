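#' Initial-concentration scan (auto-photostabilization study)
#'
#' Simulates and fits the system at a series of initial reactant
#' concentrations and reports, per concentration, the three initial-rate
#' routes for the reactant, the first photoproduct and the total-absorbance
#' trace, plus the fractional conversion reached at a common early
#' comparison time (one twentieth of the shared duration, while every run
#' is still evolving -- at long times conversions converge to their final
#' values and the slow-down becomes invisible).  All runs share one time
#' grid so conversions are comparable.
#'
#' The auto-photostabilization signature -- \eqn{|r_{0,X}|} strictly
#' increasing with \eqn{C_{X,0}} while the fractional conversion at fixed
#' time strictly decreases -- is flagged on the result.  The default
#' concentration grid is the canonical seven-point series used for this
#' study.
#'
#' @param system a [photo_system()]; its own `c0` is ignored.
#' @param c0_values concentration grid, M.
#' @param dt,t_end shared integration settings; defaults derived from the
#'   largest concentration (the slowest run).
#' @param n_terms,n_starts,seed fitting settings, see [fit_phi_order()].
#' @return data.frame (one row per concentration) with columns `c0`, the
#'   three initial-rate routes for the reactant (`r0_X_fit`, `r0_X_rk`,
#'   `r0_X_theo`) and the first photoproduct (`r0_Y1_*`), `r0_A_fit`,
#'   `conversion`, and the fit-route rate ratio `ratio_XY1`; attributes
#'   `auto_photostabilization` (logical), `t_end` and `conversion_time`.
#' @export
c0_scan <- function(system,
                    c0_values = c(1.3e-6, 1.3e-5, 3e-5, 5e-5, 7e-5, 9e-5,
                                  1e-4),
                    dt = NULL, t_end = NULL, n_terms = 2L, n_starts = 20L,
                    seed = 1234L) {
  if (any(c0_values <= 0)) stop("'c0_values' must be positive")
  sys_hi <- with_c0(system, max(c0_values))
  if (is.null(dt) || is.null(t_end)) {
    def <- default_settings(sys_hi)
    if (is.null(dt)) dt <- def$dt
    if (is.null(t_end)) t_end <- def$t_end
  }
  y1 <- system$mechanism$labels[2L]
  rows <- lapply(seq_along(c0_values), function(i) {
    c0 <- c0_values[i]
    tr <- tryCatch(
      simulate_kinetics(with_c0(system, c0), dt = dt, t_end = t_end,
                        warn_absorbance = Inf),
      error = function(e)
        stop(sprintf("simulation failed at c0 = %g M: %s", c0,
                     conditionMessage(e))))
    tx <- tryCatch(
      r0_triplet(tr, "X", n_terms, n_starts, seed),
      error = function(e)
        stop(sprintf("fit failed at c0 = %g M: %s", c0,
                     conditionMessage(e))))
    ty <- r0_triplet(tr, y1, n_terms, n_starts, seed)
    ta <- r0_triplet(tr, "A", n_terms, n_starts, seed)
    i_conv <- which.min(abs(tr$times - t_end / 20))
    data.frame(c0 = c0, r0_X_fit = tx$fit, r0_X_rk = tx$rk,
               r0_X_theo = tx$theo, r0_Y1_fit = ty$fit,
               r0_Y1_rk = ty$rk, r0_Y1_theo = ty$theo,
               r0_A_fit = ta$fit,
               conversion = (c0 - tr$conc[i_conv, "X"]) / c0,
               ratio_XY1 = tx$fit / ty$fit)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$c0)
  attr(out, "auto_photostabilization") <-
    all(diff(abs(out$r0_X_fit[ord])) > 0) &&
    all(diff(out$conversion[ord]) < 0)
  attr(out, "t_end") <- t_end
  attr(out, "conversion_time") <- t_end / 20
  out
}

with_c0 <- function(system, c_x0) {
  photo_system(system$mechanism, system$epsilons, system$lamp,
               c(c_x0, numeric(system$mechanism$n_species - 1L)),
               system$l_irr, system$l_obs, system$lambda_obs,
               system$spm, system$lamp_tag)
}

with_spm <- function(system, spm) {
  photo_system(system$mechanism, system$epsilons, system$lamp, system$c0,
               system$l_irr, system$l_obs, system$lambda_obs,
               spm, system$lamp_tag)
}

#' Spectator-molecule scan
#'
#' Scales a spectator (SPM) absorbance envelope through a series of levels
#' and reports, per level, the fitted initial rates of every photoproduct
#' and of the total-absorbance trace, together with their percent reduction
#' relative to the SPM-free baseline of the same system and settings.
#' Spectators compete for photons inside the OSIA, so every rate magnitude
#' shrinks as their absorbance grows; a spectator whose absorption overlaps
#' only one branch of a divergent mechanism suppresses that branch
#' selectively (chromatic orthogonality).
#'
#' @param system a [photo_system()] (any `spm` already present is replaced).
#' @param spm spectator absorbance envelope (dimensionless curve).
#' @param scales multipliers applied to `spm`; 0 is the baseline and is
#'   always computed.
#' @param dt,t_end shared integration settings (defaults from the
#'   baseline system).
#' @param n_terms,n_starts,seed fitting settings.
#' @return data.frame, one row per scale: `scale`, per-trace `r0_*` and
#'   `pct_reduction_*` columns for each photoproduct and for `A`.
#' @export
spm_scan <- function(system, spm, scales = c(0, 0.1, 0.2, 0.4, 0.8),
                     dt = NULL, t_end = NULL, n_terms = 2L, n_starts = 20L,
                     seed = 1234L) {
  scales <- sort(unique(c(0, scales)))
  base_sys <- with_spm(system, NULL)
  if (is.null(dt) || is.null(t_end)) {
    def <- default_settings(base_sys)
    if (is.null(dt)) dt <- def$dt
    if (is.null(t_end)) t_end <- def$t_end
  }
  products <- system$mechanism$labels[-1L]
  what <- c("X", products, "A")
  rows <- lapply(scales, function(sc) {
    spm_sc <- if (sc == 0) NULL else
      spectral_curve(spm$wavelength, spm$value * sc, spm$kind)
    tr <- simulate_kinetics(with_spm(system, spm_sc), dt = dt,
                            t_end = t_end, warn_absorbance = Inf)
    r0 <- vapply(what, function(w)
      r0_triplet(tr, w, n_terms, n_starts, seed)$fit, numeric(1))
    out <- data.frame(scale = sc)
    for (w in what) out[[paste0("r0_", w)]] <- r0[[w]]
    out
  })
  out <- do.call(rbind, rows)
  base <- out[out$scale == 0, , drop = FALSE]
  for (w in what)
    out[[paste0("pct_reduction_", w)]] <-
      100 * (1 - abs(out[[paste0("r0_", w)]]) /
               abs(base[[paste0("r0_", w)]]))
  out
}

#' Wavelength range of optimal reactivity (WROR) profile
#'
#' Per-wavelength reactivity score of the reactant,
#' \eqn{\epsilon_X(\lambda) \sum_{j'} \Phi_{X\to Y_{j'}}(\lambda)}, whose
#' profile the per-wavelength initial rate follows under an equal-photon
#' lamp.  The WROR window is the contiguous region around the global score
#' maximum where the score stays within `window_fraction` of the peak.
#' A region where the reactant absorbs but every forward quantum yield is
#' (near) zero is photokinetically inert and falls outside the window.
#'
#' @param epsilon_x reactant absorptivity curve.
#' @param phi_curves list of the reactant's forward-step quantum-yield
#'   curves.
#' @param window_fraction window threshold as a fraction of the peak score.
#' @return list with `wavelength`, `score` (M^-1 cm^-1), `window`
#'   (`c(from, to)` nm, or `NULL` when the score is identically zero) and
#'   `peak` (argmax wavelength, `NA` when empty).
#' @export
wror_profile <- function(epsilon_x, phi_curves, window_fraction = 0.95) {
  do.call(check_same_grid, c(list(epsilon_x), phi_curves))
  phi_sum <- Reduce(`+`, lapply(phi_curves, `[[`, "value"))
  score <- epsilon_x$value * phi_sum
  wl <- epsilon_x$wavelength
  if (max(score) == 0) {
    message("no photokinetically active region: score is identically zero")
    return(list(wavelength = wl, score = score, window = NULL, peak = NA))
  }
  imax <- which.max(score)
  ok <- score >= window_fraction * score[imax]
  lo <- imax; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- imax; while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  list(wavelength = wl, score = score, window = c(wl[lo], wl[hi]),
       peak = wl[imax])
}

#' LED scan: empirical WROR determination
#'
#' Replaces the system's lamp by a series of LED-like Gaussian bands of
#' equal photon budget, simulates and fits each irradiation, and reports
#' the initial-rate triplet per LED.  The LED whose centre maximizes
#' \eqn{|r_{0,X}|} estimates the WROR centre empirically; the recorded
#' absorbance traces demonstrate how the trace shape changes with the lamp.
#'
#' @param system a [photo_system()].
#' @param centers LED centre wavelengths, nm.
#' @param fwhm LED FWHM, nm.
#' @param photon_budget common total photon count per LED; default: the
#'   system lamp's total.
#' @param dt,t_end optional shared integration settings; by default each
#'   LED run uses its own [default_settings()].
#' @param n_terms,n_starts,seed fitting settings.
#' @return data.frame, one row per LED: `center`, `r0_X_fit`, `r0_X_rk`,
#'   `r0_X_theo`, `r0_Y1_fit`, `r0_A_fit`; attributes `best_center` and
#'   `absorbance_traces` (list of `data.frame(time, a_tot)`).
#' @export
led_scan <- function(system, centers, fwhm = 20,
                     photon_budget = lamp_total(system$lamp),
                     dt = NULL, t_end = NULL,
                     n_terms = 2L, n_starts = 20L, seed = 1234L) {
  grid <- system$lamp$wavelength
  y1 <- system$mechanism$labels[2L]
  traces <- vector("list", length(centers))
  rows <- lapply(seq_along(centers), function(i) {
    led <- sc_led(grid, centers[i], fwhm, photon_budget)
    sys_i <- with_lamp(system, led,
                       lamp_tag = sprintf("LED%03d", round(centers[i])))
    r0 <- rate_vector(sys_i)
    if (max(abs(r0)) == 0) {
      traces[[i]] <<- data.frame(time = c(0, 1),
                                 a_tot = rep(absorbance_at0(sys_i), 2))
      return(data.frame(center = centers[i], r0_X_fit = 0, r0_X_rk = 0,
                        r0_X_theo = 0, r0_Y1_fit = 0, r0_A_fit = 0))
    }
    tr <- simulate_kinetics(sys_i, dt = dt, t_end = t_end,
                            warn_absorbance = Inf)
    traces[[i]] <<- data.frame(time = tr$times, a_tot = absorbance_trace(tr))
    tx <- r0_triplet(tr, "X", n_terms, n_starts, seed)
    data.frame(center = centers[i], r0_X_fit = tx$fit, r0_X_rk = tx$rk,
               r0_X_theo = tx$theo,
               r0_Y1_fit = r0_triplet(tr, y1, n_terms, n_starts, seed)$fit,
               r0_A_fit = r0_triplet(tr, "A", n_terms, n_starts, seed)$fit)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_center") <- out$center[which.max(abs(out$r0_X_fit))]
  attr(out, "absorbance_traces") <- traces
  out
}

absorbance_at0 <- function(system) {
  total_absorbance(system$epsilons, system$c0, system$l_obs,
                   lam = system$lambda_obs, spm = system$spm)
}

#' Photostationary / final-state concentration ratios
#'
#' Pairwise ratios of the final concentrations of a trace that has reached
#' stationarity.  Stationarity requires the terminal rates to satisfy
#' \eqn{|dC_j/dt| \cdot t_{end} / C_{X,0} <} `tol` for every species;
#' otherwise an error reports the residual relative slope.  Species driven
#' to (numerically) zero make the ratio infinite, which is reported as full
#' conversion rather than an error.
#'
#' @param trace a `kinetic_trace`.
#' @param tol stationarity tolerance (relative residual change over the
#'   trace duration).
#' @return list with `ratios` (matrix, `ratios[i, j]` = \eqn{C_i/C_j} at the
#'   end state), `final` (named concentrations) and `full_conversion`
#'   (labels of species at zero).
#' @export
pss_ratios <- function(trace, tol = 1e-6) {
  sys <- trace$system
  final <- trace$conc[nrow(trace$conc), ]
  r_end <- rate_vector(sys, final)
  c_ref <- max(sum(trace$conc[1L, ]), max(final))
  resid <- max(abs(r_end)) * max(trace$times) / c_ref
  if (resid > tol)
    stop(sprintf(
      "trace not stationary: residual relative slope %.3g exceeds %.3g",
      resid, tol))
  n <- length(final)
  ratios <- outer(final, final, function(a, b) ifelse(b > 0, a / b, Inf))
  diag(ratios) <- 1
  dimnames(ratios) <- list(names(final), names(final))
  zero <- names(final)[final <= c_ref * 1e-12]
  list(ratios = ratios, final = final, full_conversion = zero)
}
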