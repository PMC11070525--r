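#' Default integration settings for a system
#'
#' The step size is chosen so the reactant changes by at most a fraction
#' `dc_frac` (default 1e-3) of its initial concentration per step at `t = 0`,
#' and the duration covers `n_tau` initial-rate time constants
#' \eqn{C_{X,0}/|r_{0,X}|} -- long enough for most systems to approach their
#' final state.  Both can be overridden.
#'
#' @param system a [photo_system()].
#' @param dc_frac maximum fractional reactant change per step at `t = 0`.
#' @param n_tau trace duration in units of the initial time constant.
#' @return list with `dt` (s) and `t_end` (s).
#' @export
default_settings <- function(system, dc_frac = 1e-3, n_tau = 6) {
  r0 <- rate_vector(system)
  rmax <- max(abs(r0))
  if (rmax == 0) return(list(dt = 1, t_end = 100))
  cx <- if (system$c0[1L] > 0) system$c0[1L] else max(system$c0)
  tau <- cx / rmax
  list(dt = dc_frac * tau, t_end = n_tau * tau)
}

#' Integrate the rate law into a kinetic trace
#'
#' Classic fixed-step fourth-order Runge-Kutta integration of the
#' wavelength-summed rate law, producing the concentration-versus-time trace
#' of every species.  Fixed stepping keeps runs exactly reproducible; the
#' default step is set by [default_settings()].
#'
#' A warning is emitted if the total absorbance inside the system's OSIA
#' reaches `warn_absorbance` (default 0.5) at any recorded time -- the
#' medium then leaves the spectrophotometric linearity zone the rate law
#' assumes, which is a validity caution, not a numerical failure.
#'
#' @param system a [photo_system()].
#' @param dt time step, s (default from [default_settings()]).
#' @param t_end duration, s.  When `NULL`, integration proceeds in blocks
#'   of the [default_settings()] duration until the largest species rate
#'   has fallen below `rate_tol` of its initial value (at most `max_blocks`
#'   blocks) -- truncating a trace far from its final state biases the
#'   subsequent model fit.
#' @param n_record approximate number of recorded time points per block
#'   (the integration itself always uses the full `dt` grid).
#' @param warn_absorbance in-OSIA absorbance threshold for the validity
#'   warning; set `Inf` to disable.
#' @param rate_tol,max_blocks stationarity target and cap for the adaptive
#'   duration (only used when `t_end` is `NULL`).
#' @return object of class `kinetic_trace`: list with `times` (s), `conc`
#'   (matrix, one labelled column per species, M), `dt`, and `system`.
#' @export
simulate_kinetics <- function(system, dt = NULL, t_end = NULL,
                              n_record = 201L, warn_absorbance = 0.5,
                              rate_tol = 1e-3, max_blocks = 10L) {
  def <- NULL
  if (is.null(dt) || is.null(t_end)) def <- default_settings(system)
  if (is.null(dt)) dt <- def$dt
  adaptive <- is.null(t_end)
  if (adaptive) t_end <- def$t_end
  if (dt <= 0 || t_end <= dt) stop("need dt > 0 and t_end > dt")
  cs <- compile_system(system)
  deriv <- function(t, y, parms) list(rate_vector_compiled(cs, pmax(y, 0)))
  n_steps <- ceiling(t_end / dt)
  block_times <- seq(0, by = dt, length.out = n_steps + 1L)
  r0_max <- max(abs(rate_vector_compiled(cs, system$c0)))
  conc <- matrix(system$c0, nrow = 1L)
  t_off <- 0
  times <- 0
  n_blocks <- if (adaptive && r0_max > 0) max_blocks else 1L
  for (blk in seq_len(n_blocks)) {
    y0 <- conc[nrow(conc), ]
    sol <- deSolve::rk4(y = y0, times = block_times, func = deriv,
                        parms = NULL)
    blk_conc <- unname(sol[-1L, -1L, drop = FALSE])
    if (anyNA(blk_conc) || any(!is.finite(blk_conc)))
      stop(sprintf("integration produced non-finite concentrations (dt = %g)",
                   dt))
    if (any(blk_conc < -1e-15)) {
      bad <- which(blk_conc < -1e-15, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "negative concentration %.3e for species %s at t = %.4g s: step too coarse",
        blk_conc[bad[1L], bad[2L]], system$mechanism$labels[bad[2L]],
        t_off + block_times[bad[1L] + 1L]))
    }
    blk_conc[blk_conc < 0] <- 0
    conc <- rbind(conc, blk_conc)
    times <- c(times, t_off + block_times[-1L])
    t_off <- t_off + block_times[length(block_times)]
    if (adaptive && r0_max > 0) {
      r_now <- max(abs(rate_vector_compiled(cs, conc[nrow(conc), ])))
      if (r_now <= rate_tol * r0_max) break
    }
  }
  stride <- max(1L, floor(n_steps / (n_record - 1L)))
  # dense opening: keep the first raw steps so the fastest kinetic
  # component (and hence the initial rate) is resolved by the record
  keep <- union(seq_len(min(33L, nrow(conc))),
                seq(1L, nrow(conc), by = stride))
  conc <- conc[keep, , drop = FALSE]
  colnames(conc) <- system$mechanism$labels
  trace <- structure(list(times = times[keep], conc = conc, dt = dt,
                          system = system),
                     class = "kinetic_trace")
  if (is.finite(warn_absorbance)) {
    osia <- suppressWarnings(system_osia(system))
    if (length(osia$wavelengths)) {
      sel <- match(osia$wavelengths, system$lamp$wavelength)
      E <- cs$E[sel, , drop = FALSE]
      amax <- max(E %*% t(conc) * system$l_irr +
                    cs$spm[sel])
      if (amax >= warn_absorbance)
        warning(sprintf(
          "in-OSIA absorbance reaches %.3g (>= %.2g): medium outside the linearity validity zone",
          amax, warn_absorbance))
    }
  }
  trace
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace: %d points, 0-%.4g s, species %s>\n",
              length(x$times), max(x$times),
              paste(colnames(x$conc), collapse = ", ")))
  invisible(x)
}

#' Total-absorbance trace at the observation wavelength
#'
#' \eqn{A_{tot}(\lambda_{obs}, t) = \sum_j \epsilon_j(\lambda_{obs})\,
#' l_{obs}\, C_j(t) + A_{SPM}(\lambda_{obs})}.
#'
#' @param trace a `kinetic_trace`.
#' @param lambda_obs observation wavelength, nm; defaults to the system's.
#' @param l_obs observation path length, cm; defaults to the system's.
#' @return numeric vector of absorbances, one per recorded time.
#' @export
absorbance_trace <- function(trace,
                             lambda_obs = trace$system$lambda_obs,
                             l_obs = trace$system$l_obs) {
  sys <- trace$system
  i <- grid_index(sys$lamp, lambda_obs)
  eps_obs <- vapply(sys$epsilons, function(e) e$value[i], numeric(1))
  a_spm <- if (is.null(sys$spm)) 0 else sys$spm$value[i]
  as.numeric(trace$conc %*% (eps_obs * l_obs)) + a_spm
}

#' Initial rate from the opening of a numerical trace
#'
#' Third-order one-sided finite difference on the first four recorded
#' samples of a species (or total-absorbance) trace -- the `RK:r0` route to
#' the initial rate, independent of both the rate law and the fit.
#'
#' @param trace a `kinetic_trace`.
#' @param what species label (e.g. `"X"`) or `"A"` for the total-absorbance
#'   trace.
#' @return scalar rate (M s^-1, or s^-1 for `"A"`).
#' @export
rk_r0 <- function(trace, what = "X") {
  y <- if (identical(what, "A")) absorbance_trace(trace)
       else trace$conc[, what]
  if (length(y) < 4L) stop("need at least four recorded points")
  h <- diff(trace$times[1:4])
  if (max(abs(h - h[1L])) > 1e-9 * h[1L])
    stop("the first four recorded points must be equally spaced")
  (-11 * y[1L] + 18 * y[2L] - 9 * y[3L] + 2 * y[4L]) / (6 * h[1L])
}
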