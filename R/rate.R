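#' Wavelength-summed rate law
#'
#' Evaluates the polychromatic rate of every species at a given state: for
#' species \eqn{Y_j},
#' \deqn{r_{Y_j} = \sum_\lambda \sum_{j'} \big[-\Phi_{j\to j'}(\lambda)
#'   P_a^{Y_j}(\lambda) + \Phi_{j'\to j}(\lambda) P_a^{Y_{j'}}(\lambda)\big],}
#' with \eqn{P_a^{Y_j} = \epsilon_j l\, C_j\, P_0\, PKF(A_{tot})} the light
#' absorbed by \eqn{Y_j}.  Depletion is negative.  For mechanisms that only
#' interconvert species the components sum to zero (mass conservation).
#'
#' @param system a [photo_system()].
#' @param conc molar concentrations at the evaluation state; defaults to the
#'   system's initial concentrations.
#' @return named numeric vector of rates, mol dm^-3 s^-1.
#' @export
rate_vector <- function(system, conc = system$c0) {
  if (length(conc) != system$mechanism$n_species)
    stop("one concentration per species is required")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  r <- rate_vector_compiled(compile_system(system), conc)
  names(r) <- system$mechanism$labels
  r
}

#' Initial reactant rate for a pure-reactant start
#'
#' Closed form of the reactant rate at `t = 0` when the reactant is the only
#' absorber present:
#' \deqn{r_{0,X} = -\sum_\lambda \sum_{j'} \Phi_{X\to Y_{j'}}(\lambda)
#'   P_0(\lambda)\,(1 - 10^{-A_X(\lambda,0)}).}
#' This is the largest magnitude the reactant rate attains along the whole
#' trace.  The form presumes X is the sole absorber, so any photoproduct or
#' spectator absorbance at `t = 0` is refused; use [rate_vector()] for mixed
#' initial states.
#'
#' @param system a [photo_system()].
#' @param c_x0 initial reactant concentration; defaults to the system's.
#' @return scalar rate (non-positive), mol dm^-3 s^-1.
#' @export
initial_reactant_rate <- function(system, c_x0 = system$c0[1L]) {
  if (any(system$c0[-1L] > 0))
    stop("co-species present at t = 0: use rate_vector() for mixed starts")
  if (!is.null(system$spm) && any(system$spm$value > 0))
    stop("spectator absorbance present: use rate_vector() at t = 0 instead")
  if (c_x0 < 0) stop("'c_x0' must be non-negative")
  ax <- system$epsilons[[1L]]$value * system$l_irr * c_x0
  p0 <- system$lamp$value
  r <- 0
  for (s in system$mechanism$steps) {
    if (s$from != 1L) next
    r <- r - sum(s$phi$value * p0 * (1 - 10^(-ax)))
  }
  r
}

#' Theoretical initial rates of all species and of the absorbance trace
#'
#' The rate law evaluated at `t = 0` (`Theo:r0`), plus the implied initial
#' rate of the total-absorbance trace at the observation wavelength,
#' \eqn{r_{0,A} = \sum_j \epsilon_j(\lambda_{obs})\, l_{obs}\, r_{0,Y_j}}.
#'
#' @param system a [photo_system()].
#' @param conc initial-state concentrations; defaults to the system's.
#' @return list with `species` (named rate vector) and `absorbance`
#'   (scalar, s^-1).
#' @export
theoretical_initial_rates <- function(system, conc = system$c0) {
  r <- rate_vector(system, conc)
  eps_obs <- vapply(system$epsilons, function(e)
    e$value[grid_index(e, system$lambda_obs)], numeric(1))
  list(species = r, absorbance = sum(eps_obs * system$l_obs * r))
}
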