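#' Complete photoreactive system
#'
#' Bundles everything a simulation needs: the mechanism, one absorptivity
#' curve per species, the lamp, the geometry, the observation wavelength,
#' the initial concentrations and an optional spectator (SPM) absorbance.
#'
#' @param mechanism a [mechanism()].
#' @param epsilons list of absorptivity curves, one per species (use an
#'   all-zero curve for a transparent species).
#' @param lamp lamp `spectral_curve`.
#' @param c0 initial molar concentrations; a single number is taken as the
#'   reactant concentration with all photoproducts absent.
#' @param l_irr irradiation optical path length, cm (> 0).
#' @param l_obs observation optical path length, cm (> 0).
#' @param lambda_obs observation wavelength, nm (must lie on the grid).
#' @param spm optional spectator absorbance curve (dimensionless), `NULL`
#'   for none.
#' @param lamp_tag identifier of the lamp (used to tag actinometric
#'   quantities, which are lamp-specific).
#' @export
photo_system <- function(mechanism, epsilons, lamp, c0,
                         l_irr = 1, l_obs = 1, lambda_obs,
                         spm = NULL, lamp_tag = "Lp1") {
  if (!inherits(mechanism, "mechanism")) stop("'mechanism' is required")
  if (length(epsilons) != mechanism$n_species)
    stop("one absorptivity curve per species is required")
  for (e in epsilons)
    if (!inherits(e, "spectral_curve") || e$kind != "absorptivity")
      stop("'epsilons' must be absorptivity spectral_curves")
  if (!inherits(lamp, "spectral_curve") || lamp$kind != "lamp_intensity")
    stop("'lamp' must be a lamp_intensity spectral_curve")
  args <- c(epsilons, list(lamp), lapply(mechanism$steps, `[[`, "phi"))
  if (!is.null(spm)) args <- c(args, list(spm))
  do.call(check_same_grid, args)
  if (l_irr <= 0 || l_obs <= 0) stop("path lengths must be positive")
  if (length(c0) == 1L) c0 <- c(c0, numeric(mechanism$n_species - 1L))
  if (length(c0) != mechanism$n_species || any(c0 < 0))
    stop("'c0' must give a non-negative concentration per species")
  grid_index(lamp, lambda_obs)  # errors if off grid
  structure(list(mechanism = mechanism, epsilons = epsilons, lamp = lamp,
                 c0 = c0, l_irr = l_irr, l_obs = l_obs,
                 lambda_obs = as.integer(round(lambda_obs)),
                 spm = spm, lamp_tag = lamp_tag),
            class = "photo_system")
}

#' @export
print.photo_system <- function(x, ...) {
  cat(sprintf(
    "<photo_system: %d species, %d steps, grid %d-%d nm, c0(X)=%.3g M>\n",
    x$mechanism$n_species, n_phi(x$mechanism),
    min(x$lamp$wavelength), max(x$lamp$wavelength), x$c0[1L]))
  invisible(x)
}

#' Replace the lamp of a system
#' @param system a [photo_system()].
#' @param lamp the new lamp curve (same grid).
#' @param lamp_tag tag of the new lamp; defaults to the old tag (use a new
#'   tag when the profile, not just the intensity, changes).
#' @export
with_lamp <- function(system, lamp, lamp_tag = system$lamp_tag) {
  photo_system(system$mechanism, system$epsilons, lamp, system$c0,
               system$l_irr, system$l_obs, system$lambda_obs,
               system$spm, lamp_tag)
}

# matrices used by the inner rate loop; computed once per simulation
compile_system <- function(system) {
  nl <- length(system$lamp$wavelength)
  nsp <- system$mechanism$n_species
  E <- matrix(0, nl, nsp)
  for (j in seq_len(nsp)) E[, j] <- system$epsilons[[j]]$value
  steps <- system$mechanism$steps
  PHI <- matrix(0, nl, length(steps))
  for (s in seq_along(steps)) PHI[, s] <- steps[[s]]$phi$value
  list(E = E, PHI = PHI,
       from = vapply(steps, `[[`, integer(1), "from"),
       to = vapply(steps, `[[`, integer(1), "to"),
       P0 = system$lamp$value,
       spm = if (is.null(system$spm)) numeric(nl) else system$spm$value,
       l_irr = system$l_irr, nsp = nsp)
}

# rate of every species for a compiled system at concentrations conc
rate_vector_compiled <- function(cs, conc) {
  A <- cs$E * rep(conc * cs$l_irr, each = nrow(cs$E))
  atot <- rowSums(A) + cs$spm
  w <- cs$P0 * pkf(atot)
  r <- numeric(cs$nsp)
  for (s in seq_along(cs$from)) {
    flux <- sum(cs$PHI[, s] * A[, cs$from[s]] * w)
    r[cs$from[s]] <- r[cs$from[s]] - flux
    r[cs$to[s]] <- r[cs$to[s]] + flux
  }
  r
}

#' OSIA of a system
#'
#' Overlap of the lamp with the pooled absorption of all species: the
#' wavelengths where the lamp emits and at least one species absorbs.
#'
#' @param system a [photo_system()].
#' @return as [compute_osia()].
#' @export
system_osia <- function(system) {
  pooled <- Reduce(`+`, lapply(system$epsilons, `[[`, "value"))
  compute_osia(system$lamp,
               spectral_curve(system$lamp$wavelength, pooled, "absorptivity"))
}
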