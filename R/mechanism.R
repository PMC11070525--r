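#' A single photochemical reaction step
#'
#' Unimolecular photostep `from -> to` with its wavelength-dependent quantum
#' yield.  Parallel steps between the same pair of species are allowed (they
#' model reactivity in different wavelength regions, as in photochromic
#' switches driven jointly by UV and visible light).
#'
#' @param from,to species indices (1 = reactant X); must differ.
#' @param phi quantum-yield `spectral_curve`.
#' @export
photo_step <- function(from, to, phi) {
  from <- as.integer(from); to <- as.integer(to)
  if (from == to) stop("a photostep must connect two distinct species")
  if (!inherits(phi, "spectral_curve") || phi$kind != "quantum_yield")
    stop("'phi' must be a quantum_yield spectral_curve")
  structure(list(from = from, to = to, phi = phi), class = "photo_step")
}

#' Photoreaction mechanism
#'
#' Directed graph of photosteps over `n_species` species.  Species 1 is the
#' reactant X; photoproducts are labelled Y1, Y2, ... by default.
#'
#' @param n_species number of species.
#' @param steps list of [photo_step()] objects.
#' @param labels optional species names (default `X`, `Y1`, ...).
#' @param cyclic logical; whether the step graph contains a cycle of three
#'   or more species (which widens the admissible number of fitting terms).
#'   Auto-detected when `NULL`.
#' @export
mechanism <- function(n_species, steps, labels = NULL, cyclic = NULL) {
  n_species <- as.integer(n_species)
  if (n_species < 2L) stop("a mechanism needs at least two species")
  if (length(steps) < 1L) stop("a mechanism needs at least one photostep")
  for (s in steps) {
    if (!inherits(s, "photo_step")) stop("'steps' must be photo_step objects")
    if (s$from < 1L || s$from > n_species || s$to < 1L || s$to > n_species)
      stop("photostep species index out of range")
  }
  grids <- lapply(steps, `[[`, "phi")
  do.call(check_same_grid, grids)
  if (is.null(labels))
    labels <- c("X", paste0("Y", seq_len(n_species - 1L)))
  if (length(labels) != n_species) stop("one label per species is required")
  if (is.null(cyclic)) cyclic <- has_cycle(n_species, steps)
  structure(list(n_species = n_species, steps = steps, labels = labels,
                 cyclic = isTRUE(cyclic)),
            class = "mechanism")
}

# cycle of length >= 3 in the step graph with reversible pairs collapsed
# to a single undirected edge (a bare photoreversible pair is not "cyclic")
has_cycle <- function(n, steps) {
  pairs <- unique(t(vapply(steps,
                           function(s) sort(c(s$from, s$to)), integer(2))))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
    if (a == b) return(TRUE)
    parent[a] <- b
  }
  FALSE
}

#' @export
print.mechanism <- function(x, ...) {
  arrows <- vapply(x$steps, function(s)
    paste0(x$labels[s$from], " -> ", x$labels[s$to]), character(1))
  cat(sprintf("<mechanism: %d species, %d photosteps%s>\n  %s\n",
              x$n_species, length(x$steps),
              if (x$cyclic) ", cyclic" else "", paste(arrows, collapse = ", ")))
  invisible(x)
}

#' Number of photosteps in a mechanism
#' @param mech a [mechanism()].
#' @export
n_phi <- function(mech) length(mech$steps)

#' Number of distinct reaction partners of one species
#'
#' Counts the distinct species linked to species `j` by at least one
#' photostep.  This is the quantity that bounds the number of mono-Phi-order
#' terms needed to fit the species' trace in non-cyclic mechanisms (a
#' photoreversible pair counts one partner, hence one term suffices).
#'
#' @param mech a [mechanism()].
#' @param j species index.
#' @export
n_phi_j <- function(mech, j) {
  partners <- unlist(lapply(mech$steps, function(s) {
    if (s$from == j) s$to else if (s$to == j) s$from else NULL
  }))
  length(unique(partners))
}

#' Admissible number of Phi-order fitting terms
#'
#' The number of mono-Phi-order terms admissible for a trace: the partner
#' count `n_phi_j` for a species trace of a non-cyclic mechanism, the total
#' step count `n_phi` for cyclic mechanisms and for total-absorbance traces.
#'
#' @param mech a [mechanism()].
#' @param species species index, or `NULL` for a total-absorbance trace.
#' @export
phi_order_bound <- function(mech, species = NULL) {
  if (is.null(species) || mech$cyclic) n_phi(mech) else n_phi_j(mech, species)
}

# --- mechanism templates -----------------------------------------------------
# Scheme families used throughout: primary photoprocess with a transparent
# (m1) or absorbing (m2) photoproduct, photoreversible (m3), doubly
# photoreversible chain (m4), photochrome with an extra visible-light back
# reaction (m5), divergent branching (phi_shaped), and tri/tetra-molecular
# cycles.  Templates carry the graph only; quantum-yield curves are attached
# by the system generator.
mechanism_template <- function(name) {
  switch(name,
    m1 = list(n_species = 2L, edges = rbind(c(1L, 2L)),
              labels = c("X", "Y1"), transparent = 2L),
    m2 = list(n_species = 2L, edges = rbind(c(1L, 2L)),
              labels = c("X", "Y1"), transparent = integer(0)),
    m3 = list(n_species = 2L, edges = rbind(c(1L, 2L), c(2L, 1L)),
              labels = c("X", "Y1"), transparent = integer(0)),
    m4 = list(n_species = 3L,
              edges = rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L)),
              labels = c("X", "Y1", "Y2"), transparent = integer(0)),
    m5 = list(n_species = 2L, edges = rbind(c(1L, 2L), c(2L, 1L), c(2L, 1L)),
              labels = c("X", "Y1"), transparent = integer(0)),
    phi_shaped = list(n_species = 3L, edges = rbind(c(1L, 2L), c(1L, 3L)),
                      labels = c("X", "Y1", "Y3"), transparent = integer(0)),
    cyclic3 = list(n_species = 3L,
                   edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L)),
                   labels = c("X", "Y1", "Y2"), transparent = integer(0)),
    cyclic4 = list(n_species = 4L,
                   edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L),
                                 c(1L, 3L), c(2L, 4L)),
                   labels = c("X", "Y1", "Y2", "Y3"),
                   transparent = integer(0)),
    stop(sprintf("unknown mechanism family '%s'", name))
  )
}

#' Mechanism families available in the catalog
#' @export
mechanism_families <- function() {
  c("m1", "m2", "m3", "m4", "m5", "phi_shaped", "cyclic3", "cyclic4")
}
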