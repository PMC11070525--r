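# Fixture builders shared across the test files.  Everything is generated
# in code; no data files.

# effectively monochromatic m1: one emitting grid point at 350 nm,
# flat reactant absorptivity, transparent product.
mono_m1 <- function(phi = 0.5, eps = 1e4, p0 = 1e-6, c0 = 5e-5, l = 1) {
  grid <- 348:352
  lampv <- numeric(5); lampv[3] <- p0
  photo_system(
    mechanism(2L, list(photo_step(1L, 2L, sc_constant(grid, phi)))),
    list(spectral_curve(grid, rep(eps, 5), "absorptivity"),
         spectral_curve(grid, rep(0, 5), "absorptivity")),
    spectral_curve(grid, lampv, "lamp_intensity"),
    c0, l_irr = l, l_obs = l, lambda_obs = 350)
}

# monochromatic photoreversible pair X <-> Y1
mono_m3 <- function(phi_f = 0.4, phi_r = 0.2, eps_x = 1e4, eps_y = 5e3,
                    p0 = 1e-6, c0 = 4e-5) {
  grid <- 348:352
  lampv <- numeric(5); lampv[3] <- p0
  photo_system(
    mechanism(2L, list(photo_step(1L, 2L, sc_constant(grid, phi_f)),
                       photo_step(2L, 1L, sc_constant(grid, phi_r)))),
    list(spectral_curve(grid, rep(eps_x, 5), "absorptivity"),
         spectral_curve(grid, rep(eps_y, 5), "absorptivity")),
    spectral_curve(grid, lampv, "lamp_intensity"),
    c0, l_irr = 1, l_obs = 1, lambda_obs = 350)
}

# divergent two-band reactant Y1 <- X -> Y3 with well separated bands,
# broadband lamp covering both; constant quantum yields
divergent_system <- function(phi1 = 0.3, phi3 = 0.3, c0 = 3e-5) {
  grid <- 300:450
  generate_system("phi_shaped", grid = grid,
                  bands = list(c(360, 80, 9e3), c(330, 30, 6e3),
                               c(390, 30, 6e3)),
                  phis = list(phi1, phi3),
                  lamp = list(type = "flat", from = 310, to = 440,
                              total = 1e-6),
                  c0 = c0, lambda_obs = 360)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

# divergent reactant with two separate absorption bands, each serving one
# branch through complementary quantum-yield profiles (two independently
# photoreactive groups in one molecule): the short-wavelength band drives
# X -> Y1, the long-wavelength band drives X -> Y3
chromatic_divergent <- function(c0 = 3e-5) {
  grid <- 300:450
  two_band <- sc_gaussian(grid, 330, 28, 8e3)
  long_band <- sc_gaussian(grid, 395, 28, 8e3)
  eps_x <- spectral_curve(grid, two_band$value + long_band$value,
                          "absorptivity")
  generate_system("phi_shaped", grid = grid,
                  bands = list(eps_x, c(320, 25, 4e3), c(410, 25, 4e3)),
                  phis = list(list(plateau = 0.4, center = 362, width = 4,
                                   falling = TRUE),
                              list(plateau = 0.4, center = 362, width = 4,
                                   falling = FALSE)),
                  lamp = list(type = "flat", from = 305, to = 445,
                              total = 1e-6),
                  c0 = c0, lambda_obs = 330)
}

# system with one field replaced (pure-X restart / spectator swap)
sys_with_c0 <- function(system, c_x0) {
  photo_system(system$mechanism, system$epsilons, system$lamp,
               c(c_x0, numeric(system$mechanism$n_species - 1L)),
               system$l_irr, system$l_obs, system$lambda_obs,
               system$spm, system$lamp_tag)
}

sys_with_spm <- function(system, spm) {
  photo_system(system$mechanism, system$epsilons, system$lamp, system$c0,
               system$l_irr, system$l_obs, system$lambda_obs, spm,
               system$lamp_tag)
}
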