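# actinometer fixture: photoreversible pair under a lamp that emits beyond
# the actinometer's absorption (dl_plus range wider than the OSIA)
act_system <- function(c0 = 3e-5) {
  grid <- 300:450
  generate_system("m3", grid = grid,
                  bands = list(c(350, 25, 9e3), c(382, 20, 4e3)),
                  phis = list(0.4, 0.15),
                  lamp = list(type = "flat", from = 300, to = 450,
                              total = 1e-6),
                  c0 = c0, lambda_obs = 350)
}

test_that("beta is the out-of-OSIA photon ratio", {
  grid <- 300:400
  lamp <- sc_flat_lamp(grid, 301, 400, 1e-6)  # 100 emitting steps
  bf <- beta_factor(lamp, c(321, 360))        # 40 inside
  expect_equal(bf$beta, 60 / 40)
  # scale invariance
  expect_equal(beta_factor(scale_lamp(lamp, 7.3), c(321, 360))$beta, 1.5)
  # support inside the OSIA: beta = 0
  lamp_in <- sc_flat_lamp(grid, 330, 350, 1e-6)
  expect_equal(beta_factor(lamp_in, c(321, 360))$beta, 0)
  expect_error(beta_factor(lamp, c(200, 250)), "no photons inside")
})

test_that("slope rescaling follows the worked conversion", {
  # the worked values: alpha over the full lamp output -0.1714 with
  # beta = 1.49 rescales to the OSIA-range slope -0.427 (3 s.f.)
  expect_equal(round(rescale_alpha(-0.1714, 1.49), 3), -0.427)
  expect_equal(rescale_alpha(-0.2, 0), -0.2)
  # round trip
  a <- rescale_alpha(-0.31, 0.7)
  expect_equal(rescale_alpha(a, 0.7, inverse = TRUE), -0.31)
  expect_error(rescale_alpha(-0.1, -0.2), "non-negative")
})

test_that("standardization yields a linear through-origin calibration", {
  sys <- act_system()
  line <- standardize_actinometer(sys, p0_scales = c(0.5, 1, 1.5, 2),
                                  range = "full", n_starts = 8)
  expect_s3_class(line, "calibration_line")
  expect_gt(line$r_squared, 0.9999)
  expect_equal(line$range_tag, "dl_plus")
  expect_equal(line$situation, "sit1")  # lamp wider than the OSIA
  # doubling the lamp doubles every r0: the slope is scale-free
  line2 <- standardize_actinometer(
    with_lamp(sys, scale_lamp(sys$lamp, 2)),
    p0_scales = c(0.5, 1, 1.5, 2), range = "full", n_starts = 8)
  expect_rel_equal(line2$alpha, line$alpha, 5e-3)
})

test_that("full-range and OSIA-range slopes are linked by 1 + beta", {
  sys <- act_system()
  full <- standardize_actinometer(sys, range = "full", n_starts = 8)
  osia <- standardize_actinometer(sys, range = "osia", n_starts = 8)
  expect_gt(full$beta, 0)
  # alpha_dl = alpha_dl_plus * (1 + beta), end to end through fitting
  expect_rel_equal(rescale_alpha(full$alpha, full$beta), osia$alpha, 5e-3)
  # out-of-OSIA photons leave the initial rates unchanged
  expect_rel_equal(full$points$r0[2], osia$points$r0[2], 1e-6)
})

test_that("photons outside the OSIA leave the kinetics unchanged", {
  sys <- act_system()
  osia <- system_osia(sys)
  grid <- sys$lamp$wavelength
  extra <- ifelse(grid > max(osia$wavelengths), 5e-9, 0)
  lamp_plus <- spectral_curve(grid, sys$lamp$value + extra, "lamp_intensity")
  tr1 <- simulate_kinetics(sys, dt = 1, t_end = 500, n_record = 51)
  tr2 <- simulate_kinetics(with_lamp(sys, lamp_plus), dt = 1, t_end = 500,
                           n_record = 51)
  expect_identical(tr1$conc, tr2$conc)
})

test_that("a calibration line prices unknown intensities of its own lamp only", {
  expect_equal(-0.0857 / -0.1714, 0.5)  # the division behind Eq-form P0 = r0/alpha
  sys <- act_system()
  line <- standardize_actinometer(sys, p0_scales = c(0.6, 1, 1.4, 1.8),
                                  range = "full", n_starts = 8)
  # a calibration point inverts to its own intensity
  p0_2 <- line$points$p0[2]
  expect_rel_equal(
    unknown_intensity(line$points$r0[2], line, "Lp1", "dl_plus"), p0_2,
    1e-9)
  # held-out intensity recovered end to end within 1%
  sys_unk <- with_lamp(sys, scale_lamp(sys$lamp, 1.23))
  tr <- simulate_kinetics(sys_unk, warn_absorbance = Inf)
  fit <- fit_phi_order(tr$times, absorbance_trace(tr), 2, n_starts = 8,
                       target = "absorbance")
  p0_rec <- unknown_intensity(fit$r0, line, "Lp1", "dl_plus")
  expect_rel_equal(p0_rec, lamp_total(sys_unk$lamp), 0.01)
  # tag mismatches are refused
  expect_error(unknown_intensity(fit$r0, line, "Lp2", "dl_plus"),
               "lamp tag mismatch")
  expect_error(unknown_intensity(fit$r0, line, "Lp1", "dl"),
               "range tag mismatch")
})

test_that("the m5 photochrome under combined UV and visible light calibrates linearly", {
  sys <- generate_system("m5", c0 = 3e-5)
  line <- standardize_actinometer(sys, p0_scales = c(0.5, 1, 2),
                                  range = "full", n_starts = 8,
                                  n_terms = 1L)
  expect_gt(line$r_squared, 0.9999)
})

test_that("photonic yield follows its defining ratio", {
  phyd <- photonic_yield(1e-4, 5e-5, 1e-6, 100, "reactant", "dl")
  expect_equal(as.numeric(phyd), 0.5)
  expect_equal(attr(phyd, "range_tag"), "dl")
  # before any conversion the yield is zero
  expect_equal(as.numeric(photonic_yield(1e-4, 1e-4, 1e-6, 10)), 0)
  expect_error(photonic_yield(1e-4, 5e-5, 1e-6, 0), "positive")
  # booking the larger full-lamp photon count lowers the yield
  p_dl <- 1e-6; p_dlp <- 2.5e-6
  expect_lt(as.numeric(photonic_yield(1e-4, 6e-5, p_dlp, 50,
                                      range_tag = "dl_plus")),
            as.numeric(photonic_yield(1e-4, 6e-5, p_dl, 50)))
  # along a depletion trace the reactant photonic yield decreases in time
  sys <- mono_m1(c0 = 4e-5)
  tr <- simulate_kinetics(sys, dt = 0.5, t_end = 600, n_record = 41)
  p0 <- lamp_total(sys$lamp)
  vals <- vapply(2:41, function(i)
    as.numeric(photonic_yield(4e-5, tr$conc[i, "X"], p0, tr$times[i])),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("PY is the initial-rate efficiency and equals -alpha on calibration runs", {
  expect_equal(as.numeric(efficiency_py(-2e-7, 1e-6)), 0.2)
  expect_equal(as.numeric(efficiency_py(0, 1e-6)), 0)
  sys <- act_system()
  line <- standardize_actinometer(sys, p0_scales = c(0.5, 1, 2),
                                  range = "full", what = "X", n_starts = 8)
  tr <- simulate_kinetics(sys, warn_absorbance = Inf)
  fit <- fit_phi_order(tr$times, tr$conc[, "X"], 1, n_starts = 8)
  py <- efficiency_py(fit$r0, lamp_total(sys$lamp), "dl_plus")
  expect_rel_equal(as.numeric(py), -line$alpha, 5e-3)
})

test_that("single-step quantum yield inverts the initial-rate equation", {
  # hand value consistent with the absorbed-flux example
  phi <- quantum_yield_single_step(-3.4189e-7,
    spectral_curve(348:352, c(0, 0, 1e-6, 0, 0), "lamp_intensity"),
    spectral_curve(348:352, rep(1e4, 5), "absorptivity"), 1, 5e-5)
  expect_rel_equal(as.numeric(phi), 0.5, 1e-4)
  # end-to-end recovery on a polychromatic single-step system
  sys <- generate_system("m1", bands = list(c(360, 50, 8e3), NULL),
                         phis = list(0.3),
                         lamp = list(type = "broadband", center = 365,
                                     fwhm = 60, total = 1e-6),
                         c0 = 3e-5, lambda_obs = 360)
  tr <- simulate_kinetics(sys, warn_absorbance = Inf)
  fit <- fit_phi_order(tr$times, tr$conc[, "X"], 1, n_starts = 8)
  rec <- quantum_yield_single_step(fit$r0, sys$lamp, sys$epsilons[[1]],
                                   1, 3e-5)
  expect_lt(abs(as.numeric(rec) - 0.3), 0.003)
  # wavelength-dependent quantum yield biases the estimate (direction only)
  sysw <- generate_system("m1", bands = list(c(360, 50, 8e3), NULL),
                          phis = list(list(plateau = 0.6, center = 360,
                                           width = 10, falling = TRUE)),
                          lamp = list(type = "broadband", center = 365,
                                      fwhm = 60, total = 1e-6),
                          c0 = 3e-5, lambda_obs = 360)
  trw <- simulate_kinetics(sysw, warn_absorbance = Inf)
  fitw <- fit_phi_order(trw$times, trw$conc[, "X"], 1, n_starts = 8)
  recw <- quantum_yield_single_step(fitw$r0, sysw$lamp,
                                    sysw$epsilons[[1]], 1, 3e-5)
  # the flat-equivalent value differs from the plateau
  expect_gt(abs(as.numeric(recw) - 0.6), 0.05)
})

test_that("the general quantum-yield expression solves the rate law", {
  # pure single step at t = 0: reduces to the closed-form value
  sys <- generate_system("m1", bands = list(c(360, 50, 8e3), NULL),
                         phis = list(0.3), c0 = 3e-5, lambda_obs = 360)
  r0 <- theoretical_initial_rates(sys)$species[["X"]]
  phi <- quantum_yield_general(sys, sys$c0, r0, to = 2L)
  expect_rel_equal(phi, 0.3, 1e-10)
  # reversible system at a mixed state: feeding back the true parameters
  # recovers the constructed forward quantum yield
  sys3 <- generate_system("m3", phis = list(0.35, 0.2), c0 = 3e-5)
  conc <- c(2e-5, 1e-5)
  rX <- rate_vector(sys3, conc)[["X"]]
  phi3 <- quantum_yield_general(sys3, conc, rX, to = 2L)
  expect_rel_equal(phi3, 0.35, 1e-10)
  # with no reverse steps the third term vanishes: m2 at a mixed state
  sys2 <- generate_system("m2", phis = list(0.25), c0 = 3e-5)
  conc2 <- c(2e-5, 1e-5)
  r2 <- rate_vector(sys2, conc2)[["X"]]
  expect_rel_equal(quantum_yield_general(sys2, conc2, r2, to = 2L), 0.25,
                   1e-10)
})

test_that("situation classification warns when species absorb uncounted photons", {
  grid <- 300:450
  sys <- act_system()
  wide_species <- sc_gaussian(grid, 390, 80, 6e3)
  expect_warning(
    standardize_actinometer(sys, p0_scales = c(0.5, 1, 2), range = "full",
                            species_epsilon = wide_species, n_starts = 8),
    "sit3")
})
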