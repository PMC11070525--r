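test_that("initial-rate ratio across absorbances follows the closed form", {
  # |r0| at A0 = 1 vs A0 = 0.01 for the single-absorber case
  hi <- mono_m1(c0 = 1e-4)   # A0 = 1
  lo <- mono_m1(c0 = 1e-6)   # A0 = 0.01
  ratio <- initial_reactant_rate(hi) / initial_reactant_rate(lo)
  expect_rel_equal(ratio, (1 - 10^-1) / (1 - 10^-0.01), 1e-10)
  expect_rel_equal(ratio, 39.5, 2e-3)
})

test_that("c0 scan exposes auto-photostabilization", {
  # peak absorptivities keep the whole canonical c0 grid inside the
  # spectrophotometric linearity range
  sys <- generate_system("cyclic3", grid = 300:450,
    bands = list(c(340, 40, 4e3), c(370, 40, 3.5e3), c(400, 40, 3e3)),
    phis = list(0.3, 0.25, 0.2),
    lamp = list(type = "broadband", center = 365, fwhm = 70, total = 1e-6),
    c0 = 5e-5, lambda_obs = 340)
  scan <- c0_scan(sys, c0_values = c(1.3e-6, 1.3e-5, 5e-5, 1e-4))
  expect_true(isTRUE(attr(scan, "auto_photostabilization")))
  expect_true(all(diff(abs(scan$r0_X_fit)) > 0))
  expect_true(all(diff(scan$conversion) < 0))
  # reactant-to-product initial-rate proportionality across c0: exact for
  # the rate-law route, tight for the finite-difference route, and the
  # fit route scatters around the same constant within its extraction
  # noise
  r_theo <- scan$r0_X_theo / scan$r0_Y1_theo
  expect_lt(diff(range(r_theo)) / abs(mean(r_theo)), 1e-9)
  r_rk <- scan$r0_X_rk / scan$r0_Y1_rk
  expect_lt(diff(range(r_rk)) / abs(mean(r_rk)), 1e-3)
  expect_lt(max(abs(scan$ratio_XY1 - mean(r_theo)) / abs(mean(r_theo))),
            0.06)
})

test_that("the default c0 grid is the canonical seven-point series", {
  expect_equal(eval(formals(c0_scan)$c0_values),
               c(1.3e-6, 1.3e-5, 3e-5, 5e-5, 7e-5, 9e-5, 1e-4))
})

test_that("conversion half-time becomes c0-independent in the optically thin limit", {
  half_time <- function(c0) {
    sys <- mono_m1(c0 = c0, p0 = 1e-6)
    tr <- simulate_kinetics(sys, dt = 0.5, t_end = 400, n_record = 401)
    stats::approx(tr$conc[, "X"] / c0, tr$times, xout = 0.5)$y
  }
  t1 <- half_time(1e-7)  # A0 = 1e-3
  t2 <- half_time(2e-7)  # A0 = 2e-3
  # in the PKF -> ln10 limit the kinetics are first order: k = phi eps l P0 ln10
  expect_rel_equal(t1, log(2) / (0.5 * 1e4 * 1e-6 * log(10)), 2e-3)
  expect_rel_equal(t2, t1, 2e-3)
})

test_that("spectator scan: baseline, out-of-OSIA inertness, branch selectivity", {
  sys <- chromatic_divergent()
  grid <- sys$lamp$wavelength
  # spectator covering only the long-wavelength branch band
  spm_y3 <- sc_gaussian(grid, 400, 25, 1, floor_frac = 1e-6)
  spm_y3$kind <- "absorptivity"
  scan <- spm_scan(sys, spm_y3, scales = c(0, 0.5, 1), n_starts = 10)
  expect_equal(scan$pct_reduction_X[scan$scale == 0], 0)
  expect_equal(scan$pct_reduction_A[scan$scale == 0], 0)
  # reductions grow with spectator absorbance for every trace
  expect_true(all(diff(scan$pct_reduction_Y1) > 0))
  expect_true(all(diff(scan$pct_reduction_Y3) > 0))
  # chromatic orthogonality: the overlapped branch suffers far more
  expect_gt(scan$pct_reduction_Y3[3], 3 * scan$pct_reduction_Y1[3])
  # a spectator absorbing only where the lamp is dark changes nothing
  spm_out <- spectral_curve(grid, ifelse(grid <= 304, 1, 0), "absorptivity")
  scan_out <- spm_scan(sys, spm_out, scales = c(0, 1), n_starts = 10)
  expect_lt(abs(scan_out$pct_reduction_X[2]), 1e-8)
  expect_lt(abs(scan_out$pct_reduction_Y3[2]), 1e-8)
})

test_that("reactivity score profile defines the WROR window", {
  grid <- 300:450
  eps <- sc_gaussian(grid, 360, 50, 1e4)
  # constant quantum yield: window centred on the absorption maximum
  w1 <- wror_profile(eps, list(sc_constant(grid, 0.4)))
  expect_equal(w1$peak, 360)
  expect_true(w1$window[1] < 360 && w1$window[2] > 360)
  # a zero-quantum-yield subregion is excluded even where epsilon > 0
  phi_step <- spectral_curve(grid, ifelse(grid <= 330, 0, 0.4),
                             "quantum_yield")
  w2 <- wror_profile(eps, list(phi_step))
  expect_true(all(w2$score[grid <= 330] == 0))
  expect_gte(w2$window[1], 331)
  # all-zero score: explicit empty window
  expect_message(
    w3 <- wror_profile(eps, list(sc_constant(grid, 0))),
    "no photokinetically active region")
  expect_null(w3$window)
})

test_that("per-wavelength initial rates track the reactivity score", {
  grid <- 300:450
  eps <- sc_gaussian(grid, 370, 55, 5e3)
  phi <- sc_sigmoid(grid, 0.5, 370, 15, falling = TRUE)
  score <- eps$value * phi$value
  c0 <- 2e-6  # optically thin
  r0_lam <- vapply(seq_along(grid), function(i) {
    lampv <- numeric(length(grid)); lampv[i] <- 1e-6
    sys <- photo_system(
      mechanism(2L, list(photo_step(1, 2, phi))),
      list(eps, spectral_curve(grid, numeric(length(grid)), "absorptivity")),
      spectral_curve(grid, lampv, "lamp_intensity"),
      c0, 1, 1, 370)
    abs(rate_vector(sys)[1])
  }, numeric(1))
  keep <- score > 0
  expect_gt(stats::cor(r0_lam[keep], score[keep])^2, 0.999)
})

test_that("LED scan finds the reactivity optimum and matches the score argmax", {
  sys <- divergent_system(phi1 = 0.1, phi3 = 0.5)
  prof <- wror_profile(sys$epsilons[[1]],
                       lapply(sys$mechanism$steps, `[[`, "phi"))
  centers <- seq(320, 420, by = 20)
  scan <- led_scan(sys, centers, fwhm = 20, n_starts = 8)
  best <- attr(scan, "best_center")
  expect_lte(abs(best - prof$peak), 10)  # within one LED half-width
  # two LEDs symmetric about a symmetric score peak react equally
  sym <- generate_system("m1", bands = list(c(375, 40, 8e3), NULL),
                         phis = list(0.4),
                         lamp = list(type = "flat", total = 1e-6),
                         c0 = 2e-5, lambda_obs = 375)
  scan2 <- led_scan(sym, c(365, 385), fwhm = 15, n_starts = 8)
  expect_rel_equal(scan2$r0_X_fit[1], scan2$r0_X_fit[2], 1e-3)
  # an LED where the score vanishes produces no reaction
  scan3 <- led_scan(sym, 300, fwhm = 4, n_starts = 8)
  expect_lt(abs(scan3$r0_X_fit[1]),
            1e-3 * max(abs(scan2$r0_X_fit)))
})

test_that("photostationary ratios follow the stationarity condition", {
  sys <- mono_m3(phi_f = 0.4, phi_r = 0.2, eps_x = 1e4, eps_y = 5e3)
  tr <- simulate_kinetics(sys, dt = 0.2, t_end = 4000, n_record = 101)
  pss <- pss_ratios(tr, tol = 1e-5)
  expect_rel_equal(pss$ratios["Y1", "X"],
                   (0.4 * 1e4) / (0.2 * 5e3), 1e-4)
  # ratios are invariant across the canonical c0 grid
  ratios <- vapply(c(1.3e-6, 1.3e-5, 5e-5, 1e-4), function(c0) {
    tr_i <- suppressWarnings(
      simulate_kinetics(sys_with_c0(sys, c0), dt = 0.2, t_end = 4000,
                        n_record = 51))
    pss_ratios(tr_i, tol = 1e-5)$ratios["Y1", "X"]
  }, numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-3)
  # an unfinished trace is rejected with a stationarity diagnostic
  tr_short <- simulate_kinetics(sys, dt = 0.2, t_end = 40, n_record = 21)
  expect_error(pss_ratios(tr_short, tol = 1e-6), "not stationary")
  # irreversible depletion flags full conversion
  m1 <- mono_m1()
  tr1 <- suppressWarnings(simulate_kinetics(m1, dt = 0.5, t_end = 6000,
                                            n_record = 51))
  pss1 <- pss_ratios(tr1, tol = 1e-3)
  expect_true("X" %in% pss1$full_conversion)
  expect_gt(pss1$ratios["Y1", "X"], 1e12)
})


test_that("scaling c0, path length, or absorptivity act through one absorbance history", {
  base <- generate_system("m2", c0 = 2e-5)
  f <- 2
  # path-length and absorptivity scaling are exactly interchangeable
  sys_l <- photo_system(base$mechanism, base$epsilons, base$lamp, 2e-5,
                        l_irr = f, l_obs = 1, lambda_obs = base$lambda_obs)
  tr_l <- simulate_kinetics(sys_l, dt = 2, t_end = 600, n_record = 41)
  eps_f <- lapply(base$epsilons, function(e)
    spectral_curve(e$wavelength, e$value * f, "absorptivity"))
  sys_e <- photo_system(base$mechanism, eps_f, base$lamp, 2e-5,
                        l_irr = 1, l_obs = 1, lambda_obs = base$lambda_obs)
  tr_e <- simulate_kinetics(sys_e, dt = 2, t_end = 600, n_record = 41)
  expect_equal(tr_l$conc, tr_e$conc, tolerance = 1e-12)
  # c0 scaling gives the same absorbance history dilated in time by f
  # (the slow-down at higher loading): C_{fc0}(f t) = f C_{c0, fl}(t)
  tr_c0 <- simulate_kinetics(sys_with_c0(base, 2e-5 * f), dt = 2 * f,
                             t_end = 600 * f, n_record = 41)
  expect_equal(tr_c0$times, tr_l$times * f)
  expect_equal(tr_c0$conc, f * tr_l$conc, tolerance = 1e-9)
})
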