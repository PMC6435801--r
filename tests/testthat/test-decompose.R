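random_profiles <- function(seed = 1, n = 12) {
  set.seed(seed)
  R <- seq(0.5, 1.6, length.out = n)
  list(f_gb = fe_profile(R, rnorm(n), runif(n, 0, 0.1), component = "F_GB"),
       mu = fe_profile(R, rnorm(n), runif(n, 0, 0.1), component = "mu_ex_gb"),
       dmu = fe_profile(R, rnorm(n), runif(n, 0, 0.1), component = "dmu_ref"))
}

test_that("cycle assembly satisfies its algebraic identities exactly", {
  pr <- random_profiles(101)
  dec <- assemble_cycle(pr$f_gb, pr$mu, pr$dmu, R_ref = 0.5)
  p <- dec$profiles
  expect_lt(max(abs(p$F$value - p$F_vac$value - p$mu_ex$value)), 1e-12)
  expect_identical(p$F$value[1], 0)          # shifted at R_ref
  g <- glance(dec)
  expect_lt(g$closure_F, 1e-12)
  # degenerate cases
  zero <- fe_profile(pr$f_gb$R, 0, 0)
  d2 <- assemble_cycle(pr$f_gb, pr$mu, zero, R_ref = 0.5)
  expect_equal(d2$profiles$F$value, d2$profiles$F_GB$value, tolerance = 1e-12)
  expect_equal(d2$profiles$mu_ex$value, d2$profiles$mu_ex_gb$value, tolerance = 1e-12)
  d3 <- assemble_cycle(pr$f_gb, zero, pr$dmu, R_ref = 0.5)
  expect_equal(d3$profiles$F_vac$value, d3$profiles$F_GB$value, tolerance = 1e-12)
  # grid mismatch is refused
  bad <- fe_profile(pr$f_gb$R + 0.01, pr$mu$value, 0)
  expect_error(assemble_cycle(pr$f_gb, bad, zero), "same R grid")
})

test_that("nonpolar and energy/entropy splits close bin-wise", {
  pr <- random_profiles(102)
  dec <- assemble_cycle(pr$f_gb, pr$mu, pr$dmu, R_ref = 0.5)
  set.seed(103)
  np <- fe_profile(pr$f_gb$R, rnorm(12), runif(12, 0, 0.1))
  dec <- add_nonpolar(dec, np)
  p <- dec$profiles
  expect_lt(max(abs(p$mu_ex$value - p$mu_nonpol$value - p$mu_pol$value)), 1e-12)
  ei <- fe_profile(pr$f_gb$R, rnorm(12), runif(12, 0, 0.1))
  dec <- add_intramolecular(dec, ei)
  p <- dec$profiles
  expect_lt(max(abs(p$F_vac$value - p$E_intra$value - p$neg_TS_intra$value)), 1e-12)
  g <- glance(dec)
  expect_lt(max(g$closure_mu, g$closure_Fvac), 1e-12)
})

test_that("the charge-zeroed route is refused for charged topologies", {
  top <- flexible_chain()
  expect_error(
    nonpolar_profile(top, c(0.5, 0.6), quick_protocol(10), gb_backend(80)),
    "charge-zeroed")
})

test_that("rigid uncharged systems give the closed-form nonpolar profile", {
  toy <- harmonic_dumbbell(charges = c(0, 0), gamma = 0.02)
  top <- toy$topology
  grid <- c(0.5, 0.7, 0.9)
  p <- quick_protocol(n_frames = 30, seed = 104)
  bk <- gb_backend(80, sa = TRUE)
  np <- nonpolar_profile(top, grid, p, bk, fixed_mode = "exact")
  # mu_nonpol(R) = gamma * A(R) in kT (backend = sampling model, so the
  # reweighting term vanishes)
  exact <- toy$solvation_exact(grid, solvent_model(80, sa = TRUE)) / kT(298)
  expect_equal(np$value, exact, tolerance = 1e-10)
  # with the surface term absent it is identically zero
  toy0 <- harmonic_dumbbell(charges = c(0, 0), gamma = 0)
  np0 <- nonpolar_profile(toy0$topology, grid, p, gb_backend(80, sa = TRUE),
                          fixed_mode = "exact")
  expect_lt(max(abs(np0$value)), 1e-12)
})

test_that("vacuum ensembles give the dumbbell energy/entropy split analytically", {
  toy <- harmonic_dumbbell(k_b = 1000, r0 = 0.5)
  top <- toy$topology
  grid <- seq(0.4, 0.7, by = 0.1)
  p <- quick_protocol(n_frames = 40, seed = 105)
  vac_frames <- lapply(grid, function(R)
    run_sampling(top, vacuum(), p, fixed_R = R, fixed_mode = "exact"))
  ei <- intramolecular_energy_profile(vac_frames, top, grid)
  beta <- 1 / kT(298)
  expect_equal(ei$value, beta * 0.5 * 1000 * (grid - 0.5)^2, tolerance = 1e-10)
  # -TS = F_vac - E is the Jacobian term -2 ln R up to a constant
  F_vac <- fe_profile(grid, toy$F_exact(grid), 0)
  negTS <- F_vac$value - ei$value
  expect_equal(diff(negTS), diff(-2 * log(grid)), tolerance = 1e-10)
  # a rigid molecule has a flat entropy term
  expect_lt(max(abs(diff(ei$value - beta * 0.5 * 1000 * (grid - 0.5)^2))), 1e-10)
})

test_that("temperature differencing is zero at equal T and additive always", {
  pr <- random_profiles(106)
  dec1 <- assemble_cycle(pr$f_gb, pr$mu, pr$dmu, R_ref = 0.5)
  d0 <- delta_T_profiles(dec1, dec1)
  expect_identical(max(abs(d0$value)), 0)
  pr2 <- random_profiles(107)
  dec2 <- assemble_cycle(pr2$f_gb, pr2$mu, pr2$dmu, R_ref = 0.5)
  dT <- delta_T_profiles(dec1, dec2)
  wide <- tidyr::pivot_wider(dT[, c("component", "R", "value")],
                             names_from = "component", values_from = "value")
  expect_lt(max(abs(wide$F - wide$F_vac - wide$mu_ex)), 1e-12)
  expect_error(delta_T_profiles(dec1,
    assemble_cycle(pr2$f_gb, pr2$mu, pr2$dmu, R_ref = 0.6)), "references differ")
})

test_that("pressure differencing enforces the vacuum-leg identity", {
  pr <- random_profiles(108)
  dec1 <- assemble_cycle(pr$f_gb, pr$mu, pr$dmu, R_ref = 0.5)
  expect_identical(max(abs(delta_P_profiles(dec1, dec1)$value)), 0)
  pr2 <- random_profiles(109)
  dec2 <- assemble_cycle(pr2$f_gb, pr2$mu, pr2$dmu, R_ref = 0.5)
  dec2$temperature <- dec1$temperature
  dP <- delta_P_profiles(dec1, dec2)
  wide <- tidyr::pivot_wider(dP[, c("component", "R", "value")],
                             names_from = "component", values_from = "value")
  expect_identical(wide$F, wide$mu_ex)
})

test_that("unfolding free energy matches the three-point enumeration", {
  prof <- fe_profile(c(0.5, 0.6, 1.8), c(0, 0, 0), 0)
  res <- unfolding_free_energy(prof, folded_R = c(0.5, 0.6), n_boot = 0)
  expect_equal(res$dFu, log(2), tolerance = 1e-12)
  expect_equal(res$p_folded, 2 / 3, tolerance = 1e-12)
  # degenerate profiles are guarded
  deep <- fe_profile(c(0.5, 0.6, 1.8), c(0, 0, 800), 0)
  expect_error(unfolding_free_energy(deep, n_boot = 0), "degenerate")
  # published-style worked arithmetic: dFu 2.7 at 298 K, -0.1 at 373 K
  expect_equal(delta_T_unfolding(2.7, -0.1), -2.8, tolerance = 1e-14)
})

test_that("partial molar volume conversion follows the unit oracle", {
  expect_equal(partial_molar_volume(c(2, 2, 2), c(1, 4000, 8000))$dV_cm3_mol, 0,
               tolerance = 1e-12)
  # linear drop 2.7 -> 1.0 kT between 1 and 8000 bar at 298 K
  res <- partial_molar_volume(c(2.7, 1.0), c(1, 8000), temperature = 298)
  oracle <- (1.0 - 2.7) * kT(298) * 1000 / (8000 - 1) * 10
  expect_equal(res$dV_cm3_mol, oracle, tolerance = 1e-12)
  expect_equal(oracle, -5.27, tolerance = 0.01)
  # local two-point slopes track an analytic quadratic derivative
  Ps <- c(2000, 2100)
  dfu <- 3 - 1e-4 * Ps - 2e-8 * Ps^2
  slope <- partial_molar_volume(dfu, Ps, 298)$dV_cm3_mol
  analytic <- (-1e-4 - 4e-8 * 2050) * kT(298) * 1000 * 10
  expect_equal(slope, analytic, tolerance = 1e-6)
  expect_error(partial_molar_volume(2.7, 1), "two pressures")
})
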