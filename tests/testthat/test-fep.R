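test_that("zero perturbation returns exactly zero for every estimator", {
  kt <- kT(298)
  x <- rnorm(100)
  expect_identical(fep_one_step(x, x, 298)$value, 0)
  expect_identical(fep_reweight(x, x, 298)$value, 0)
  lad <- dielectric_ladder(intermediates = c(10, 2))
  tab <- purrr::map_dfr(lad$state, function(s) {
    out <- tibble::tibble(state = s, frame = 1:20, R = 0.5)
    for (s2 in lad$state) out[[paste0("dG_", s2)]] <- 0
    out
  })
  expect_identical(fep_bidirectional_ladder(tab, lad, 298)$value, 0)
})

test_that("two-point exponential averages match their closed forms", {
  kt <- kT(298)
  r1 <- fep_one_step(c(0, kt * log(2)), c(0, 0), 298, n_eff_floor = 0)
  expect_equal(r1$value, -log((1 + 0.5) / 2), tolerance = 1e-12)
  expect_equal(r1$value, 0.2876820724517809, tolerance = 1e-12)
  r2 <- fep_reweight(c(0, kt), c(0, 0), 298, n_eff_floor = 0)
  expect_equal(r2$value, -log((1 + exp(-1)) / 2), tolerance = 1e-12)
  expect_equal(r2$value, 0.3798854930417224, tolerance = 1e-10)
})

test_that("the Gaussian FEP identity holds at large n", {
  set.seed(71)
  kt <- kT(298)
  m <- 1.2; s <- 0.6                       # kJ/mol
  dd <- rnorm(1e5, m, s)
  r <- fep_one_step(dd, rep(0, 1e5), 298)
  expected <- m / kt - s^2 / (2 * kt^2)
  expect_lt(abs(r$value - expected), 3 * r$stderr)
  expect_gt(r$stderr, 0)
})

test_that("the rigid Born-ion ladder telescopes to the endpoint difference", {
  toy <- harmonic_dumbbell(charges = c(1, 0), born_radius = 0.2)
  top <- toy$topology
  lad <- dielectric_ladder()                 # twelve intermediates
  p <- quick_protocol(n_frames = 25, seed = 81)
  fss <- sequential_ladder_sampling(top, lad, 0.5, p, fixed_mode = "exact")
  tab <- ladder_energy_table(fss, top, lad)
  bi <- fep_bidirectional_ladder(tab, lad, 298)
  expect_identical(nrow(bi$detail), 13L)     # thirteen bidirectional steps
  exact <- toy$solvation_exact(0.5, solvent_model(80, sa = FALSE)) / kT(298)
  expect_equal(bi$value, exact, tolerance = 1e-12)
  # telescoping is independent of ladder resolution for rigid systems
  lad2 <- dielectric_ladder(intermediates = c(5))
  fss2 <- sequential_ladder_sampling(top, lad2, 0.5, p, fixed_mode = "exact")
  bi2 <- fep_bidirectional_ladder(ladder_energy_table(fss2, top, lad2), lad2, 298)
  expect_equal(bi2$value, bi$value, tolerance = 1e-12)
})

test_that("forward and reverse one-step estimates agree in expectation", {
  top <- flexible_chain()
  lad <- dielectric_ladder(intermediates = c(40))
  p <- sampling_protocol(n_equil = 2000, n_frames = 4000, stride = 10,
                         step_nm = 0.05, seed = 91)
  fss <- sequential_ladder_sampling(top, lad, 0.6, p)
  tab <- ladder_energy_table(fss, top, lad)
  t80 <- tab[tab$state == "eps80", ]; t40 <- tab[tab$state == "eps40", ]
  fwd <- fep_one_step(t80$dG_eps40, t80$dG_eps80, 298)  # 80 -> 40
  rev <- fep_one_step(t40$dG_eps80, t40$dG_eps40, 298)  # 40 -> 80
  expect_lt(abs(fwd$value + rev$value),
            3 * sqrt(fwd$stderr^2 + rev$stderr^2))
})

test_that("refining the ladder does not move the flexible-chain estimate", {
  top <- flexible_chain()
  p <- sampling_protocol(n_equil = 2000, n_frames = 5000, stride = 10,
                         step_nm = 0.05, seed = 92)
  coarse <- dielectric_ladder(intermediates = c(20, 5, 2))
  fine <- dielectric_ladder(intermediates = c(40, 20, 10, 5, 3.5, 2, 1.4))
  est <- function(lad) {
    fss <- sequential_ladder_sampling(top, lad, 0.6, p)
    fep_bidirectional_ladder(ladder_energy_table(fss, top, lad), lad, 298)
  }
  a <- est(coarse); b <- est(fine)
  expect_lt(abs(a$value - b$value), 3 * sqrt(a$stderr^2 + b$stderr^2))
})

test_that("block standard errors follow the defining contract", {
  expect_identical(block_standard_error(rep(2.5, 1000)), 0)
  expect_error(block_standard_error(1:100, n_blocks = 1), ">= 2")
  # 5000 frames in 5 blocks of 1000 each
  lens <- block_standard_error(seq_len(5000), n_blocks = 5, estimator = length)
  expect_identical(lens, 0)                  # all blocks identical in length
  blocks <- split(seq_len(5000), ceiling(seq_len(5000) / 1000))
  expect_identical(lengths(blocks), setNames(rep(1000L, 5), as.character(1:5)))
  # iid Gaussian: block error within a factor 2 of the delta-method value
  set.seed(93)
  sg <- 0.8; n <- 1e4
  x <- rnorm(n, 0, sg)
  be <- block_standard_error(x, n_blocks = 5)
  analytic <- sqrt((exp(sg^2) - 1) / n)
  expect_gt(be / analytic, 0.5)
  expect_lt(be / analytic, 2)
})

test_that("poor phase-space overlap is flagged through the effective sample size", {
  set.seed(94)
  dd <- c(rep(30, 99), 0)                    # one frame dominates
  expect_warning(r <- fep_one_step(dd, rep(0, 100), 298), "effective sample size")
  expect_true(r$low_overlap)
  expect_lt(r$n_eff, 2)
  r2 <- fep_one_step(dd, rep(0, 100), 298, n_eff_floor = 0)
  expect_false(r2$low_overlap)
})
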