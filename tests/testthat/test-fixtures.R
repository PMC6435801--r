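test_that("the dumbbell analytic profile is stationary where predicted", {
  toy <- harmonic_dumbbell(k_b = 1000, r0 = 0.5)
  beta <- 1 / kT(298)
  opt <- stats::optimize(function(R) toy$F_exact(R), c(0.4, 0.7))
  # stationarity: beta k (R - r0) = 2 / R
  resid <- beta * 1000 * (opt$minimum - 0.5) - 2 / opt$minimum
  expect_lt(abs(resid), 0.01)
  # the bond term is even about r0
  U <- function(R) toy$F_exact(R) + 2 * log(R)
  expect_equal(U(0.5 + 0.07), U(0.5 - 0.07), tolerance = 1e-10)
  # a charged variant has zero solvation in vacuum
  toyq <- harmonic_dumbbell(charges = c(1, -1))
  expect_identical(toyq$solvation_exact(c(0.4, 0.6), vacuum()), c(0, 0))
  expect_error(harmonic_dumbbell(k_b = -5), "positive")
})

test_that("the freely jointed chain density matches brute-force simulation", {
  toy <- freely_jointed_chain(3, bond_length = 1)   # two links
  expect_error(freely_jointed_chain(2), "at least 3")
  set.seed(201)
  Rs <- toy$sample_R(2e5)
  # exact density for two unit links is linear: p(R) = R/2 on [0, 2]
  expect_equal(toy$density_exact(c(0.5, 1, 1.5)), c(0.25, 0.5, 0.75),
               tolerance = 1e-12)
  h <- hist(Rs, breaks = seq(0, 2, by = 0.1), plot = FALSE)
  expected <- vapply(seq_len(20), function(i)
    stats::integrate(toy$density_exact, (i - 1) * 0.1, i * 0.1)$value, numeric(1))
  expect_lt(max(abs(h$counts / length(Rs) - expected)), 0.005)
  # four links: density integrates to one and matches simulated moments
  toy5 <- freely_jointed_chain(5, bond_length = 0.38)
  expect_equal(stats::integrate(toy5$density_exact, 0, 4 * 0.38)$value, 1,
               tolerance = 1e-6)
  set.seed(202)
  R5 <- toy5$sample_R(2e5)
  expect_equal(mean(R5^2), 4 * 0.38^2, tolerance = 0.01)  # n b^2
  grid <- seq(0.2, 1.2, by = 0.05)
  Fsim <- -log(vapply(grid, function(g) mean(abs(R5 - g) < 0.025) / 0.05,
                      numeric(1)))
  Fex <- toy5$F_exact(grid)
  expect_lt(max(abs((Fsim - mean(Fsim)) - (Fex - mean(Fex)))), 0.1)
  # beyond full extension the profile is undefined and guarded
  expect_identical(toy5$density_exact(4 * 0.38 + 0.1), 0)
  expect_error(toy5$F_exact(2), "full extension")
})

test_that("reference tables regenerate byte-identically and feed the pipeline", {
  toy <- harmonic_dumbbell(charges = c(0.8, -0.8), gamma = 0.02)
  lad <- dielectric_ladder(intermediates = c(10, 2))
  p <- quick_protocol(n_frames = 40, seed = 301)
  bk <- gb_backend(80, sa = TRUE)
  grid <- c(0.5, 0.8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  t1 <- generate_reference_tables(toy, grid, p, lad, bk, d1, fixed_mode = "exact")
  t2 <- generate_reference_tables(toy, grid, p, lad, bk, d2, fixed_mode = "exact")
  expect_identical(nrow(t1), 2L)
  for (i in seq_len(nrow(t1))) {
    expect_identical(readLines(t1$file[i]), readLines(t2$file[i]))
  }
  tab <- read_energy_table(t1$file[1])
  expect_identical(nrow(tab), 40L * nrow(lad))   # frames x ladder states
  # ingestion equivalence: file-fed estimates equal the in-memory route
  fss <- sequential_ladder_sampling(toy$topology, lad, grid[1],
                                    quick_protocol(n_frames = 40, seed = 301 + 100000L),
                                    fixed_mode = "exact")
  mem <- fep_bidirectional_ladder(ladder_energy_table(fss, toy$topology, lad),
                                  lad, 298)
  filed <- fep_bidirectional_ladder(tab, lad, 298)
  expect_identical(filed$value, mem$value)
  ws <- lad$state[1]
  sub <- tab[tab$state == ws, ]
  rw_file <- fep_reweight(sub$dG_hyd, sub[[paste0("dG_", ws)]], 298)
  dG_hyd_mem <- backend_evaluate(bk, toy$topology, fss[[ws]])
  rw_mem <- fep_reweight(dG_hyd_mem,
                         eval_frames(fss[[ws]]$frames, toy$topology,
                                     solvent_model(80, sa = TRUE)), 298)
  expect_identical(rw_file$value, rw_mem$value)
})
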