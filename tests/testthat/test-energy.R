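test_that("harmonic bond energy matches the closed form", {
  top <- chain_topology(2, bond_r0 = 0.5, bond_k = 1000)
  conf <- default_conformation(top)
  expect_identical(intramolecular_energy(top, conf), 0)
  conf[2, 1] <- conf[2, 1] + 0.1
  expect_equal(intramolecular_energy(top, conf), 5.0, tolerance = 1e-12)
})

test_that("intramolecular energy equals the term-by-term oracle", {
  top <- rich_chain()
  for (s in 1:4) {
    conf <- random_conformation(top, seed = s)
    expect_equal(intramolecular_energy(top, conf),
                 intra_energy_oracle(top, conf), tolerance = 1e-10)
  }
})

test_that("an isolated charged bead reproduces the Born ion energy", {
  # partner bead 50 nm away and uncharged: descreening is negligible
  top <- chain_topology(2, bond_r0 = 50, bond_k = 1e-4,
                        charge = c(1, 0), born_radius = 0.2)
  conf <- default_conformation(top)
  born <- -coulomb_const / (2 * 0.2) * (1 - 1 / 80)   # ~ -342.997 kJ/mol
  got <- solvation_free_energy(top, conf, solvent_model(80, sa = FALSE))
  expect_equal(got, born, tolerance = 1e-6)
  expect_lt(abs(got - (-342.9969)), 1e-3)
})

test_that("the polar term vanishes at eps_r = 1 and is never positive", {
  top <- rich_chain()
  conf <- random_conformation(top, seed = 3)
  expect_identical(solvation_free_energy(top, conf, solvent_model(1, sa = FALSE)), 0)
  for (eps in c(1.2, 2, 5, 20, 80)) {
    expect_lte(solvation_free_energy(top, conf, solvent_model(eps, sa = FALSE)), 0)
  }
})

test_that("the polar magnitude shrinks monotonically as eps_r decreases to 1", {
  top <- rich_chain()
  conf <- random_conformation(top, seed = 4)
  eps <- c(80, 20, 5, 2, 1.2, 1)
  vals <- vapply(eps, function(e)
    solvation_free_energy(top, conf, solvent_model(e, sa = FALSE)), numeric(1))
  expect_true(all(diff(abs(vals)) <= 0))
  expect_identical(vals[length(vals)], 0)
})

test_that("charge-zeroed solvation is eps-independent and equals the SA term", {
  top0 <- zero_charges(rich_chain())
  conf <- random_conformation(top0, seed = 5)
  sa80 <- solvation_free_energy(top0, conf, solvent_model(80, sa = TRUE))
  sa2 <- solvation_free_energy(top0, conf, solvent_model(2, sa = TRUE))
  expect_identical(sa80, sa2)
  terms <- energy_terms(top0, conf, solvent_model(80, sa = TRUE))
  expect_identical(terms$gb, 0)
  expect_equal(sa80, sum(top0$gamma * terms$sasa), tolerance = 1e-12)
  expect_gt(sa80, 0)
})

test_that("effective energy is the sum of its two parts", {
  top <- harmonic_dumbbell(charges = c(1, -1))$topology
  conf <- default_conformation(top)
  expect_identical(effective_energy(top, conf, vacuum()),
                   intramolecular_energy(top, conf))
  top0 <- zero_charges(rich_chain())
  conf0 <- random_conformation(top0, seed = 6)
  expect_equal(effective_energy(top0, conf0, solvent_model(80, sa = TRUE)),
               intramolecular_energy(top0, conf0) +
                 solvation_free_energy(top0, conf0, solvent_model(80, sa = TRUE)),
               tolerance = 1e-12)
  # the intramolecular part cancels in effective-energy differences
  s1 <- solvent_model(80, sa = FALSE); s2 <- solvent_model(4, sa = FALSE)
  expect_equal(
    effective_energy(top, conf, s1) - effective_energy(top, conf, s2),
    solvation_free_energy(top, conf, s1) - solvation_free_energy(top, conf, s2),
    tolerance = 1e-12)
})

test_that("pairwise GB closed form matches the engine on a dumbbell", {
  toy <- harmonic_dumbbell(k_b = 1000, r0 = 0.5, charges = c(0.7, -0.5),
                           born_radius = c(0.2, 0.25), gamma = 0.02)
  solv <- solvent_model(80, sa = TRUE)
  for (R in c(0.4, 0.5, 0.8, 1.5)) {
    conf <- default_conformation(toy$topology, R = R)
    expect_equal(solvation_free_energy(toy$topology, conf, solv),
                 toy$solvation_exact(R, solv), tolerance = 1e-10)
  }
})
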