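# Shared builders for the test suite. Everything is generated in code;
# sizes are kept small enough that the whole suite runs in minutes.

# a flexible 5-bead chain exercising every energy term
rich_chain <- function() {
  chain_topology(
    5,
    bonds = tibble::tibble(i = 1:4, j = 2:5, r0 = c(0.38, 0.4, 0.38, 0.42),
                           k = c(1000, 800, 1200, 900)),
    angles = tibble::tibble(a = 1:3, b = 2:4, c = 3:5,
                            theta0 = rep(1.9, 3), k = rep(40, 3)),
    charge = c(0.5, -0.3, 0, 0.4, -0.6),
    born_radius = c(0.2, 0.25, 0.18, 0.22, 0.2),
    lj_sigma = 0.33, lj_eps = 0.4, gamma = 0.015)
}

# a small flexible charged chain for statistical FEP checks
flexible_chain <- function() {
  chain_topology(3, bond_r0 = 0.4, bond_k = 800, charge = c(0.6, -0.2, -0.4),
                 born_radius = 0.2, gamma = 0.01)
}

random_conformation <- function(topology, jitter = 0.08, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- default_conformation(topology)
  base + matrix(rnorm(length(base), 0, jitter), ncol = 3)
}

random_rigid_motion <- function(conformation, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(conformation %*% q, 2, rnorm(3, 0, 2), `+`)
}

# independent R evaluation of the intramolecular energy, term by term
intra_energy_oracle <- function(topology, conf) {
  d <- function(i, j) sqrt(sum((conf[i, ] - conf[j, ])^2))
  e <- 0
  for (b in seq_len(nrow(topology$bonds))) {
    bb <- topology$bonds[b, ]
    e <- e + 0.5 * bb$k * (d(bb$i, bb$j) - bb$r0)^2
  }
  for (a in seq_len(nrow(topology$angles))) {
    aa <- topology$angles[a, ]
    v1 <- conf[aa$a, ] - conf[aa$b, ]; v2 <- conf[aa$c, ] - conf[aa$b, ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    e <- e + 0.5 * aa$k * (th - aa$theta0)^2
  }
  bonded <- paste(pmin(topology$bonds$i, topology$bonds$j),
                  pmax(topology$bonds$i, topology$bonds$j))
  for (i in seq_len(topology$n_beads - 1)) {
    for (j in (i + 1):topology$n_beads) {
      if (paste(i, j) %in% bonded) next
      r <- d(i, j)
      epsij <- sqrt(topology$lj_eps[i] * topology$lj_eps[j])
      if (epsij > 0) {
        s <- 0.5 * (topology$lj_sigma[i] + topology$lj_sigma[j])
        e <- e + 4 * epsij * ((s / r)^12 - (s / r)^6)
      }
      e <- e + coulomb_const * topology$charge[i] * topology$charge[j] / r
    }
  }
  e
}

# tiny, fast protocol for statistical tests
quick_protocol <- function(n_frames = 1000, seed = 1, ...) {
  sampling_protocol(n_equil = 500, n_frames = n_frames, stride = 5,
                    step_nm = 0.05, seed = seed, ...)
}

# closed-form expectation of a *binned* free-energy estimator: -ln of the
# Boltzmann weight integrated over each bin (removes the discretisation bias
# of comparing bin averages against bin-centre values)
binned_exact_profile <- function(toy, mids, width, solvent = vacuum(),
                                 temperature = 298) {
  vapply(mids, function(m) {
    -log(stats::integrate(function(r)
      exp(-toy$F_exact(r, solvent, temperature)),
      m - width / 2, m + width / 2)$value / width)
  }, numeric(1))
}
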