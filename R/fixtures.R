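#' Toy systems with closed-form free-energy profiles
#'
#' A toy system bundles a [chain_topology()] with analytic callables used as
#' oracles in validation: `F_exact(R, solvent, temperature)` returning the
#' radial potential of mean force in k_B T (up to an additive constant), and
#' `solvation_exact(R, solvent)` returning the closed-form solvation free
#' energy in kJ mol^-1 (when available).
#'
#' @name toy_system
NULL

new_toy_system <- function(topology, F_exact = NULL, solvation_exact = NULL,
                           density_exact = NULL, label = "toy") {
  structure(list(topology = topology, F_exact = F_exact,
                 solvation_exact = solvation_exact,
                 density_exact = density_exact, label = label),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("<toy_system> %s (%d beads)%s\n", x$label, x$topology$n_beads,
              if (!is.null(x$F_exact)) ", analytic profile attached" else ""))
  invisible(x)
}

# Closed-form GB pair solvation for two beads at separation R, duplicating
# the engine's formulas in plain R so the compiled path is cross-checked.
pair_solvation_exact_r <- function(R, topology, solvent) {
  if (solvent$eps_r <= 1 && !solvent$sa) return(rep(0, length(R)))
  rho <- topology$born_radius[1:2]
  q <- topology$charge[1:2]
  descreen <- function(r, p) 0.5 * (p / (r^2 - p^2) + (0.5 / r) * log((r - p) / (r + p)))
  vapply(R, function(r) {
    rr <- pmax(r, sum(rho))
    B1 <- 1 / (1 / rho[1] - descreen(rr, rho[2]))
    B2 <- 1 / (1 / rho[2] - descreen(rr, rho[1]))
    f <- sqrt(r^2 + B1 * B2 * exp(-r^2 / (4 * B1 * B2)))
    gb <- if (solvent$eps_r > 1)
      -0.5 * coulomb_const * (1 - 1 / solvent$eps_r) *
        (q[1]^2 / B1 + q[2]^2 / B2 + 2 * q[1] * q[2] / f)
    else 0
    sa <- if (solvent$sa) {
      a <- rho + 0.14
      area <- 4 * pi * a^2
      buried <- function(ai, aj) {
        if (r >= ai + aj) return(0)
        h <- ai - (r^2 + ai^2 - aj^2) / (2 * r)
        if (h > 0) 2 * pi * ai * h else 0
      }
      topology$gamma[1] * max(0, area[1] - buried(a[1], a[2])) +
        topology$gamma[2] * max(0, area[2] - buried(a[2], a[1]))
    } else 0
    gb + sa
  }, numeric(1))
}

#' Harmonic dumbbell toy system
#'
#' Two beads joined by a harmonic bond. The radial potential of mean force
#' is known in closed form: F(R)/k_B T = beta U(R) - 2 ln R + const, where
#' the -2 ln R term is the three-dimensional radial Jacobian and U collects
#' the bond energy plus (for charged variants under a solvent) the pairwise
#' GB/SA solvation free energy. The bonded pair carries no nonbonded
#' intramolecular interaction, so the vacuum energy is the bond term alone.
#'
#' @param k_b Bond stiffness (kJ mol^-1 nm^-2, > 0).
#' @param r0 Bond equilibrium length (nm).
#' @param charges Length-2 charges (e).
#' @param born_radius Intrinsic Born radii (nm), recycled.
#' @param gamma Surface-tension coefficients (kJ mol^-1 nm^-2), recycled.
#' @return A `toy_system`.
#' @export
harmonic_dumbbell <- function(k_b = 1000, r0 = 0.5, charges = c(0, 0),
                              born_radius = 0.2, gamma = 0) {
  if (k_b <= 0) stop("bond stiffness must be positive")
  top <- chain_topology(2, bond_r0 = r0, bond_k = k_b, charge = charges,
                        born_radius = born_radius, gamma = gamma,
                        label = "harmonic dumbbell")
  solv_exact <- function(R, solvent) pair_solvation_exact_r(R, top, solvent)
  F_exact <- function(R, solvent = vacuum(), temperature = 298) {
    beta <- 1 / kT(temperature)
    U <- 0.5 * k_b * (R - r0)^2 + solv_exact(R, solvent)
    beta * U - 2 * log(R)
  }
  new_toy_system(top, F_exact = F_exact, solvation_exact = solv_exact,
                 label = sprintf("harmonic dumbbell (k=%g, r0=%g)", k_b, r0))
}

#' Freely jointed chain toy system
#'
#' N beads joined by stiff bonds of length b emulating rigid links. The
#' exact end-to-end distance density of an ideal chain of n = N - 1 freely
#' jointed links is the classical piecewise-polynomial convolution result;
#' `density_exact(R)` evaluates it, `F_exact(R)` is -ln of it (undefined and
#' guarded beyond full extension n b). `sample_R(m)` draws m independent
#' end-to-end distances of the ideal chain directly (sum of random unit
#' vectors) for brute-force validation.
#'
#' @param N Number of beads (>= 3).
#' @param bond_length Link length b (nm).
#' @param bond_k Stiffness of the emulating harmonic bonds.
#' @return A `toy_system` with an extra element `sample_R`.
#' @export
freely_jointed_chain <- function(N, bond_length = 0.38, bond_k = 50000) {
  if (N < 3) stop("a freely jointed chain toy needs at least 3 beads")
  n <- N - 1L                                # number of links
  b <- bond_length
  top <- chain_topology(N, bond_r0 = b, bond_k = bond_k,
                        born_radius = 0.01, label = "freely jointed chain")
  density <- function(R) {
    x <- R / b
    vapply(x, function(xx) {
      if (xx <= 0 || xx >= n) return(0)
      kmax <- floor((n - xx) / 2)
      s <- sum(vapply(0:kmax, function(k)
        (-1)^k * choose(n, k) * (n - 2 * k - xx)^(n - 2), numeric(1)))
      xx * s / (2^(n - 1) * factorial(n - 2))
    }, numeric(1)) / b                        # density in R
  }
  F_exact <- function(R, ...) {
    p <- density(R)
    if (any(p <= 0))
      stop("end-to-end density is zero at the requested R (beyond full extension)")
    -log(p)
  }
  sample_R <- function(m) {
    R2 <- matrix(0, m, 3)
    for (l in seq_len(n)) {
      z <- runif(m, -1, 1)
      phi <- runif(m, 0, 2 * pi)
      s <- sqrt(1 - z^2)
      R2 <- R2 + b * cbind(s * cos(phi), s * sin(phi), z)
    }
    sqrt(rowSums(R2^2))
  }
  ts <- new_toy_system(top, F_exact = F_exact, density_exact = density,
                       label = sprintf("freely jointed chain (N=%d, b=%g)", N, b))
  ts$sample_R <- sample_R
  ts
}

#' Emit the full set of per-frame energy tables for a toy system
#'
#' Runs the sequential dielectric ladder at each requested R, evaluates
#' every ladder-state energy column plus the backend hydration column on the
#' water-state ensemble, and writes one TSV per R with provenance metadata
#' (seed, toy label, ladder, T, P). Regenerating with the same seed is
#' byte-identical.
#'
#' @param toy A `toy_system`.
#' @param grid R values (nm).
#' @param protocol A [sampling_protocol()] (its seed drives everything).
#' @param ladder A [dielectric_ladder()].
#' @param backend A `hydration_backend`.
#' @param dir Output directory (created if needed).
#' @param temperature,pressure Backend evaluation state.
#' @param ... Passed to [sequential_ladder_sampling()].
#' @return Tibble with columns `R` and `file`.
#' @export
generate_reference_tables <- function(toy, grid, protocol, ladder, backend, dir,
                                      temperature = protocol$temperature,
                                      pressure = 1, ...) {
  stopifnot(inherits(toy, "toy_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(grid))
  for (i in seq_along(grid)) {
    p <- protocol
    if (!is.null(p$seed)) p$seed <- p$seed + 100000L * i
    fss <- sequential_ladder_sampling(toy$topology, ladder, grid[i], p, ...)
    tab <- ladder_energy_table(fss, toy$topology, ladder)
    dG_hyd <- backend_evaluate(backend, toy$topology, fss[[1]],
                               temperature = temperature, pressure = pressure)
    tab$dG_hyd <- NA_real_
    tab$dG_hyd[tab$state == ladder$state[1]] <- dG_hyd
    files[i] <- file.path(dir, sprintf("energies_R%.4f.tsv", grid[i]))
    write_energy_table(tab, files[i], meta = list(
      toy = toy$label, R_nm = grid[i], seed = p$seed %||% "unset",
      temperature_K = temperature, pressure_bar = pressure,
      backend = attr(backend, "id"),
      ladder = paste(ladder$eps_r, collapse = ",")))
  }
  tibble::tibble(R = grid, file = files)
}
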