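#' Define a coarse-grained chain topology
#'
#' A chain of spherical beads connected by harmonic bonds, optionally with
#' harmonic angle terms, per-bead partial charges, intrinsic Born radii,
#' Lennard-Jones parameters and surface-tension coefficients. Two terminal
#' bead indices define the end-to-end coordinate R used throughout the
#' package. Nonbonded (Lennard-Jones and Coulomb) interactions exclude
#' directly bonded 1-2 pairs; the generalized Born solvation term always
#' involves all charge pairs including self terms.
#'
#' @param n_beads Number of beads (>= 2).
#' @param bonds Data frame with columns `i`, `j` (1-based bead indices),
#'   `r0` (equilibrium length, nm) and `k` (stiffness, kJ mol^-1 nm^-2).
#'   Default: a linear chain i -- i+1.
#' @param bond_r0,bond_k Convenience scalars used to build the default linear
#'   chain bond list.
#' @param angles Optional data frame with columns `a`, `b`, `c` (1-based,
#'   vertex `b`), `theta0` (rad) and `k` (kJ mol^-1 rad^-2).
#' @param charge Per-bead partial charge (e); recycled.
#' @param born_radius Per-bead intrinsic Born radius (nm, > 0); recycled.
#' @param lj_sigma,lj_eps Per-bead Lennard-Jones sigma (nm) and epsilon
#'   (kJ mol^-1); `lj_eps = 0` disables the term. Recycled.
#' @param gamma Per-bead surface-tension coefficient (kJ mol^-1 nm^-2);
#'   recycled.
#' @param terminals Length-2 integer vector of terminal bead indices defining
#'   R (default first and last bead).
#' @param label Free-text label.
#' @return An object of class `chain_topology`.
#' @examples
#' top <- chain_topology(2, bond_r0 = 0.5, bond_k = 1000, charge = c(1, -1))
#' @export
chain_topology <- function(n_beads, bonds = NULL, bond_r0 = 0.38, bond_k = 1000,
                           angles = NULL, charge = 0, born_radius = 0.2,
                           lj_sigma = 0.35, lj_eps = 0, gamma = 0,
                           terminals = c(1L, n_beads), label = "chain") {
  n_beads <- as.integer(n_beads)
  if (n_beads < 2) stop("a chain needs at least 2 beads")
  if (is.null(bonds)) {
    bonds <- tibble::tibble(i = seq_len(n_beads - 1L), j = seq_len(n_beads - 1L) + 1L,
                            r0 = bond_r0, k = bond_k)
  }
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("i", "j", "r0", "k") %in% names(bonds)))
  if (is.null(angles)) {
    angles <- tibble::tibble(a = integer(), b = integer(), c = integer(),
                             theta0 = numeric(), k = numeric())
  }
  angles <- tibble::as_tibble(angles)
  rec <- function(v) rep_len(as.numeric(v), n_beads)
  born_radius <- rec(born_radius)
  if (any(born_radius <= 0)) stop("all Born radii must be > 0")
  terminals <- as.integer(terminals)
  if (length(terminals) != 2L || terminals[1] == terminals[2] ||
      any(terminals < 1L | terminals > n_beads)) {
    stop("terminals must be two distinct in-range bead indices")
  }
  idx_ok <- function(v) all(v >= 1 & v <= n_beads)
  if (!idx_ok(bonds$i) || !idx_ok(bonds$j)) stop("bond indices out of range")
  structure(list(
    n_beads = n_beads, bonds = bonds, angles = angles,
    charge = rec(charge), born_radius = born_radius,
    lj_sigma = rec(lj_sigma), lj_eps = rec(lj_eps), gamma = rec(gamma),
    terminals = terminals, label = label
  ), class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("<chain_topology> '%s': %d beads, %d bonds, %d angles\n",
              x$label, x$n_beads, nrow(x$bonds), nrow(x$angles)))
  cat(sprintf("  terminals %d-%d define R; total charge %+.3f e\n",
              x$terminals[1], x$terminals[2], sum(x$charge)))
  invisible(x)
}

#' Remove all partial charges from a topology
#'
#' Used by the nonpolar route: the charge-zeroed solute isolates the
#' nonpolar (cavity/dispersion-like) part of the excess chemical potential.
#'
#' @param topology A `chain_topology`.
#' @return The same topology with every charge exactly 0.
#' @export
zero_charges <- function(topology) {
  stopifnot(inherits(topology, "chain_topology"))
  topology$charge <- rep(0, topology$n_beads)
  topology$label <- paste0(topology$label, " (uncharged)")
  topology
}

#' Define the continuum solvent state
#'
#' @param eps_r Relative dielectric constant (>= 1); the solute interior
#'   dielectric is fixed at 1, so `eps_r = 1` switches the polar generalized
#'   Born term off exactly.
#' @param sa Logical: include the surface-area nonpolar term?
#' @return An object of class `solvent_model`.
#' @export
solvent_model <- function(eps_r = 80, sa = TRUE) {
  if (!is.numeric(eps_r) || length(eps_r) != 1L || eps_r < 1)
    stop("eps_r must be a single number >= 1")
  structure(list(eps_r = as.numeric(eps_r), sa = isTRUE(sa)),
            class = "solvent_model")
}

#' Vacuum solvent state (eps_r = 1, surface term off)
#' @rdname solvent_model
#' @export
vacuum <- function() solvent_model(eps_r = 1, sa = FALSE)

#' @export
print.solvent_model <- function(x, ...) {
  cat(sprintf("<solvent_model> eps_r = %g, surface-area term %s\n",
              x$eps_r, if (x$sa) "on" else "off"))
  invisible(x)
}

as_conformation <- function(x, topology) {
  x <- as.matrix(x)
  if (!is.numeric(x) || ncol(x) != 3L)
    stop("a conformation is an n_beads x 3 numeric matrix (nm)")
  if (nrow(x) != topology$n_beads)
    stop(sprintf("conformation has %d beads but topology has %d",
                 nrow(x), topology$n_beads))
  if (!all(is.finite(x))) stop("conformation contains non-finite coordinates")
  storage.mode(x) <- "double"
  x
}

#' End-to-end distance of a conformation
#'
#' @param conformation n_beads x 3 coordinate matrix (nm).
#' @param topology A `chain_topology` (supplies the terminal indices).
#' @return The distance R (nm) between the two terminal beads.
#' @export
end_to_end <- function(conformation, topology) {
  conformation <- as_conformation(conformation, topology)
  d <- conformation[topology$terminals[1], ] - conformation[topology$terminals[2], ]
  sqrt(sum(d^2))
}

#' Build a straight-line starting conformation
#'
#' Beads are placed along the x axis. If `R` is given, the terminal beads end
#' up exactly at distance `R` (equal spacing); otherwise consecutive beads sit
#' at their bond equilibrium lengths.
#'
#' @param topology A `chain_topology`.
#' @param R Optional target end-to-end distance (nm).
#' @return An n_beads x 3 coordinate matrix.
#' @export
default_conformation <- function(topology, R = NULL) {
  n <- topology$n_beads
  if (is.null(R)) {
    sp <- c(0, topology$bonds$r0[match(seq_len(n - 1L),
                                       pmin(topology$bonds$i, topology$bonds$j))])
    sp[is.na(sp)] <- mean(topology$bonds$r0)
    xs <- cumsum(sp)
  } else {
    if (R <= 0) stop("R must be positive")
    xs <- seq(0, R, length.out = n)
  }
  cbind(x = xs, y = rep(0, n), z = rep(0, n))
}

# plain-list form consumed by the C++ engine (0-based indices)
topo_to_cpp <- function(topology) {
  list(
    n = topology$n_beads,
    bonds = cbind(as.integer(topology$bonds$i) - 1L,
                  as.integer(topology$bonds$j) - 1L),
    bond_r0 = as.numeric(topology$bonds$r0),
    bond_k = as.numeric(topology$bonds$k),
    angles = if (nrow(topology$angles))
      cbind(as.integer(topology$angles$a) - 1L,
            as.integer(topology$angles$b) - 1L,
            as.integer(topology$angles$c) - 1L)
    else matrix(integer(), 0, 3),
    angle_theta0 = as.numeric(topology$angles$theta0),
    angle_k = as.numeric(topology$angles$k),
    charge = topology$charge,
    born_radius = topology$born_radius,
    lj_sigma = topology$lj_sigma,
    lj_eps = topology$lj_eps,
    gamma = topology$gamma,
    terminals = topology$terminals - 1L
  )
}
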