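#' Intramolecular potential energy of a conformation
#'
#' Sum of harmonic bond, harmonic angle, Lennard-Jones and Coulomb terms
#' (interior dielectric 1; 1-2 bonded pairs excluded from the nonbonded
#' terms). This is the vacuum energy E_intra entering the energy/entropy
#' split of the vacuum profile.
#'
#' @param topology A [chain_topology()].
#' @param conformation n_beads x 3 coordinate matrix (nm).
#' @return Energy in kJ mol^-1.
#' @export
intramolecular_energy <- function(topology, conformation) {
  conformation <- as_conformation(conformation, topology)
  tt <- cpp_energy_terms(conformation, topo_to_cpp(topology), 1, FALSE)
  tt$bonded + tt$lj + tt$coulomb
}

#' Implicit-solvent solvation free energy of a conformation
#'
#' Polar generalized Born term (Still-style pairwise formula over all charge
#' pairs, including self terms, with effective Born radii from pairwise
#' descreening) with prefactor -(1 - 1/eps_r)/2, plus a per-bead
#' surface-area nonpolar term when the solvent's surface flag is on. At
#' `eps_r = 1` the polar term is exactly zero, so the vacuum solvent state
#' returns exactly 0.
#'
#' @inheritParams intramolecular_energy
#' @param solvent A [solvent_model()].
#' @return Solvation free energy in kJ mol^-1.
#' @export
solvation_free_energy <- function(topology, conformation, solvent) {
  stopifnot(inherits(solvent, "solvent_model"))
  conformation <- as_conformation(conformation, topology)
  tt <- cpp_energy_terms(conformation, topo_to_cpp(topology), solvent$eps_r, solvent$sa)
  tt$gb + tt$sa
}

#' Effective (sampling) energy: intramolecular + solvation
#'
#' The per-conformation solvation free energy acts as a potential term in
#' the effective Hamiltonian that the sampler equilibrates.
#'
#' @inheritParams solvation_free_energy
#' @return Energy in kJ mol^-1.
#' @export
effective_energy <- function(topology, conformation, solvent) {
  intramolecular_energy(topology, conformation) +
    solvation_free_energy(topology, conformation, solvent)
}

#' Energy terms, effective Born radii and per-bead surface areas
#'
#' Diagnostic breakdown of every term the engine computes for one
#' conformation.
#'
#' @inheritParams solvation_free_energy
#' @return A list with components `bonded`, `lj`, `coulomb`, `gb`, `sa`
#'   (kJ mol^-1), `born_radii` (nm) and `sasa` (nm^2).
#' @export
energy_terms <- function(topology, conformation, solvent = solvent_model()) {
  conformation <- as_conformation(conformation, topology)
  cpp_energy_terms(conformation, topo_to_cpp(topology), solvent$eps_r, solvent$sa)
}

#' Total solvent-accessible surface area of a conformation
#'
#' Pairwise spherical-cap approximation with a 0.14 nm probe.
#'
#' @inheritParams intramolecular_energy
#' @return Area in nm^2.
#' @export
total_sasa <- function(topology, conformation) {
  conformation <- as_conformation(conformation, topology)
  sum(cpp_energy_terms(conformation, topo_to_cpp(topology), 1, TRUE)$sasa)
}

# vectorised evaluation over a frame array (n x 3 x F)
eval_frames <- function(frames, topology, solvent = NULL,
                        what = c("solvation", "intra", "effective", "sasa")) {
  what <- match.arg(what)
  code <- match(what, c("solvation", "intra", "effective", "sasa")) - 1L
  eps_r <- if (is.null(solvent)) 1 else solvent$eps_r
  sa <- if (is.null(solvent)) FALSE else solvent$sa
  cpp_eval_frames(frames, topo_to_cpp(topology), eps_r, sa, code)
}
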