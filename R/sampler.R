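#' Umbrella window
#'
#' Harmonic bias 1/2 k (R - R0)^2 on the end-to-end distance. The reference
#' configuration mirrors common practice for peptide end-to-end umbrella
#' sampling: k = 1875 kJ mol^-1 nm^-2.
#'
#' @param center Window centre R0 (nm, > 0).
#' @param k Force constant (kJ mol^-1 nm^-2, > 0).
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k = 1875) {
  if (center <= 0) stop("window centre must be > 0")
  if (k <= 0) stop("force constant must be > 0")
  structure(list(center = as.numeric(center), k = as.numeric(k)),
            class = "umbrella_window")
}

#' Umbrella bias energy at a given end-to-end distance
#'
#' @param R End-to-end distance(s) (nm) or a conformation matrix (with
#'   `topology` supplied).
#' @param window An [umbrella_window()].
#' @param topology Optional topology, needed when `R` is a conformation.
#' @return Bias energy 1/2 k (R - R0)^2 in kJ mol^-1.
#' @export
umbrella_bias_energy <- function(R, window, topology = NULL) {
  stopifnot(inherits(window, "umbrella_window"))
  if (is.matrix(R)) {
    if (is.null(topology)) stop("supply the topology to compute R from coordinates")
    R <- end_to_end(R, topology)
  }
  0.5 * window$k * (R - window$center)^2
}

#' Sampling protocol
#'
#' Metropolis Monte Carlo with single-bead Gaussian displacement moves is the
#' default integrator (the surface-area term has derivative kinks that an MC
#' sampler is indifferent to). Step counts are configurable; defaults are
#' sized for toy chains.
#'
#' @param n_equil Equilibration moves discarded before production.
#' @param n_frames Number of production frames saved.
#' @param stride Moves between saved frames.
#' @param step_nm Standard deviation of the per-coordinate Gaussian move (nm).
#' @param temperature Temperature (K).
#' @param seed Integer seed recorded in the output; if non-NULL the run is
#'   bit-for-bit reproducible.
#' @return An object of class `sampling_protocol`.
#' @export
sampling_protocol <- function(n_equil = 10000, n_frames = 5000, stride = 10,
                              step_nm = 0.05, temperature = 298, seed = NULL) {
  stopifnot(n_frames > 0, stride >= 1, n_equil >= 0, step_nm > 0, temperature > 0)
  structure(list(n_equil = as.integer(n_equil), n_frames = as.integer(n_frames),
                 stride = as.integer(stride), step_nm = step_nm,
                 temperature = temperature, seed = seed),
            class = "sampling_protocol")
}

new_frame_set <- function(frames, R, acceptance, final, provenance) {
  structure(list(frames = frames, R = R, acceptance = acceptance,
                 final = final, provenance = provenance),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<frame_set> %d frames of %d beads (eps_r = %g, SA %s, %g K, mode %s)\n",
    length(x$R), dim(x$frames)[1], p$eps_r, if (p$sa) "on" else "off",
    p$temperature, p$mode))
  cat(sprintf("  R in [%.4f, %.4f] nm, acceptance %.2f, seed %s\n",
              min(x$R), max(x$R), x$acceptance,
              if (is.null(p$seed)) "unset" else format(p$seed)))
  invisible(x)
}

#' Number of frames in a frame set
#' @param fs A `frame_set`.
#' @export
n_frames <- function(fs) length(fs$R)

#' Sample equilibrium conformations of the effective Hamiltonian
#'
#' Generates a Boltzmann-weighted frame set under the effective energy
#' (intramolecular + solvation), optionally biased. Three modes:
#' unrestrained (`window = NULL, fixed_R = NULL`), umbrella
#' (`window` given), and fixed end-to-end distance (`fixed_R` given).
#' Fixed-R mode either applies a stiff auxiliary restraint
#' (`fixed_mode = "restrain"`, default k = 18750 kJ mol^-1 nm^-2, i.e. ten
#' times the reference umbrella constant) and reports the residual R spread,
#' or freezes the two terminal beads (`fixed_mode = "exact"`), which
#' preserves R to machine precision.
#'
#' @param topology A [chain_topology()].
#' @param solvent A [solvent_model()].
#' @param protocol A [sampling_protocol()].
#' @param window Optional [umbrella_window()].
#' @param fixed_R Optional fixed end-to-end distance (nm).
#' @param fixed_mode `"restrain"` or `"exact"`.
#' @param restraint_k Restraint constant for `fixed_mode = "restrain"`.
#' @param init Optional starting conformation; defaults to a straight chain
#'   (placed at `fixed_R` when fixing R).
#' @return A `frame_set`: coordinate array (n_beads x 3 x n_frames),
#'   per-frame R, acceptance rate, final conformation, and provenance
#'   (solvent, bias, temperature, seed, mode).
#' @export
run_sampling <- function(topology, solvent, protocol, window = NULL,
                         fixed_R = NULL, fixed_mode = c("restrain", "exact"),
                         restraint_k = 18750, init = NULL) {
  stopifnot(inherits(topology, "chain_topology"),
            inherits(solvent, "solvent_model"),
            inherits(protocol, "sampling_protocol"))
  fixed_mode <- match.arg(fixed_mode)
  if (!is.null(window) && !is.null(fixed_R))
    stop("give either an umbrella window or a fixed R, not both")
  if (!is.null(fixed_R) && fixed_R <= 0) stop("fixed_R must be positive")

  if (is.null(init)) {
    init <- default_conformation(topology, R = fixed_R)
  }
  init <- as_conformation(init, topology)

  mode <- "free"; bias_mode <- 0L; bias_k <- 0; bias_r0 <- 0
  if (!is.null(window)) {
    stopifnot(inherits(window, "umbrella_window"))
    mode <- "umbrella"; bias_mode <- 1L; bias_k <- window$k; bias_r0 <- window$center
  } else if (!is.null(fixed_R)) {
    if (fixed_mode == "exact") {
      if (abs(end_to_end(init, topology) - fixed_R) > 1e-9)
        stop("exact fixed-R mode needs an initial conformation at the target R")
      mode <- "fixed-exact"; bias_mode <- 2L
    } else {
      mode <- "fixed-restrain"; bias_mode <- 1L; bias_k <- restraint_k; bias_r0 <- fixed_R
    }
  }

  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  beta <- 1 / kT(protocol$temperature)
  res <- cpp_mc_sample(init, topo_to_cpp(topology), solvent$eps_r, solvent$sa,
                       beta, protocol$n_equil, protocol$n_frames,
                       protocol$stride, protocol$step_nm,
                       bias_mode, bias_k, bias_r0)
  prov <- list(eps_r = solvent$eps_r, sa = solvent$sa,
               temperature = protocol$temperature, seed = protocol$seed,
               mode = mode, init = init, window = window, fixed_R = fixed_R,
               restraint_k = if (mode == "fixed-restrain") restraint_k else NA_real_)
  fs <- new_frame_set(res$frames, res$R, res$acceptance, res$final, prov)
  if (!is.null(fixed_R)) {
    fs$R_target <- fixed_R
    fs$R_max_dev <- max(abs(fs$R - fixed_R))
  }
  fs
}

#' Dielectric ladder between water and vacuum
#'
#' Ordered sequence of solvent states from eps_r = 80 (water) through
#' intermediates down to eps_r = 1 (vacuum). The default intermediates are
#' the twelve-state schedule 40, 20, 10, 5, 4.2, 3.5, 2.9, 2.4, 2.0, 1.7,
#' 1.4, 1.2. The surface-area term stays on for every state except the
#' final true-vacuum state, so the ladder's endpoint difference is the full
#' solvation free energy (polar + nonpolar).
#'
#' @param intermediates Strictly decreasing dielectric constants strictly
#'   between 80 and 1 (may be empty).
#' @param sa Surface-area flag for the non-vacuum states.
#' @return An object of class `dielectric_ladder`: a tibble with columns
#'   `state` (label), `eps_r` and `sa`, ordered from water to vacuum.
#' @export
dielectric_ladder <- function(intermediates = c(40, 20, 10, 5, 4.2, 3.5, 2.9,
                                                2.4, 2.0, 1.7, 1.4, 1.2),
                              sa = TRUE) {
  eps <- c(80, as.numeric(intermediates), 1)
  if (any(diff(eps) >= 0)) stop("ladder must be strictly decreasing from 80 to 1")
  out <- tibble::tibble(
    state = paste0("eps", format(eps, trim = TRUE, drop0trailing = TRUE)),
    eps_r = eps,
    sa = c(rep(isTRUE(sa), length(eps) - 1L), FALSE))
  class(out) <- c("dielectric_ladder", class(out))
  out
}

#' Sequentially sample every state of a dielectric ladder at fixed R
#'
#' Runs one fixed-R sampling per ladder state from high to low dielectric;
#' the final conformation of each run seeds the next (one step lower eps_r)
#' run, which keeps successive states equilibrated near each other.
#'
#' @param topology A [chain_topology()].
#' @param ladder A [dielectric_ladder()].
#' @param fixed_R End-to-end distance (nm) to hold.
#' @param protocol A [sampling_protocol()]; per-state seeds are derived from
#'   `protocol$seed` so the whole ladder is reproducible.
#' @param ... Passed to [run_sampling()] (e.g. `fixed_mode`).
#' @return A named list of `frame_set`s, one per ladder state, in ladder
#'   order.
#' @export
sequential_ladder_sampling <- function(topology, ladder, fixed_R, protocol, ...) {
  stopifnot(inherits(ladder, "dielectric_ladder"))
  init <- NULL
  out <- vector("list", nrow(ladder))
  names(out) <- ladder$state
  for (i in seq_len(nrow(ladder))) {
    p <- protocol
    if (!is.null(p$seed)) p$seed <- p$seed + i - 1L
    solv <- solvent_model(eps_r = ladder$eps_r[i], sa = ladder$sa[i])
    fs <- run_sampling(topology, solv, p, fixed_R = fixed_R, init = init, ...)
    fs$provenance$state <- ladder$state[i]
    out[[i]] <- fs
    init <- fs$final
  }
  out
}
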