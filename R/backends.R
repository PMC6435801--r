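#' Construct a hydration free-energy backend
#'
#' A backend supplies a per-conformation hydration free energy
#' dG_hyd(topology, conformation, T, P) in kJ mol^-1 on a declared (T, P)
#' validity domain. Backends are the plug point for external liquid-state
#' theories: anything that can score a conformation (in memory or via an
#' exported table) can correct the GB profile through [fep_reweight()].
#'
#' @param id Identifier string.
#' @param fun Function `(topology, conformation, temperature, pressure,
#'   frame)`; `frame` is the frame id, used by table-based backends.
#' @param T_range,P_range Validity domains (K, bar).
#' @return An object of class `hydration_backend` (callable).
#' @export
hydration_backend <- function(id, fun, T_range = c(1, Inf), P_range = c(0, Inf)) {
  b <- function(topology, conformation, temperature = 298, pressure = 1,
                frame = NULL) {
    if (temperature < T_range[1] || temperature > T_range[2] ||
        pressure < P_range[1] || pressure > P_range[2])
      stop(sprintf("backend '%s' is not defined at T = %g K, P = %g bar",
                   id, temperature, pressure))
    fun(topology, conformation, temperature, pressure, frame)
  }
  structure(b, id = id, T_range = T_range, P_range = P_range,
            class = c("hydration_backend", "function"))
}

#' @export
print.hydration_backend <- function(x, ...) {
  cat(sprintf("<hydration_backend> '%s' (T in [%g, %g] K, P in [%g, %g] bar)\n",
              attr(x, "id"), attr(x, "T_range")[1], attr(x, "T_range")[2],
              attr(x, "P_range")[1], attr(x, "P_range")[2]))
  invisible(x)
}

#' Generalized Born self-consistency backend
#'
#' Returns the package's own GB/SA solvation free energy at a fixed
#' dielectric as a backend; temperature and pressure are ignored. Feeding
#' `gb_backend(80)` to [fep_reweight()] yields an identically zero
#' correction, which closes the thermodynamic cycle exactly.
#'
#' @param eps_r Relative dielectric (>= 1).
#' @param sa Surface-area flag.
#' @return A `hydration_backend`.
#' @export
gb_backend <- function(eps_r = 80, sa = TRUE) {
  solv <- solvent_model(eps_r = eps_r, sa = sa)
  hydration_backend(
    sprintf("GB(eps_r=%g%s)", eps_r, if (sa) "" else ", SA off"),
    function(topology, conformation, temperature, pressure, frame)
      solvation_free_energy(topology, conformation, solv))
}

#' Toy reference backend with explicit temperature and pressure dependence
#'
#' A closed-form stand-in for a molecular-level hydration theory:
#' dG_hyd = GB'(conformation) + gamma(T) A(conformation) + P v_ex(conformation)
#' where GB' is a GB evaluation with rescaled Born radii, gamma(T) =
#' gamma298 (1 + alpha (T - 298)) multiplies the solvent-accessible area A
#' (nm^2), and the excluded volume v_ex = v0 + c_A A (cm^3 mol^-1) gives an
#' exactly linear pressure term (1 bar cm^3/mol = 1e-4 kJ/mol), so
#' d dG_hyd / dP = v_ex * 1e-4 kJ mol^-1 bar^-1 analytically.
#'
#' @param eps_r Dielectric of the GB' part.
#' @param radius_scale Multiplier on the intrinsic Born radii of GB'.
#' @param gamma298 Surface coefficient at 298 K (kJ mol^-1 nm^-2).
#' @param alpha Linear temperature coefficient (K^-1).
#' @param v0 Conformation-independent excluded volume (cm^3 mol^-1).
#' @param c_A Area coefficient of the excluded volume (cm^3 mol^-1 nm^-2).
#' @param T_range,P_range Validity domains.
#' @return A `hydration_backend`.
#' @export
toy_reference_backend <- function(eps_r = 80, radius_scale = 1.1,
                                  gamma298 = 0.02, alpha = 0.002,
                                  v0 = 10, c_A = 5,
                                  T_range = c(250, 450), P_range = c(0, 20000)) {
  hydration_backend(
    "toy-reference",
    function(topology, conformation, temperature, pressure, frame) {
      top2 <- topology
      top2$born_radius <- topology$born_radius * radius_scale
      gb <- solvation_free_energy(top2, conformation,
                                  solvent_model(eps_r = eps_r, sa = FALSE))
      A <- total_sasa(topology, conformation)
      gam <- gamma298 * (1 + alpha * (temperature - 298))
      vex <- v0 + c_A * A
      gb + gam * A + pressure * vex * 1e-4
    },
    T_range = T_range, P_range = P_range)
}

#' Excluded volume used by the toy reference backend
#'
#' @inheritParams intramolecular_energy
#' @param v0,c_A As in [toy_reference_backend()].
#' @return v_ex in cm^3 mol^-1.
#' @export
toy_backend_vex <- function(topology, conformation, v0 = 10, c_A = 5) {
  v0 + c_A * total_sasa(topology, conformation)
}

#' Table-based backend: ingest externally computed hydration energies
#'
#' Reads a TSV of per-frame hydration free energies (columns `frame`,
#' `temperature`, `pressure`, `dG_hyd`; `#`-prefixed metadata lines allowed)
#' and serves them by exact (frame, T, P) lookup, so full-fidelity external
#' model outputs can drive the reweighting step.
#'
#' @param file Path to the TSV.
#' @return A `hydration_backend` whose callable requires `frame`.
#' @export
table_backend <- function(file) {
  tab <- read_energy_table(file)
  need <- c("frame", "temperature", "pressure", "dG_hyd")
  if (!all(need %in% names(tab)))
    stop("backend table must have columns: ", paste(need, collapse = ", "))
  key <- paste(tab$frame, tab$temperature, tab$pressure)
  vals <- setNames(tab$dG_hyd, key)
  hydration_backend(
    paste0("table:", basename(file)),
    function(topology, conformation, temperature, pressure, frame) {
      if (is.null(frame)) stop("table backend needs a frame id")
      k <- paste(frame, temperature, pressure)
      hit <- vals[k]
      if (any(is.na(match(k, key))))
        stop(sprintf("no table entry for frame %s at T = %g K, P = %g bar",
                     paste(frame[is.na(match(k, key))], collapse = ","),
                     temperature, pressure))
      unname(hit)
    },
    T_range = range(tab$temperature), P_range = range(tab$pressure))
}

#' Evaluate a backend over every frame of a frame set
#'
#' @param backend A `hydration_backend`.
#' @param topology The sampled [chain_topology()].
#' @param frame_set A `frame_set` (frames sampled at eps_r = 80).
#' @param temperature,pressure Evaluation state.
#' @return Numeric vector of dG_hyd per frame (kJ mol^-1).
#' @export
backend_evaluate <- function(backend, topology, frame_set, temperature = 298,
                             pressure = 1) {
  stopifnot(inherits(backend, "hydration_backend"))
  nf <- n_frames(frame_set)
  vapply(seq_len(nf), function(f) {
    backend(topology, frame_set$frames[, , f, drop = TRUE],
            temperature = temperature, pressure = pressure, frame = f)
  }, numeric(1))
}
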