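#' Run configuration for the full decomposition pipeline
#'
#' Collects every knob of the umbrella-sampling + ladder + reweighting
#' workflow. The reference configuration mirrors the production-scale
#' protocol this method was designed around (0.0125 nm window spacing, 208
#' windows, k = 1875 kJ mol^-1 nm^-2, the twelve-intermediate dielectric
#' ladder, five-block errors, folded state at R = 0.5 and 0.6 nm, zero
#' reference at 0.5 nm); toy-scale runs override the sizes.
#'
#' @param R_min First umbrella window centre (nm).
#' @param spacing Window spacing (nm, > 0).
#' @param n_windows Number of windows (>= 1).
#' @param umbrella_k Umbrella force constant (kJ mol^-1 nm^-2).
#' @param ladder A [dielectric_ladder()].
#' @param protocol A [sampling_protocol()] (shared sizes; per-run seeds are
#'   derived from its seed).
#' @param fep_grid R values (nm) where the ladder/reweighting legs are
#'   evaluated; defaults to every other window centre.
#' @param temperatures,pressures Conditions to analyse (K, bar).
#' @param folded_R Folded-state distances (nm).
#' @param R_ref Zero-reference distance (nm).
#' @param n_boot WHAM bootstrap replicates.
#' @param n_blocks Blocks for FEP standard errors.
#' @param fixed_mode Fixed-R mode for ladder ensembles
#'   (see [run_sampling()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(R_min = 0.5, spacing = 0.0125, n_windows = 208,
                       umbrella_k = 1875, ladder = dielectric_ladder(),
                       protocol = sampling_protocol(),
                       fep_grid = NULL, temperatures = 298, pressures = 1,
                       folded_R = c(0.5, 0.6), R_ref = 0.5,
                       n_boot = 50, n_blocks = 5,
                       fixed_mode = "restrain") {
  stopifnot(spacing > 0, n_windows >= 1, umbrella_k > 0)
  centers <- R_min + spacing * (seq_len(n_windows) - 1L)
  if (is.null(fep_grid))
    fep_grid <- centers[seq(1, n_windows, by = max(1, n_windows %/% 20))]
  structure(list(R_min = R_min, spacing = spacing, n_windows = n_windows,
                 umbrella_k = umbrella_k, centers = centers, ladder = ladder,
                 protocol = protocol, fep_grid = fep_grid,
                 temperatures = temperatures, pressures = pressures,
                 folded_R = folded_R, R_ref = R_ref, n_boot = n_boot,
                 n_blocks = n_blocks, fixed_mode = fixed_mode),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d windows from %g nm, spacing %g nm, k = %g\n",
              x$n_windows, x$R_min, x$spacing, x$umbrella_k))
  cat(sprintf("  ladder: %d states; FEP grid: %d points; T = %s K; P = %s bar\n",
              nrow(x$ladder), length(x$fep_grid),
              paste(x$temperatures, collapse = "/"),
              paste(x$pressures, collapse = "/")))
  invisible(x)
}

# ladder + reweighting legs at one temperature; returns per-R tables and the
# water-state frame sets (reused for backend pressure scans)
ladder_leg <- function(topology, config, temperature) {
  p <- config$protocol
  p$temperature <- temperature
  purrr::map(seq_along(config$fep_grid), function(i) {
    pi <- p
    if (!is.null(pi$seed)) pi$seed <- pi$seed + 100L * i + as.integer(temperature)
    fss <- sequential_ladder_sampling(topology, config$ladder, config$fep_grid[i],
                                      pi, fixed_mode = config$fixed_mode)
    list(R = config$fep_grid[i], frames = fss,
         table = ladder_energy_table(fss, topology, config$ladder))
  })
}

#' Full free-energy decomposition at one thermodynamic state
#'
#' Runs the complete workflow on one topology: umbrella sampling + WHAM for
#' F_GB(R); the sequential bidirectional dielectric ladder for mu_ex^GB(R)
#' at each FEP grid point; backend reweighting for dmu_ref(R); the
#' charge-zeroed route for mu_nonpol(R); and the vacuum ensembles (the
#' ladder's eps_r = 1 state, reused) for E_intra(R). F_GB is resampled onto
#' the FEP grid before assembly. Pressure is scanned by re-evaluating only
#' the backend reweighting on the shared eps_r = 80 ensembles.
#'
#' @param topology A [chain_topology()].
#' @param backend A `hydration_backend`.
#' @param config A [run_config()].
#' @param temperature Temperature (K).
#' @param pressures Pressures (bar) to evaluate (default from config).
#' @return A named list of `decomposed_profiles`, one per pressure
#'   (names = pressure values).
#' @export
decompose_pipeline <- function(topology, backend, config,
                               temperature = config$temperatures[1],
                               pressures = config$pressures) {
  p <- config$protocol
  p$temperature <- temperature

  # Leg 1: umbrella sampling + WHAM
  frames_w <- umbrella_run(topology, solvent_model(80, sa = TRUE),
                           config$centers, p, k = config$umbrella_k)
  breaks <- seq(config$R_min - config$spacing / 2,
                max(config$centers) + 10 * config$spacing, by = config$spacing)
  f_gb <- wham_profile(frames_w, breaks = breaks, n_boot = config$n_boot,
                       seed = if (!is.null(p$seed)) p$seed + 7L else NULL)
  f_gb_grid <- profile_resample(f_gb, config$fep_grid)

  # Leg 2: dielectric ladder at each grid R
  leg <- ladder_leg(topology, config, temperature)
  mu_vals <- purrr::map(leg, function(l)
    fep_bidirectional_ladder(l$table, config$ladder, temperature, config$n_blocks))
  mu_ex_gb <- fe_profile(config$fep_grid,
                         purrr::map_dbl(mu_vals, "value"),
                         purrr::map_dbl(mu_vals, "stderr"),
                         temperature = temperature, component = "mu_ex_gb")

  # Leg 4 input: vacuum ensembles are the ladder's final state, reused
  vac_state <- config$ladder$state[nrow(config$ladder)]
  e_intra <- intramolecular_energy_profile(
    purrr::map(leg, function(l) l$frames[[vac_state]]),
    topology, config$fep_grid, temperature, config$n_blocks)

  # Leg 5: charge-zeroed nonpolar route
  top0 <- zero_charges(topology)
  mu_nonpol <- purrr::map(pressures, function(P)
    nonpolar_profile(top0, config$fep_grid, p, backend,
                     temperature = temperature, pressure = P,
                     n_blocks = config$n_blocks, fixed_mode = config$fixed_mode))

  # Leg 3 + assembly per pressure (shared ensembles, backend varies)
  water_state <- config$ladder$state[1]
  out <- purrr::imap(setNames(pressures, pressures), function(P, nm) {
    rw <- purrr::map(leg, function(l) {
      fs <- l$frames[[water_state]]
      dG_hyd <- backend_evaluate(backend, topology, fs,
                                 temperature = temperature, pressure = P)
      dG_gb <- l$table[l$table$state == water_state, ][[state_col(water_state)]]
      fep_reweight(dG_hyd, dG_gb, temperature, config$n_blocks)
    })
    dmu <- fe_profile(config$fep_grid, purrr::map_dbl(rw, "value"),
                      purrr::map_dbl(rw, "stderr"),
                      temperature = temperature, pressure = P,
                      component = "dmu_ref")
    dec <- assemble_cycle(f_gb_grid, mu_ex_gb, dmu, R_ref = config$R_ref)
    dec <- add_nonpolar(dec, mu_nonpol[[match(P, pressures)]])
    add_intramolecular(dec, e_intra)
  })
  out
}

#' Unfolding thermodynamics across the configured conditions
#'
#' Applies [unfolding_free_energy()] to the total profile F of every
#' decomposed result, and where several pressures are present estimates the
#' partial molar volume change from the pressure slope.
#'
#' @param decomposed_list Named nested list: `decomposed[[T]][[P]]` or a flat
#'   named list of `decomposed_profiles`.
#' @param folded_R Folded-state distances (nm).
#' @param seed Seed for the error resampling.
#' @return A list with `dFu` (tibble per condition) and `dV` (tibble or
#'   NULL).
#' @export
thermo_summary <- function(decomposed_list, folded_R = c(0.5, 0.6), seed = NULL) {
  flat <- list()
  for (x in decomposed_list) {
    if (inherits(x, "decomposed_profiles")) flat[[length(flat) + 1L]] <- x
    else for (y in x) flat[[length(flat) + 1L]] <- y
  }
  dfu <- purrr::map_dfr(flat, function(d)
    unfolding_free_energy(d$profiles$F, folded_R = folded_R, seed = seed))
  dv <- NULL
  for (Tk in unique(dfu$temperature)) {
    sub <- dfu[dfu$temperature == Tk, ]
    if (length(unique(sub$pressure)) >= 2) {
      v <- partial_molar_volume(sub$dFu, sub$pressure, temperature = Tk)
      v$temperature <- Tk
      dv <- dplyr::bind_rows(dv, v)
    }
  }
  list(dFu = dfu, dV = dv)
}
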