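new_decomposed_profiles <- function(profiles, temperature, pressure, R_ref) {
  structure(list(profiles = profiles, temperature = temperature,
                 pressure = pressure, R_ref = R_ref),
            class = "decomposed_profiles")
}

#' @export
print.decomposed_profiles <- function(x, ...) {
  cat(sprintf("<decomposed_profiles> at %g K, %g bar; zero at R = %g nm\n",
              x$temperature, x$pressure, x$R_ref))
  cat("  components:", paste(names(x$profiles), collapse = ", "), "\n")
  cat(sprintf("  grid: %d points, R in [%g, %g] nm\n",
              nrow(x$profiles[[1]]), min(x$profiles[[1]]$R), max(x$profiles[[1]]$R)))
  invisible(x)
}

#' @export
tidy.decomposed_profiles <- function(x, ...) {
  purrr::imap_dfr(x$profiles, function(p, nm)
    tibble::tibble(component = nm, R = p$R, value = p$value, stderr = p$stderr))
}

#' @export
glance.decomposed_profiles <- function(x, ...) {
  res <- function(a, b, cc) if (all(c(a, b, cc) %in% names(x$profiles)))
    max(abs(x$profiles[[a]]$value - x$profiles[[b]]$value - x$profiles[[cc]]$value),
        na.rm = TRUE) else NA_real_
  tibble::tibble(
    temperature = x$temperature, pressure = x$pressure, R_ref = x$R_ref,
    n_grid = nrow(x$profiles[[1]]),
    closure_F = res("F", "F_vac", "mu_ex"),
    closure_mu = res("mu_ex", "mu_nonpol", "mu_pol"),
    closure_Fvac = res("F_vac", "E_intra", "neg_TS_intra"))
}

#' Assemble the thermodynamic cycle from its three measured legs
#'
#' Given the umbrella-sampling profile F_GB(R), the dielectric-ladder excess
#' chemical potential mu_ex^GB(R) and the backend reweighting correction
#' dmu_ref(R), builds: F_vac = F_GB - mu_ex^GB, F = F_GB + dmu_ref and
#' mu_ex = mu_ex^GB + dmu_ref, so the closure F = F_vac + mu_ex holds bin
#' for bin by construction. Errors combine in quadrature. All inputs must
#' share one grid ([profile_resample()] is the explicit prior step) and are
#' shifted to a common zero reference.
#'
#' @param f_gb,mu_ex_gb,dmu_ref [fe_profile()]s on a common grid (k_B T).
#' @param R_ref Zero-reference distance (nm), default 0.5.
#' @return A `decomposed_profiles` object holding F, F_GB, F_vac, mu_ex,
#'   mu_ex_gb and dmu_ref.
#' @export
assemble_cycle <- function(f_gb, mu_ex_gb, dmu_ref, R_ref = 0.5) {
  check_same_grid(f_gb, mu_ex_gb); check_same_grid(f_gb, dmu_ref)
  relabel <- function(p, cc) { attr(p, "component") <- cc; p }
  pr <- list(
    F_GB = relabel(f_gb, "F_GB"),
    mu_ex_gb = relabel(mu_ex_gb, "mu_ex_gb"),
    dmu_ref = relabel(dmu_ref, "dmu_ref"),
    F_vac = profile_combine(f_gb, mu_ex_gb, `-`, component = "F_vac"),
    F = profile_combine(f_gb, dmu_ref, `+`, component = "F"),
    mu_ex = profile_combine(mu_ex_gb, dmu_ref, `+`, component = "mu_ex"))
  pr <- lapply(pr, profile_shift, R_ref = R_ref)
  press <- attr(dmu_ref, "pressure") %||% attr(f_gb, "pressure")
  pr <- lapply(pr, function(p) { attr(p, "pressure") <- press; p })
  new_decomposed_profiles(pr, attr(f_gb, "temperature"), press, R_ref)
}

#' Attach the nonpolar / polar split
#'
#' mu_nonpol comes from the charge-zeroed route; mu_pol = mu_ex - mu_nonpol
#' fills the polar remainder so the split is exact by construction.
#'
#' @param decomposed A `decomposed_profiles` from [assemble_cycle()].
#' @param mu_nonpol [fe_profile()] on the same grid.
#' @return The augmented `decomposed_profiles`.
#' @export
add_nonpolar <- function(decomposed, mu_nonpol) {
  check_same_grid(decomposed$profiles$mu_ex, mu_nonpol)
  mu_nonpol <- profile_shift(mu_nonpol, decomposed$R_ref)
  attr(mu_nonpol, "component") <- "mu_nonpol"
  decomposed$profiles$mu_nonpol <- mu_nonpol
  decomposed$profiles$mu_pol <-
    profile_combine(decomposed$profiles$mu_ex, mu_nonpol, `-`, component = "mu_pol")
  decomposed
}

#' Attach the vacuum energy / entropy split
#'
#' E_intra(R) is the mean intramolecular energy over the vacuum fixed-R
#' ensemble; the conformational-entropy term -T S_intra = F_vac - E_intra is
#' the exact remainder.
#'
#' @param decomposed A `decomposed_profiles`.
#' @param e_intra [fe_profile()] of mean vacuum intramolecular energy (k_B T)
#'   on the same grid.
#' @return The augmented `decomposed_profiles`.
#' @export
add_intramolecular <- function(decomposed, e_intra) {
  check_same_grid(decomposed$profiles$F_vac, e_intra)
  e_intra <- profile_shift(e_intra, decomposed$R_ref)
  attr(e_intra, "component") <- "E_intra"
  decomposed$profiles$E_intra <- e_intra
  decomposed$profiles$neg_TS_intra <-
    profile_combine(decomposed$profiles$F_vac, e_intra, `-`,
                    component = "neg_TS_intra")
  decomposed
}

#' Mean intramolecular energy profile from vacuum fixed-R ensembles
#'
#' @param vacuum_frames Named list (by grid point) of vacuum `frame_set`s.
#' @param topology The [chain_topology()].
#' @param grid R grid (nm) matching `vacuum_frames` order.
#' @param temperature Temperature (K).
#' @param n_blocks Blocks for the standard error of the mean.
#' @return An [fe_profile()] of E_intra (k_B T), unshifted.
#' @export
intramolecular_energy_profile <- function(vacuum_frames, topology, grid,
                                          temperature = 298, n_blocks = 5) {
  if (length(vacuum_frames) != length(grid))
    stop("one vacuum ensemble is required per grid point")
  kt <- kT(temperature)
  vals <- ses <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fs <- vacuum_frames[[i]]
    if (is.null(fs)) stop(sprintf("missing vacuum ensemble at R = %g nm", grid[i]))
    e <- eval_frames(fs$frames, topology, what = "intra") / kt
    vals[i] <- mean(e)
    ses[i] <- if (length(e) >= n_blocks)
      block_standard_error(e, n_blocks, estimator = mean) else 0
  }
  fe_profile(grid, vals, ses, temperature = temperature, component = "E_intra")
}

#' Nonpolar excess chemical potential via the charge-zeroed route
#'
#' Samples the charge-zeroed solute at each grid R in vacuum (eps_r = 1) and
#' with only the nonpolar surface term (eps_r = 80, charges absent), takes
#' the single bidirectional perturbation step between the two states, and
#' adds the charge-zeroed backend reweighting correction.
#'
#' @param topology_zero A charge-zeroed [chain_topology()] (error otherwise).
#' @param grid R grid (nm).
#' @param protocol A [sampling_protocol()].
#' @param backend A `hydration_backend` evaluated on the uncharged solute.
#' @param temperature,pressure Thermodynamic state.
#' @param n_blocks Blocks for standard errors.
#' @param ... Passed to [run_sampling()] / [sequential_ladder_sampling()].
#' @return An [fe_profile()] of mu_nonpol (k_B T), unshifted.
#' @export
nonpolar_profile <- function(topology_zero, grid, protocol, backend,
                             temperature = protocol$temperature, pressure = 1,
                             n_blocks = 5, ...) {
  if (any(topology_zero$charge != 0))
    stop("the nonpolar route requires a charge-zeroed topology; see zero_charges()")
  two_state <- dielectric_ladder(intermediates = numeric(0))  # 80 <-> 1, no ladder
  vals <- ses <- numeric(length(grid))
  for (i in seq_along(grid)) {
    p <- protocol
    p$temperature <- temperature
    if (!is.null(p$seed)) p$seed <- p$seed + 10000L * i
    fss <- sequential_ladder_sampling(topology_zero, two_state, grid[i], p, ...)
    tab <- ladder_energy_table(fss, topology_zero, two_state)
    bi <- fep_bidirectional_ladder(tab, two_state, temperature, n_blocks)
    dG_hyd <- backend_evaluate(backend, topology_zero, fss[[1]],
                               temperature = temperature, pressure = pressure)
    dG_gb <- tab[tab$state == two_state$state[1], ][[state_col(two_state$state[1])]]
    rw <- fep_reweight(dG_hyd, dG_gb, temperature, n_blocks)
    vals[i] <- bi$value + rw$value
    ses[i] <- sqrt(bi$stderr^2 + rw$stderr^2)
  }
  fe_profile(grid, vals, ses, temperature = temperature, pressure = pressure,
             component = "mu_nonpol")
}

delta_pair <- function(p1, p2, label) {
  check_same_grid(p1, p2)
  tibble::tibble(component = label, R = p1$R, value = p2$value - p1$value,
                 stderr = sqrt(p1$stderr^2 + p2$stderr^2))
}

#' Temperature-difference profiles
#'
#' For each shared component, Delta_T X(R) = X(R, T2)/k_B T2 - X(R, T1)/k_B T1
#' (profiles are already in their own k_B T units). The component additivity
#' Delta_T F = Delta_T F_vac + Delta_T mu_ex (and the nonpolar/polar split)
#' carries over exactly.
#'
#' @param dec1,dec2 `decomposed_profiles` at two temperatures on a shared
#'   grid with the same zero reference.
#' @return A tibble (component, R, value, stderr), dimensionless.
#' @export
delta_T_profiles <- function(dec1, dec2) {
  if (!isTRUE(all.equal(dec1$R_ref, dec2$R_ref)))
    stop("zero references differ between the two temperature sets")
  shared <- intersect(names(dec1$profiles), names(dec2$profiles))
  purrr::map_dfr(shared, function(nm)
    delta_pair(dec1$profiles[[nm]], dec2$profiles[[nm]], nm))
}

#' Pressure-difference profiles
#'
#' Pressure enters only through the backend reweighting, so the vacuum leg is
#' pressure independent and Delta_P F = Delta_P mu_ex is enforced as an
#' identity; the nonpolar and polar splits are returned alongside.
#'
#' @param dec1,dec2 `decomposed_profiles` at two pressures (same temperature,
#'   shared sampling ensembles and grid).
#' @return A tibble (component, R, value, stderr), dimensionless.
#' @export
delta_P_profiles <- function(dec1, dec2) {
  if (!isTRUE(all.equal(dec1$temperature, dec2$temperature)))
    stop("pressure differencing requires a shared temperature")
  if (!isTRUE(all.equal(dec1$R_ref, dec2$R_ref)))
    stop("zero references differ between the two pressure sets")
  dmu <- delta_pair(dec1$profiles$mu_ex, dec2$profiles$mu_ex, "mu_ex")
  out <- dplyr::bind_rows(
    dplyr::mutate(dmu, component = "F"),   # F_vac is pressure independent
    dmu)
  for (nm in intersect(c("mu_nonpol", "mu_pol"), names(dec1$profiles)))
    out <- dplyr::bind_rows(out, delta_pair(dec1$profiles[[nm]],
                                            dec2$profiles[[nm]], nm))
  out
}

#' Unfolding free energy from a profile
#'
#' Folded-state probability p_f is the sum of Boltzmann weights
#' w(R) proportional to exp(-F(R)/k_B T) over the folded grid points
#' (nearest-bin match); the unfolded probability p_u sums every other
#' non-missing grid point in the sampled range. Returns
#' Delta F_u = ln(p_f/p_u) in k_B T, so positive values mean the folded
#' state is the more stable one. Errors come from resampling the profile
#' within its per-bin standard errors.
#'
#' @param profile An [fe_profile()] (values in k_B T).
#' @param folded_R Distances (nm) defining the folded state (default the
#'   native-plus-misfolded convention 0.5 and 0.6 nm).
#' @param n_boot Profile-replicate resamples for the error (0 to skip).
#' @param seed Seed for the resampling.
#' @return A tibble with `dFu`, `stderr` (k_B T), `p_folded`, `temperature`,
#'   `pressure`.
#' @export
unfolding_free_energy <- function(profile, folded_R = c(0.5, 0.6),
                                  n_boot = 200, seed = NULL) {
  stopifnot(inherits(profile, "fe_profile"))
  ok <- which(!is.na(profile$value))
  if (!length(ok)) stop("profile has no usable bins")
  idx_f <- unique(vapply(folded_R, function(r) {
    i <- which.min(abs(profile$R - r))
    if (abs(profile$R[i] - r) > 1.01 * max(diff(profile$R)))
      stop(sprintf("folded-state distance %g nm is outside the profile grid", r))
    i
  }, integer(1)))
  idx_f <- intersect(idx_f, ok)
  if (!length(idx_f)) stop("folded-state bins are all missing")
  idx_u <- setdiff(ok, idx_f)
  if (!length(idx_u)) stop("no unfolded bins remain in the sampled range")
  weights_of <- function(v) exp(-(v - min(v[ok], na.rm = TRUE)))
  dfu_of <- function(v) {
    w <- weights_of(v)
    pf <- sum(w[idx_f]); pu <- sum(w[idx_u])
    if (pf <= 0 || pu <= 0 || !is.finite(pf) || !is.finite(pu))
      stop("degenerate profile: folded or unfolded probability is numerically 0")
    log(pf / pu)
  }
  dfu <- dfu_of(profile$value)
  se <- NA_real_
  if (n_boot > 0 && any(profile$stderr > 0, na.rm = TRUE)) {
    if (!is.null(seed)) set.seed(seed)
    sds <- ifelse(is.na(profile$stderr), 0, profile$stderr)
    reps <- vapply(seq_len(n_boot), function(b)
      dfu_of(profile$value + rnorm(length(sds), 0, sds)), numeric(1))
    se <- sd(reps)
  }
  w0 <- weights_of(profile$value)
  tibble::tibble(dFu = dfu, stderr = se,
                 p_folded = sum(w0[idx_f]) / (sum(w0[idx_f]) + sum(w0[idx_u])),
                 temperature = attr(profile, "temperature"),
                 pressure = attr(profile, "pressure"))
}

#' Relative stabilisation of the unfolded state by heating
#'
#' Delta_T F_u = Delta F_u(T2)/k_B T2 - Delta F_u(T1)/k_B T1, with both
#' inputs already dimensionless (k_B T units at their own temperatures).
#'
#' @param dFu_T1,dFu_T2 Unfolding free energies (k_B T) at the lower and
#'   higher temperature.
#' @return Dimensionless difference.
#' @export
delta_T_unfolding <- function(dFu_T1, dFu_T2) dFu_T2 - dFu_T1

#' Partial molar volume change from the pressure dependence of Delta F_u
#'
#' Least-squares slope of Delta F_u k_B T (J mol^-1) against pressure (bar),
#' converted with 1 J mol^-1 bar^-1 = 10 cm^3 mol^-1. Negative values mean
#' pressure stabilises the unfolded state.
#'
#' @param dFu Unfolding free energies (k_B T) at each pressure.
#' @param pressure Pressures (bar), at least two distinct values.
#' @param temperature Temperature (K) used to convert k_B T to J mol^-1.
#' @return A tibble with `dV_cm3_mol` and its standard error (NA with only
#'   two pressures).
#' @export
partial_molar_volume <- function(dFu, pressure, temperature = 298) {
  if (length(unique(pressure)) < 2)
    stop("at least two pressures are needed for a volume estimate")
  if (length(dFu) != length(pressure)) stop("dFu and pressure lengths differ")
  y <- dFu * kT(temperature) * 1000          # J mol^-1
  fit <- lm(y ~ pressure)
  slope <- coef(fit)[["pressure"]]           # J mol^-1 bar^-1
  se <- if (length(pressure) > 2)
    suppressWarnings(summary(fit)$coefficients["pressure", 2]) else NA_real_
  tibble::tibble(dV_cm3_mol = slope * 10, stderr = se * 10)
}
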