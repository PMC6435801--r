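# log of mean(exp(x)), overflow-safe
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

new_fep_result <- function(value, stderr, n, n_eff, from, to, low_overlap = FALSE,
                           detail = NULL) {
  structure(list(value = value, stderr = stderr, n = n, n_eff = n_eff,
                 from = from, to = to, low_overlap = low_overlap,
                 detail = detail),
            class = "fep_result")
}

#' @export
print.fep_result <- function(x, ...) {
  cat(sprintf("<fep_result> %s -> %s: %.6g +/- %.3g kT (n = %d, n_eff = %.1f)%s\n",
              x$from, x$to, x$value, x$stderr, x$n, x$n_eff,
              if (x$low_overlap) "  [low overlap]" else ""))
  invisible(x)
}

#' Block standard error of an exponential-average estimator
#'
#' The per-frame exponent series is split into `n_blocks` contiguous equal
#' blocks (default 5), the estimator is recomputed on each block, and the
#' standard error is sd(block estimates)/sqrt(n_blocks). With a reference
#' ensemble of 5000 frames this is the conventional five-block error.
#'
#' @param x Per-frame exponent series (the -ddG/kT values the estimator
#'   averages exp() of).
#' @param n_blocks Number of contiguous blocks (>= 2).
#' @param estimator Function applied to each block (default the free-energy
#'   estimator -log mean exp).
#' @return Standard error (same units as the estimator).
#' @export
block_standard_error <- function(x, n_blocks = 5,
                                 estimator = function(b) -log_mean_exp(b)) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  n <- length(x)
  if (n < n_blocks) stop("fewer frames than blocks")
  idx <- split(seq_len(n), ceiling(seq_len(n) / (n / n_blocks)))
  est <- vapply(idx, function(i) estimator(x[i]), numeric(1))
  sd(est) / sqrt(length(est))
}

#' One-step free-energy perturbation between two Hamiltonians
#'
#' Estimates Delta mu = -k_B T ln < exp(-(G_target - G_sampled)/k_B T) >
#' over frames drawn from the sampled state, in k_B T units, with
#' log-sum-exp stabilisation. Reports the exponential-weight effective
#' sample size n_eff = (sum w)^2 / sum w^2 and flags results whose n_eff
#' falls below `n_eff_floor`.
#'
#' @param dG_target Per-frame energy of the target state (kJ mol^-1).
#' @param dG_sampled Per-frame energy of the sampled state (kJ mol^-1).
#' @param temperature Temperature (K).
#' @param n_blocks Contiguous blocks for the standard error.
#' @param n_eff_floor Overlap warning threshold.
#' @param from,to State labels recorded in the result.
#' @return A `fep_result`: value and standard error in k_B T, frame count,
#'   effective sample size and direction metadata.
#' @export
fep_one_step <- function(dG_target, dG_sampled, temperature = 298,
                         n_blocks = 5, n_eff_floor = 50,
                         from = "sampled", to = "target") {
  n <- length(dG_sampled)
  if (n == 0) stop("empty frame set")
  if (length(dG_target) != n) stop("energy columns have different frame counts")
  x <- -(dG_target - dG_sampled) / kT(temperature)
  w <- exp(x - max(x))
  n_eff <- sum(w)^2 / sum(w^2)
  value <- -log_mean_exp(x)
  stderr <- if (n >= n_blocks) block_standard_error(x, n_blocks) else NA_real_
  low <- n_eff < n_eff_floor && any(x != x[1])
  if (low)
    warning(sprintf("FEP %s -> %s: effective sample size %.1f below %g",
                    from, to, n_eff, n_eff_floor), call. = FALSE)
  new_fep_result(value, stderr, n, n_eff, from, to, low_overlap = low)
}

state_col <- function(state) paste0("dG_", state)

#' Bidirectional dielectric-ladder estimate of the excess chemical potential
#'
#' For each adjacent ladder pair the forward and reverse one-step
#' perturbations are averaged, each step taken in the hydration direction
#' (sampled at the lower dielectric targeting the higher one, minus the
#' reverse, over two), and the steps are summed. The telescoped total is
#' Delta G_solv(80) - Delta G_solv(1), i.e. mu_ex^GB = F_GB - F_vac, the
#' solvation free energy at fixed R including conformational relaxation.
#' Step errors combine in quadrature.
#'
#' @param table Per-frame energy table: a tibble with columns `state` (the
#'   sampled ladder state label), `frame`, and one `dG_<state>` column per
#'   evaluated ladder state (kJ mol^-1), as built by [ladder_energy_table()].
#' @param ladder A [dielectric_ladder()].
#' @param temperature Temperature (K).
#' @param n_blocks,n_eff_floor Passed to [fep_one_step()].
#' @return A `fep_result` for mu_ex^GB (k_B T) with a per-step tibble in
#'   `$detail`.
#' @export
fep_bidirectional_ladder <- function(table, ladder, temperature = 298,
                                     n_blocks = 5, n_eff_floor = 50) {
  stopifnot(inherits(ladder, "dielectric_ladder"))
  states <- ladder$state
  missing <- setdiff(states, unique(table$state))
  if (length(missing))
    stop("per-frame table is missing sampled ladder state(s): ",
         paste(missing, collapse = ", "))
  steps <- purrr::map_dfr(seq_len(nrow(ladder) - 1L), function(a) {
    hi <- states[a]; lo <- states[a + 1L]       # ladder runs water -> vacuum
    th <- table[table$state == hi, ]
    tl <- table[table$state == lo, ]
    for (cc in c(state_col(hi), state_col(lo)))
      if (!cc %in% names(table)) stop("missing energy column ", cc)
    fwd <- fep_one_step(tl[[state_col(hi)]], tl[[state_col(lo)]], temperature,
                        n_blocks, n_eff_floor, from = lo, to = hi)
    rev <- fep_one_step(th[[state_col(lo)]], th[[state_col(hi)]], temperature,
                        n_blocks, n_eff_floor, from = hi, to = lo)
    tibble::tibble(upper = hi, lower = lo,
                   forward = fwd$value, reverse = rev$value,
                   value = (fwd$value - rev$value) / 2,
                   stderr = sqrt(fwd$stderr^2 + rev$stderr^2) / 2,
                   n_eff = min(fwd$n_eff, rev$n_eff),
                   low_overlap = fwd$low_overlap || rev$low_overlap)
  })
  new_fep_result(sum(steps$value), sqrt(sum(steps$stderr^2)),
                 n = nrow(table), n_eff = min(steps$n_eff),
                 from = states[length(states)], to = states[1],
                 low_overlap = any(steps$low_overlap), detail = steps)
}

#' Reweight the water-dielectric ensemble to a reference hydration model
#'
#' Computes Delta mu_ref^GB(R; T, P) =
#' -k_B T ln < exp(-(dG_hyd - dG_solv^GB(80)) / k_B T) > over frames sampled
#' at eps_r = 80, i.e. the correction from the generalized Born description
#' of hydration to an arbitrary backend description at the requested
#' temperature and pressure. The effective sample size guards against poor
#' configurational overlap between the two descriptions.
#'
#' @param dG_hyd Per-frame backend hydration free energies (kJ mol^-1).
#' @param dG_gb Per-frame GB solvation free energies at eps_r = 80
#'   (kJ mol^-1).
#' @inheritParams fep_one_step
#' @return A `fep_result` (k_B T).
#' @export
fep_reweight <- function(dG_hyd, dG_gb, temperature = 298, n_blocks = 5,
                         n_eff_floor = 50) {
  fep_one_step(dG_hyd, dG_gb, temperature, n_blocks, n_eff_floor,
               from = "GB(80)", to = "reference")
}

#' Per-frame ladder energy table from sampled frame sets
#'
#' Evaluates the solvation free energy of every frame of every sampled
#' ladder state at every ladder state's Hamiltonian, producing the tidy
#' table the FEP estimators consume.
#'
#' @param frame_sets Named list of `frame_set`s from
#'   [sequential_ladder_sampling()] (names = ladder state labels).
#' @param topology The sampled [chain_topology()].
#' @param ladder The [dielectric_ladder()].
#' @return A tibble with columns `state`, `frame`, `R` and one
#'   `dG_<state>` column per ladder state (kJ mol^-1).
#' @export
ladder_energy_table <- function(frame_sets, topology, ladder) {
  stopifnot(inherits(ladder, "dielectric_ladder"))
  purrr::map_dfr(ladder$state, function(s) {
    fs <- frame_sets[[s]]
    if (is.null(fs)) stop("no frame set for ladder state ", s)
    row <- tibble::tibble(state = s, frame = seq_along(fs$R), R = fs$R)
    for (i in seq_len(nrow(ladder))) {
      solv <- solvent_model(eps_r = ladder$eps_r[i], sa = ladder$sa[i])
      row[[state_col(ladder$state[i])]] <- eval_frames(fs$frames, topology, solv)
    }
    row
  })
}

#' @export
tidy.fep_result <- function(x, ...) {
  if (!is.null(x$detail)) return(x$detail)
  tibble::tibble(from = x$from, to = x$to, value = x$value, stderr = x$stderr,
                 n = x$n, n_eff = x$n_eff)
}

#' @export
glance.fep_result <- function(x, ...) {
  tibble::tibble(value = x$value, stderr = x$stderr, n = x$n, n_eff = x$n_eff,
                 low_overlap = x$low_overlap)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
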