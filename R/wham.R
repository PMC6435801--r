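#' Bin umbrella-window frame sets into a common histogram set
#'
#' @param frame_sets List of `frame_set`s produced under umbrella bias.
#' @param windows List of the matching [umbrella_window()]s (defaults to the
#'   windows recorded in each frame set's provenance).
#' @param breaks Common bin edges (nm). Default: bins of width equal to the
#'   window spacing, spanning all windows.
#' @param temperature Temperature (K); defaults to the first frame set's.
#' @return An object of class `umbrella_histograms`: list with `breaks`,
#'   `mids`, `counts` (windows x bins), `windows` (tibble of centre, k) and
#'   `temperature`.
#' @export
bin_histograms <- function(frame_sets, windows = NULL, breaks = NULL,
                           temperature = NULL) {
  if (is.null(windows))
    windows <- lapply(frame_sets, function(f) f$provenance$window)
  if (any(vapply(windows, is.null, logical(1))))
    stop("every frame set needs an umbrella window")
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ks <- vapply(windows, `[[`, numeric(1), "k")
  if (is.null(breaks)) {
    sp <- if (length(centers) > 1) min(diff(sort(centers))) else 0.0125
    rng <- range(unlist(lapply(frame_sets, `[[`, "R")))
    breaks <- seq(floor(rng[1] / sp) * sp - sp / 2, rng[2] + sp, by = sp)
  }
  counts <- t(vapply(frame_sets, function(f) {
    R <- f$R
    if (any(R < breaks[1] | R > breaks[length(breaks)]))
      stop("sampled R values fall outside the histogram breaks")
    as.numeric(table(cut(R, breaks = breaks, include.lowest = TRUE)))
  }, numeric(length(breaks) - 1L)))
  structure(list(
    breaks = breaks, mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
    counts = counts,
    windows = tibble::tibble(center = centers, k = ks),
    temperature = temperature %||% frame_sets[[1]]$provenance$temperature
  ), class = "umbrella_histograms")
}

# bias matrix in kT units (windows x bins), evaluated at the bin centres;
# bins should be narrow enough that the bias varies little within one bin
wham_bias_kt <- function(hist) {
  beta <- 1 / kT(hist$temperature)
  outer(seq_len(nrow(hist$windows)), seq_along(hist$mids), function(w, b) {
    beta * 0.5 * hist$windows$k[w] * (hist$mids[b] - hist$windows$center[w])^2
  })
}

# Windows must jointly cover a contiguous R range: the union of each
# window's occupied bin range may not leave a hole. Sparse zero-count bins
# inside one window's range are benign (they become missing profile bins).
check_window_overlap <- function(hist) {
  nb <- length(hist$mids)
  covered <- rep(FALSE, nb)
  for (w in seq_len(nrow(hist$counts))) {
    o <- which(hist$counts[w, ] > 0)
    if (length(o)) covered[min(o):max(o)] <- TRUE
  }
  occ <- which(covered)
  if (!length(occ)) stop("all histogram bins are empty")
  gap <- setdiff(seq(min(occ), max(occ)), occ)
  if (length(gap)) {
    runs <- split(gap, cumsum(c(1, diff(gap) != 1)))
    g <- runs[[1]]
    stop(sprintf(
      "umbrella windows do not overlap: no counts in R = [%.4f, %.4f] nm",
      hist$breaks[min(g)], hist$breaks[max(g) + 1]))
  }
  invisible(TRUE)
}

#' Solve the WHAM equations for the unbiased free-energy profile
#'
#' Direct self-consistent iteration of the weighted-histogram equations with
#' log-sum-exp stabilisation: window free-energy constants f_w and the
#' unbiased bin probabilities are updated until max |delta f_w| falls below
#' `tol` (in k_B T). The profile is -ln p in k_B T; bins with zero pooled
#' counts are returned as NA (missing, never interpolated). The profile is
#' shifted to `R_ref` when given.
#'
#' @param hist An `umbrella_histograms` from [bin_histograms()].
#' @param tol Convergence tolerance on the window constants (k_B T).
#' @param max_iter Maximum iterations.
#' @param R_ref Optional zero-reference distance (nm).
#' @param f_init Optional warm-start window constants (k_B T).
#' @return An [fe_profile()] (component `"F_GB"`) with zero standard errors;
#'   see [wham_bootstrap()] for errors. The converged window constants are
#'   attached as attribute `f_window`.
#' @export
wham_solve <- function(hist, tol = 1e-8, max_iter = 1e5, R_ref = NULL,
                       f_init = NULL) {
  stopifnot(inherits(hist, "umbrella_histograms"), tol > 0)
  check_window_overlap(hist)
  U <- wham_bias_kt(hist)                    # windows x bins, kT units
  N <- rowSums(hist$counts)
  M <- colSums(hist$counts)                  # pooled counts per bin
  occ <- M > 0
  f <- f_init %||% rep(0, nrow(U))
  logc <- -U[, occ, drop = FALSE]            # log exp(-beta U)
  logM <- log(M[occ])
  logN <- log(N)
  for (it in seq_len(max_iter)) {
    # log denominator per bin: logsumexp over windows of (logN + f + logc)
    A <- sweep(logc, 1, logN + f, `+`)
    amax <- apply(A, 2, max)
    logden <- amax + log(colSums(exp(sweep(A, 2, amax, `-`))))
    logp <- logM - logden
    # f_w = -ln sum_b exp(logc_wb + logp_b)
    B <- sweep(logc, 2, logp, `+`)
    bmax <- apply(B, 1, max)
    f_new <- -(bmax + log(rowSums(exp(B - bmax))))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kT)",
                 as.integer(max_iter), delta))
  logp <- logp - max(logp)
  val <- rep(NA_real_, length(hist$mids))
  val[occ] <- -(logp - log(sum(exp(logp))))
  prof <- fe_profile(hist$mids, val, NA_real_, temperature = hist$temperature,
                     component = "F_GB")
  attr(prof, "f_window") <- f
  if (!is.null(R_ref)) prof <- profile_shift(prof, R_ref)
  prof
}

#' Bootstrap standard errors for a WHAM profile
#'
#' Within each window the binned frame counts are resampled multinomially
#' (frame-level bootstrap of the histogram) and WHAM is re-solved, warm
#' started from the full-data solution. The per-bin standard deviation over
#' replicates, after shifting each replicate to the common reference, is the
#' standard error.
#'
#' @inheritParams wham_solve
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed (reproducible replicates).
#' @return Numeric vector of per-bin standard errors (k_B T; NA for missing
#'   bins).
#' @export
wham_bootstrap <- function(hist, n_boot = 50, seed = NULL, tol = 1e-8,
                           max_iter = 1e5, R_ref = NULL) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (any(rowSums(hist$counts) == 0)) stop("empty umbrella window in histogram set")
  if (!is.null(seed)) set.seed(seed)
  base <- wham_solve(hist, tol = tol, max_iter = max_iter, R_ref = R_ref)
  f0 <- attr(base, "f_window")
  ref_i <- if (is.null(R_ref)) which.min(abs(hist$mids - hist$mids[!is.na(base$value)][1]))
           else which.min(abs(hist$mids - R_ref))
  reps <- matrix(NA_real_, n_boot, length(hist$mids))
  for (b in seq_len(n_boot)) {
    h2 <- hist
    for (w in seq_len(nrow(hist$counts))) {
      n_w <- sum(hist$counts[w, ])
      h2$counts[w, ] <- as.numeric(stats::rmultinom(1, n_w, hist$counts[w, ] / n_w))
    }
    p <- try(wham_solve(h2, tol = tol, max_iter = max_iter, f_init = f0), silent = TRUE)
    if (inherits(p, "try-error")) next
    v <- p$value
    if (is.na(v[ref_i])) next
    reps[b, ] <- v - v[ref_i]
  }
  apply(reps, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) >= 2) sd(col) else NA_real_
  })
}

#' Umbrella sampling + WHAM free-energy profile with bootstrap errors
#'
#' Convenience wrapper: bins the frame sets, solves WHAM, attaches bootstrap
#' standard errors and shifts to the reference distance.
#'
#' @inheritParams bin_histograms
#' @inheritParams wham_bootstrap
#' @return An [fe_profile()] with standard errors.
#' @export
wham_profile <- function(frame_sets, windows = NULL, breaks = NULL,
                         n_boot = 50, seed = NULL, R_ref = NULL,
                         tol = 1e-8, max_iter = 1e5) {
  hist <- bin_histograms(frame_sets, windows = windows, breaks = breaks)
  prof <- wham_solve(hist, tol = tol, max_iter = max_iter, R_ref = R_ref)
  se <- wham_bootstrap(hist, n_boot = n_boot, seed = seed, tol = tol,
                       max_iter = max_iter, R_ref = R_ref)
  prof$stderr <- se
  prof
}

#' Run umbrella sampling over a schedule of windows
#'
#' @param topology A [chain_topology()].
#' @param solvent A [solvent_model()].
#' @param windows List of [umbrella_window()]s, or a numeric vector of
#'   centres (with `k` applied to all).
#' @param protocol A [sampling_protocol()]; per-window seeds are derived from
#'   `protocol$seed`.
#' @param k Force constant used when `windows` is a numeric vector.
#' @return A list of `frame_set`s, one per window.
#' @export
umbrella_run <- function(topology, solvent, windows, protocol, k = 1875) {
  if (is.numeric(windows)) windows <- lapply(windows, umbrella_window, k = k)
  purrr::imap(windows, function(w, i) {
    p <- protocol
    if (!is.null(p$seed)) p$seed <- p$seed + 1000L * i
    run_sampling(topology, solvent, p, window = w,
                 init = default_conformation(topology, R = w$center))
  })
}
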