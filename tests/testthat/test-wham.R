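make_hist <- function(counts, centers, k, breaks, temperature = 298) {
  structure(list(
    breaks = breaks, mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
    counts = matrix(counts, nrow = length(centers), byrow = TRUE),
    windows = tibble::tibble(center = centers, k = k),
    temperature = temperature), class = "umbrella_histograms")
}

test_that("a single unbiased window reduces WHAM to Boltzmann inversion", {
  set.seed(21)
  counts <- as.numeric(stats::rmultinom(1, 5000, c(1, 3, 6, 3, 1)))
  h <- make_hist(counts, centers = 0.5, k = 1e-12,
                 breaks = seq(0.3, 0.8, by = 0.1))
  prof <- wham_solve(h)
  direct <- -log(counts / sum(counts))
  expect_equal(diff(prof$value), diff(direct), tolerance = 1e-6)
})

test_that("WHAM recovers the analytic dumbbell profile within bootstrap errors", {
  toy <- harmonic_dumbbell(k_b = 1000, r0 = 0.5)
  p <- sampling_protocol(n_equil = 1000, n_frames = 2500, stride = 10,
                         step_nm = 0.05, seed = 31)
  centers <- seq(0.35, 0.73, by = 0.02)
  fss <- umbrella_run(toy$topology, vacuum(), centers, p)
  breaks <- seq(0.25, 0.85, by = 0.005)
  prof <- wham_profile(fss, breaks = breaks, n_boot = 25, seed = 32, R_ref = 0.5)
  ok <- which(!is.na(prof$value) & prof$stderr > 0)
  Fex <- binned_exact_profile(toy, prof$R[ok], 0.005)
  Fex <- Fex - Fex[which.min(abs(prof$R[ok] - 0.5))]
  z <- (prof$value[ok] - Fex) / prof$stderr[ok]
  expect_gte(mean(abs(z) <= 3), 0.95)
})

test_that("two overlapping windows match a brute-force reweighting oracle", {
  # two biased Gaussian histograms over a flat underlying profile
  set.seed(41)
  breaks <- seq(0.3, 0.9, by = 0.02)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  k <- 400; centers <- c(0.5, 0.62); beta <- 1 / kT(298)
  probs <- lapply(centers, function(c0) {
    w <- exp(-beta * 0.5 * k * (mids - c0)^2); w / sum(w)
  })
  counts <- t(vapply(probs, function(pr) as.numeric(stats::rmultinom(1, 2e5, pr)),
                     numeric(length(mids))))
  h <- make_hist(c(t(counts)), centers, k, breaks)
  prof <- wham_solve(h)
  # oracle: unbias each window independently, align on the overlap, pool
  unb <- lapply(1:2, function(w) {
    v <- -log(counts[w, ] / sum(counts[w, ])) - beta * 0.5 * k * (mids - centers[w])^2
    v
  })
  both <- counts[1, ] > 50 & counts[2, ] > 50
  offset <- mean(unb[[2]][both] - unb[[1]][both])
  pooled <- ifelse(counts[1, ] >= counts[2, ], unb[[1]], unb[[2]] - offset)
  ok <- colSums(counts) > 100
  expect_lt(max(abs(diff(prof$value[ok]) - diff(pooled[ok]))), 0.05)
})

test_that("non-overlapping windows raise an error naming the gap", {
  breaks <- seq(0, 1, by = 0.1)
  counts <- rbind(c(5, 10, 5, 0, 0, 0, 0, 0, 0, 0),
                  c(0, 0, 0, 0, 0, 0, 0, 5, 10, 5))
  h <- make_hist(c(t(counts)), c(0.15, 0.85), 100, breaks)
  expect_error(wham_solve(h), "do not overlap.*0\\.3")
})

test_that("bootstrap errors are reproducible, positive, and scale like 1/sqrt(n)", {
  toy <- harmonic_dumbbell()
  dens <- function(mids, c0, k) {
    beta <- 1 / kT(298)
    w <- mids^2 * exp(-beta * (0.5 * 1000 * (mids - 0.5)^2 + 0.5 * k * (mids - c0)^2))
    w[w < 1e-9 * max(w)] <- 0               # trim far tails so coverage is contiguous
    w / sum(w)
  }
  breaks <- seq(0.3, 0.75, by = 0.015)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  centers <- seq(0.4, 0.65, by = 0.05); k <- 800
  draw <- function(n) {
    counts <- t(vapply(centers, function(c0)
      as.numeric(stats::rmultinom(1, n, dens(mids, c0, k))), numeric(length(mids))))
    make_hist(c(t(counts)), centers, k, breaks)
  }
  set.seed(55)
  h1 <- draw(10000); h2 <- draw(20000)
  e1a <- wham_bootstrap(h1, n_boot = 30, seed = 5, R_ref = 0.5)
  e1b <- wham_bootstrap(h1, n_boot = 30, seed = 5, R_ref = 0.5)
  expect_identical(e1a, e1b)
  expect_true(all(e1a[!is.na(e1a)] >= 0))
  e2 <- wham_bootstrap(h2, n_boot = 30, seed = 6, R_ref = 0.5)
  ratio <- stats::median(e1a / e2, na.rm = TRUE)
  expect_gt(ratio, 1.15)   # ~ sqrt(2) with statistical slack
  expect_lt(ratio, 1.75)
})

test_that("a delta-function histogram has zero bootstrap error", {
  counts <- c(0, 0, 200, 0, 0)
  h <- make_hist(counts, centers = 0.5, k = 1e-12, breaks = seq(0.3, 0.8, 0.1))
  e <- wham_bootstrap(h, n_boot = 5, seed = 1)
  expect_identical(e[3], 0)
  expect_true(all(is.na(e[-3])))
})

test_that("profile shifting is idempotent, gauge-invariant and difference-preserving", {
  set.seed(61)
  prof <- fe_profile(seq(0.5, 2.0, by = 0.1), rnorm(16), runif(16, 0, 0.2))
  s1 <- profile_shift(prof, 0.5)
  expect_identical(s1$value[1], 0)
  expect_identical(profile_shift(s1, 0.5)$value, s1$value)
  s2 <- profile_shift(s1, 1.8)
  expect_equal(diff(s2$value), diff(prof$value), tolerance = 1e-12)
  shifted_const <- fe_profile(prof$R, prof$value + 3.7, prof$stderr)
  expect_equal(profile_shift(shifted_const, 0.5)$value, s1$value, tolerance = 1e-12)
  expect_error(profile_shift(prof, 5), "outside")
})

test_that("profiles resample explicitly and refuse mismatched grids", {
  a <- fe_profile(seq(0.5, 1.5, 0.1), seq(0, 1, 0.1))
  b <- fe_profile(seq(0.5, 1.5, 0.25), 0)
  expect_error(pmfdecomp:::check_same_grid(a, b), "same R grid")
  rs <- profile_resample(a, b$R)
  expect_equal(rs$value, (b$R - 0.5), tolerance = 1e-12)
})
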