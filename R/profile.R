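#' Construct a free-energy profile
#'
#' A tibble with columns `R` (nm, strictly increasing), `value` (k_B T) and
#' `stderr` (k_B T, >= 0 or NA), carrying metadata attributes: temperature
#' (K), pressure (bar), component label and the zero-reference distance
#' `R_ref` (nm). Missing bins (no counts) are kept as NA rows, never
#' interpolated.
#'
#' @param R Grid of end-to-end distances (nm), strictly increasing.
#' @param value Profile values in k_B T.
#' @param stderr Standard errors in k_B T (default 0).
#' @param temperature Temperature (K).
#' @param pressure Pressure (bar).
#' @param component Label such as `"F_GB"` or `"mu_ex"`.
#' @param R_ref Zero-reference distance (nm) or NA if not yet shifted.
#' @return An object of class `fe_profile` (a tibble).
#' @export
fe_profile <- function(R, value, stderr = 0, temperature = 298, pressure = 1,
                       component = "F", R_ref = NA_real_) {
  R <- as.numeric(R)
  if (any(diff(R) <= 0)) stop("profile grid must be strictly increasing")
  value <- rep_len(as.numeric(value), length(R))
  stderr <- rep_len(as.numeric(stderr), length(R))
  if (any(stderr < 0, na.rm = TRUE)) stop("standard errors must be >= 0")
  out <- tibble::tibble(R = R, value = value, stderr = stderr)
  attr(out, "temperature") <- temperature
  attr(out, "pressure") <- pressure
  attr(out, "component") <- component
  attr(out, "R_ref") <- R_ref
  class(out) <- c("fe_profile", class(out))
  out
}

profile_meta <- function(p) {
  list(temperature = attr(p, "temperature"), pressure = attr(p, "pressure"),
       component = attr(p, "component"), R_ref = attr(p, "R_ref"))
}

check_same_grid <- function(a, b, what = "profiles") {
  if (nrow(a) != nrow(b) || max(abs(a$R - b$R)) > 1e-12)
    stop(sprintf("%s are not on the same R grid; resample explicitly first", what))
  invisible(TRUE)
}

#' Shift a profile so its value is zero at a reference distance
#'
#' The grid point nearest `R_ref` is subtracted from every value, so pairwise
#' differences are preserved exactly and shifting is idempotent. All figures
#' in this package use `R_ref = 0.5` nm by convention.
#'
#' @param profile An [fe_profile()].
#' @param R_ref Reference distance (nm); must fall inside the grid and hit a
#'   non-missing bin.
#' @return The shifted `fe_profile` with its `R_ref` attribute set.
#' @export
profile_shift <- function(profile, R_ref) {
  stopifnot(inherits(profile, "fe_profile"))
  if (R_ref < min(profile$R) - 1e-9 || R_ref > max(profile$R) + 1e-9)
    stop(sprintf("R_ref = %g nm lies outside the profile grid [%g, %g]",
                 R_ref, min(profile$R), max(profile$R)))
  i <- which.min(abs(profile$R - R_ref))
  if (is.na(profile$value[i]))
    stop(sprintf("profile is missing at the reference bin R = %g nm", profile$R[i]))
  m <- profile_meta(profile)
  fe_profile(profile$R, profile$value - profile$value[i], profile$stderr,
             temperature = m$temperature, pressure = m$pressure,
             component = m$component, R_ref = R_ref)
}

#' Linearly resample a profile onto a new grid
#'
#' Downstream cycle assembly requires all profiles on one grid; resampling is
#' always this explicit step, never implicit. Values and standard errors are
#' interpolated linearly; points outside the original grid become NA.
#'
#' @param profile An [fe_profile()].
#' @param R_new New grid (nm), strictly increasing.
#' @return An `fe_profile` on `R_new`.
#' @export
profile_resample <- function(profile, R_new) {
  stopifnot(inherits(profile, "fe_profile"))
  ok <- !is.na(profile$value)
  m <- profile_meta(profile)
  v <- approx(profile$R[ok], profile$value[ok], xout = R_new, rule = 1)$y
  se <- approx(profile$R[ok], profile$stderr[ok], xout = R_new, rule = 1)$y
  fe_profile(R_new, v, se, temperature = m$temperature, pressure = m$pressure,
             component = m$component, R_ref = m$R_ref)
}

# value +/- combination with errors in quadrature; metadata from `a` unless given
profile_combine <- function(a, b, op = `+`, component = NULL) {
  stopifnot(inherits(a, "fe_profile"), inherits(b, "fe_profile"))
  check_same_grid(a, b)
  m <- profile_meta(a)
  fe_profile(a$R, op(a$value, b$value), sqrt(a$stderr^2 + b$stderr^2),
             temperature = m$temperature, pressure = m$pressure,
             component = component %||% m$component, R_ref = m$R_ref)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.fe_profile <- function(x, ...) {
  m <- profile_meta(x)
  cat(sprintf("<fe_profile> %s at %g K, %g bar (k_B T units, zero at R = %s nm)\n",
              m$component, m$temperature, m$pressure,
              if (is.na(m$R_ref)) "unset" else format(m$R_ref)))
  NextMethod()
}
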