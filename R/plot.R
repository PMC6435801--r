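#' Plot a free-energy profile
#'
#' Line plot with a +/- 1 standard-error ribbon, in k_B T against R (nm).
#'
#' @param object An [fe_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fe_profile <- function(object, ...) {
  m <- profile_meta(object)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$stderr,
                                      ymax = .data$value + .data$stderr),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "R (nm)",
                  y = sprintf("%s / k_B T", m$component),
                  title = sprintf("%s at %g K, %g bar", m$component,
                                  m$temperature, m$pressure)) +
    ggplot2::theme_minimal()
}

#' Plot a full decomposition
#'
#' Overlays the component profiles of a `decomposed_profiles` object.
#'
#' @param object A `decomposed_profiles`.
#' @param components Which components to draw (default the physical five).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decomposed_profiles <- function(object,
                                         components = c("F", "F_GB", "F_vac",
                                                        "mu_ex", "mu_nonpol"),
                                         ...) {
  df <- tidy(object)
  df <- df[df$component %in% components, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$stderr,
                                      ymax = .data$value + .data$stderr,
                                      fill = .data$component),
                         alpha = 0.15, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "R (nm)", y = "profile / k_B T",
                  title = sprintf("Free-energy decomposition at %g K, %g bar",
                                  object$temperature, object$pressure)) +
    ggplot2::theme_minimal()
}

#' Plot temperature- or pressure-difference profiles
#'
#' @param delta A tibble from [delta_T_profiles()] or [delta_P_profiles()].
#' @param components Which components to draw.
#' @return A ggplot object.
#' @export
plot_delta_profiles <- function(delta, components = unique(delta$component)) {
  df <- delta[delta$component %in% components, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "R (nm)", y = "difference (dimensionless)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.fe_profile <- function(x, ...) {
  m <- profile_meta(x)
  tibble::tibble(R = x$R, value = x$value, stderr = x$stderr,
                 component = m$component, temperature = m$temperature,
                 pressure = m$pressure)
}

#' @export
glance.fe_profile <- function(x, ...) {
  m <- profile_meta(x)
  tibble::tibble(component = m$component, temperature = m$temperature,
                 pressure = m$pressure, R_ref = m$R_ref,
                 n_grid = nrow(x), n_missing = sum(is.na(x$value)),
                 range = diff(range(x$value, na.rm = TRUE)))
}
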