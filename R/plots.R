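# ggplot2 views of the result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a parameter sweep
#'
#' FFR and FSS amplitudes against the swept parameter, one panel per
#' quantity, colour per boundary case. Radius, permeability and strain
#' sweeps spanning more than a decade are drawn on log scales.
#'
#' @param object an `osteon_sweep` tibble from [sweep_parameter()] or
#'   [sweep_fixed_strain_rate()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.osteon_sweep <- function(object, ...) {
  xvar <- if ("value" %in% names(object)) "value" else "freq_hz"
  long <- tidyr::pivot_longer(
    object[, c(xvar, "case", "abs_Q_m3_s", "abs_tau_pa",
               intersect("strain_rate", names(object)))],
    cols = c("abs_Q_m3_s", "abs_tau_pa"),
    names_to = "quantity", values_to = "amplitude")
  long$quantity <- factor(long$quantity, c("abs_Q_m3_s", "abs_tau_pa"),
                          c("FFR amplitude (m^3/s)", "FSS amplitude (Pa)"))
  grp <- if ("strain_rate" %in% names(long))
    interaction(long$case, long$strain_rate) else long$case
  gg <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data[[xvar]], y = .data$amplitude,
    colour = .data$case, group = grp)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = attr(object, "swept") %||% xvar, y = NULL,
                  colour = "case") +
    ggplot2::theme_minimal()
  xs <- long[[xvar]]
  if (min(xs) > 0 && max(xs) / min(xs) > 30)
    gg <- gg + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  gg
}

#' Plot a time response
#'
#' @param object an `osteon_time_response` tibble from [time_response()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.osteon_time_response <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = c("strain", "Q_m3_s", "tau_pa"),
                              names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal, c("strain", "Q_m3_s", "tau_pa"),
                        c("axial strain", "FFR (m^3/s)", "FSS (Pa)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value,
                                     colour = .data$case)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "case") +
    ggplot2::theme_minimal()
}

#' Plot a radial pore-pressure profile
#'
#' @param object an `osteon_radial_field` tibble from [pressure_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.osteon_radial_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_m * 1e6,
                                       y = .data$abs_p_pa,
                                       colour = .data$case)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (um)", y = "|p_0(r)| (Pa)", colour = "case") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
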