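#' Plot an exchange correlation curve
#'
#' Lin-log representation of F(t): a logarithmic decay appears as a straight
#' segment.
#'
#' @param object An `exchange_run` or a data frame with `time_s` (or
#'   `time_cycles`) and `F`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exchange_run <- function(object, ...) {
  df <- object$series[object$series$time_cycles > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_cycles, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (MC cycles)", y = "F(t)",
                  title = "Tagged-chain exchange correlation") +
    ggplot2::theme_minimal()
}

#' Plot an Eyring fit
#'
#' Data and fitted curve on a lin-log time axis.
#'
#' @param object An [eyring_fit()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eyring_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$F), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$F_fit), colour = "red3") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "F(t)",
                  title = sprintf("Modified Eyring fit (R² = %.4f, type %s)",
                                  object$r2, object$class)) +
    ggplot2::theme_minimal()
}

#' Plot a micellization scan
#'
#' Standard chemical-potential difference versus aggregation number with
#' the preferred micelle size marked.
#'
#' @param object A [micellization_scan()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.micellization_scan <- function(object, ...) {
  g <- ggplot2::ggplot(object$scan,
                       ggplot2::aes(x = .data$N, y = .data$delta_mu)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "aggregation number N",
                  y = expression((mu[N]^0 - mu[1]^0) / k[B] * T)) +
    ggplot2::theme_minimal()
  if (isTRUE(object$micellized)) {
    g <- g + ggplot2::geom_vline(xintercept = object$N_star,
                                 linetype = "dashed", colour = "red3")
  }
  g
}

#' Plot a master-curve collapse
#'
#' Scaled curves (t*, y*) from [classify_and_collapse()] on log-log axes,
#' with the slope -1 guide of the logarithmic regime.
#'
#' @param collapse A [classify_and_collapse()] result.
#' @return A ggplot.
#' @export
plot_collapse <- function(collapse) {
  df <- collapse$scaled
  df <- df[is.finite(df$log_y_star) & df$t_star > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$t_star),
                                   y = .data$log_y_star / log(10),
                                   colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = -1, intercept = 0, linetype = "dotdash",
                         colour = "grey50") +
    ggplot2::labs(x = "log10 t*", y = "log10 y*",
                  title = "Master-curve collapse") +
    ggplot2::theme_minimal()
}

#' Plot radial conformational profiles
#'
#' @param profiles A [radial_profiles()] tibble.
#' @param boundaries Optional [region_boundaries()] list to mark the
#'   core/corona and corona/bulk interfaces.
#' @param what `"rg"` (Rg_PO/Rg*) or `"angle"` (EO-PO-EO angle).
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles, boundaries = NULL,
                          what = c("rg", "angle")) {
  what <- match.arg(what)
  y <- if (what == "rg") "rg_ratio" else "angle"
  lab <- if (what == "rg") expression(R[g] / R[g] * "*") else
    "EO-PO-EO angle (deg)"
  g <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$r_mid, y = .data[[y]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance from micelle centre (sigma)", y = lab) +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    g <- g + ggplot2::geom_vline(
      xintercept = c(boundaries$r_core_corona, boundaries$r_corona_bulk),
      linetype = "dashed", colour = "blue3")
  }
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
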