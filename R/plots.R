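#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated dose-response curve
#'
#' LFP response (|transepithelial deflection|) against log10 odorant
#' dilution for one stimulated ORN.
#'
#' @param object A [dose_response()] result (rows with `x = Inf` are
#'   dropped from the plot).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensillum_dose_response <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$x))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$lfp_mV,
                                   colour = .data$orn_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "log10 odorant dilution", y = "|LFP| (mV)",
                  colour = "ORN") +
    ggplot2::theme_minimal()
}

#' Plot both membrane potentials along a concentration sweep
#'
#' Shows the ephaptic signature: the stimulated ORN depolarizes while its
#' neighbor hyperpolarizes.
#'
#' @param model A calibrated [sensillum_model()].
#' @param stimulated Which ORN is swept.
#' @param x_grid log10 dilutions.
#' @param background_fraction Neighbor activation fraction.
#' @return A ggplot.
#' @export
plot_membrane_potentials <- function(model, stimulated = 1,
                                     x_grid = seq(-10, 0, by = 0.25),
                                     background_fraction = 0) {
  dr <- dose_response(model, stimulated, x_grid, background_fraction)
  df <- dr |>
    dplyr::filter(is.finite(.data$x)) |>
    tidyr::pivot_longer(c("vm_active_mV", "vm_neighbor_mV"),
                        names_to = "neuron", values_to = "V_m") |>
    dplyr::mutate(neuron = ifelse(.data$neuron == "vm_active_mV",
                                  "stimulated", "neighbor"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$V_m,
                                   linetype = .data$neuron)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10 odorant dilution", y = "V_m (mV)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fitted curves over measured replicate means
#'
#' @param object A [global_fit()] result.
#' @param ... Unused.
#' @return A ggplot faceted by sensillum.
#' @export
autoplot.sensillum_fit <- function(object, ...) {
  res <- object$residuals
  ggplot2::ggplot(res, ggplot2::aes(.data$x, colour = .data$orn)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_mean)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted)) +
    ggplot2::facet_wrap(~sensillum) +
    ggplot2::labs(x = "log10 odorant dilution", y = "|LFP| (mV)",
                  colour = "ORN") +
    ggplot2::theme_minimal()
}
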