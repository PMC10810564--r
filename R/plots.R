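#' @importFrom ggplot2 autoplot ggplot aes geom_line facet_wrap labs
#'   theme_minimal geom_point geom_hline
#' @export
ggplot2::autoplot

bc_long <- function(data, channels) {
  data |>
    dplyr::select(dplyr::all_of(c("t", channels))) |>
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "value") |>
    dplyr::mutate(channel = factor(.data$channel, levels = channels))
}

#' Plot a simulation's key output channels
#'
#' @param object A `bc_sim` object from [bc_simulate()].
#' @param channels Channels to facet (defaults to the headline outputs).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bc_sim <- function(object,
                            channels = c("dCBF_pct", "TOI", "oxCCO",
                                         "CMRO2", "Dp", "NADNADHrat"),
                            ...) {
  ggplot(bc_long(object, channels), aes(x = .data$t, y = .data$value)) +
    geom_line(colour = "#2c7fb8") +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time (s)", y = NULL,
         title = "Simulated hypercapnia response") +
    theme_minimal()
}

#' Plot a fit: modelled versus observed target signals
#'
#' @param object A `bc_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bc_fit <- function(object, ...) {
  chans <- object$target_set
  obs <- bc_long(object$observed, chans) |> dplyr::mutate(source = "observed")
  mod <- bc_long(object$sim, chans) |> dplyr::mutate(source = "modelled")
  ggplot(dplyr::bind_rows(obs, mod),
         aes(x = .data$t, y = .data$value, colour = .data$source)) +
    geom_line() +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time (s)", y = NULL,
         title = sprintf("%s-regime fit (targets: %s)", object$regime,
                         paste(chans, collapse = ", "))) +
    theme_minimal()
}

#' Plot the parameter spread across repeated fits
#'
#' @param object A `bc_repeat` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bc_repeat <- function(object, ...) {
  free <- bc_regime_free(object$regime)
  long <- object$table |>
    tidyr::pivot_longer(dplyr::all_of(free), names_to = "term",
                        values_to = "value")
  ggplot(long, aes(x = .data$term, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "#a6bddb") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    facet_wrap(~term, scales = "free") +
    labs(x = NULL, y = "fitted value",
         title = sprintf("Parameter spread over %d repeats (%s regime)",
                         object$repeats, object$regime)) +
    theme_minimal()
}
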