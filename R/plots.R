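#' Plot an activation map
#' @param object an [activation_map()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.activation_map <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    value = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(name = "ΔHbT (frac)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "HbT activation map (stim - baseline)")
}

#' Plot an ROI haemoglobin time series
#' @param series tibble with `time_s`, `hbt`, `hbo`, `hbr`.
#' @return A ggplot.
#' @export
plot_roi_series <- function(series) {
  long <- tidyr::pivot_longer(series, dplyr::any_of(c("hbt", "hbo", "hbr")),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Time (s)", y = "Fractional change",
                  colour = NULL)
}

#' Plot a trial-averaged evoked response with its SEM ribbon
#' @param avg output of [trial_average()].
#' @return A ggplot.
#' @export
plot_trial_average <- function(avg) {
  ggplot2::ggplot(avg, ggplot2::aes(.data$time_rel_s, .data$mean,
                                    colour = .data$component,
                                    fill = .data$component)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Time from stimulus onset (s)",
                  y = "Fractional change", colour = NULL, fill = NULL)
}

#' Plot a binned MUA depth heat map
#' @param mua tibble from [bin_threshold()] (after [depth_select()] if
#'   desired).
#' @return A ggplot.
#' @export
plot_mua_heatmap <- function(mua) {
  ggplot2::ggplot(mua, ggplot2::aes(.data$bin_start_s,
                                    factor(.data$channel),
                                    fill = .data$fractional)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Fractional MUA") +
    ggplot2::labs(x = "Time (s)", y = "Channel (depth)")
}

#' Plot the neurovascular-coupling scatter and fitted line
#' @param object a [fit_line()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.coupling_fit <- function(object, ...) {
  lab <- sprintf("y = %.4gx %s %.4g, R² = %.3f",
                 object$slope, if (object$intercept >= 0) "+" else "-",
                 abs(object$intercept), object$r_squared)
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$peak_mua_fractional,
                               .data$peak_hbt_fractional)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$stim_duration))) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::labs(x = "Evoked MUA peak (fractional)",
                  y = "Evoked HbT peak (fractional)",
                  colour = "Stim (s)", subtitle = lab)
}
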