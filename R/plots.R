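#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a temperature trace
#'
#' Mean thermal waveform with the heating phase shaded.
#'
#' @param object A [temperature_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot temperature_trace
#' @export
autoplot.temperature_trace <- function(object, ...) {
  df <- tidy.temperature_trace(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$temperature)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Temperature (°C)")
  if (!object$trimmed) {
    idx <- protocol_frame_indices(object$protocol)
    p <- p + ggplot2::annotate("rect",
                               xmin = idx$lamp_on / object$fps,
                               xmax = idx$lamp_off / object$fps,
                               ymin = -Inf, ymax = Inf, alpha = 0.12)
  }
  p
}

#' Plot the mean thermal waveform of every class
#'
#' One noiseless lumped-model trace per class spec, overlaid — the
#' class-level waveform families (peak height and cooling slope).
#'
#' @param class_specs List of [class_spec()] objects.
#' @param protocol An [acquisition_protocol()].
#' @return A ggplot.
#' @export
plot_class_waveforms <- function(class_specs = study_classes(),
                                 protocol = acquisition_protocol()) {
  df <- purrr::map_dfr(class_specs, function(sp) {
    dplyr::mutate(tidy.temperature_trace(simulate_trace(sp$thermal_params,
                                                        protocol)),
                  class = sp$class_name)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$temperature,
                                   color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Temperature (°C)",
                  color = "Class")
}

#' Heatmap of pairwise Hotelling p-values
#'
#' @param object A [pairwise_hotelling()] result.
#' @param alpha Significance threshold marked in the fill scale.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pairwise_hotelling
#' @export
autoplot.pairwise_hotelling <- function(object, alpha = 0.001, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$p_matrix, rownames = "class1"),
    -"class1", names_to = "class2", values_to = "p_value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class2, y = .data$class1,
                                   fill = log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 p",
                  title = sprintf("Pairwise Hotelling T² (threshold %.3g)",
                                  alpha)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Canonical scores scatter plot
#'
#' First two canonical variates colored by class.
#'
#' @param object A [canonical_discriminant()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot canonical_discriminant
#' @export
autoplot.canonical_discriminant <- function(object, ...) {
  df <- tidy.canonical_discriminant(object)
  if (!"can2" %in% names(df)) df$can2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$can1, y = .data$can2,
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Canonical variate 1", y = "Canonical variate 2",
                  color = "Class")
}

#' Confusion-matrix heatmap of a LOOCV report
#'
#' @param object A [loocv()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loocv_report
#' @export
autoplot.loocv_report <- function(object, ...) {
  df <- tibble::as_tibble(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted", y = "Truth",
                  title = sprintf("%s / %s: accuracy %.4f", object$task,
                                  object$classifier, object$accuracy)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a phasegram or ampligram
#'
#' @param image Matrix from [pixelwise_spectra()].
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_spectral_image <- function(image, title = NULL) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(image, .name_repair = ~ as.character(seq_along(.x))),
    dplyr::everything(), names_to = "col", values_to = "value")
  df$row <- rep(seq_len(nrow(image)), each = ncol(image))
  df$col <- as.integer(df$col)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = title)
}

#' @importFrom dplyr .data
NULL
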