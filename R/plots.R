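#' Plot an SpO2 trace with optional event annotations
#'
#' @param record An [spo2_record()].
#' @param events Optional annotation tibble; event spans are shaded.
#' @return A ggplot.
#' @export
plot_spo2 <- function(record, events = NULL) {
  tb <- spo2_tbl(record)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$time_s / 60, y = .data$spo2)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "Time (min)", y = expression(SpO[2] ~ "(%)")) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    ev <- tibble::as_tibble(events)
    p <- p + ggplot2::geom_rect(
      data = ev,
      ggplot2::aes(xmin = .data$onset_s / 60,
                   xmax = (.data$onset_s + .data$duration_s) / 60,
                   ymin = -Inf, ymax = Inf, fill = .data$kind),
      alpha = 0.15, inherit.aes = FALSE
    ) + ggplot2::labs(fill = "Event")
  }
  p
}

#' @export
autoplot.scg_history <- function(object, ...) {
  tb <- tidyr::pivot_longer(object$iterations,
                            cols = c("train_mse", "val_mse"),
                            names_to = "set", values_to = "mse")
  tb$set <- ifelse(tb$set == "train_mse", "training", "validation")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$iteration, y = .data$mse,
                                   colour = .data$set)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$best_iteration,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "SCG iteration", y = "MSE (normalized target space)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.osa_evaluation <- function(object, ...) {
  lab <- toupper(object$index)
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$reference, y = .data$estimate,
                               colour = .data$ref_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("Reference %s (events/hour)", lab),
                  y = sprintf("Estimated %s (events/hour)", lab),
                  colour = "Severity") +
    ggplot2::theme_minimal()
}
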