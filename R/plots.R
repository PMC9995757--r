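#' Plot estimated segment tilt angles
#'
#' @param object A `tilt_series` from [estimate_tilt()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tilt_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"t",
                              names_to = "placement", values_to = "theta")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$theta,
                                     color = .data$placement)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "tilt (rad)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.correlation_screen <- function(object, ...) {
  keep <- c(object$ranking$feature, object$outcome)
  m <- object$matrix[keep, keep]
  long <- tibble(row = rep(rownames(m), times = ncol(m)),
                 col = rep(colnames(m), each = nrow(m)),
                 r = as.vector(m))
  long$row <- factor(long$row, levels = keep)
  long$col <- factor(long$col, levels = rev(keep))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$row, y = .data$col,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r), "NA", sprintf("%.2f", .data$r))),
      size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a labeled event stream as an activity timeline
#'
#' @param events Event tibble (`start`, `end`, `label`).
#' @param compare Optional second stream drawn underneath (e.g.
#'   predictions vs. annotations).
#' @return A ggplot.
#' @export
plot_event_stream <- function(events, compare = NULL) {
  events <- validate_events(events)
  events$stream <- "truth"
  if (!is.null(compare)) {
    compare <- validate_events(compare)
    compare$stream <- "predicted"
    events <- dplyr::bind_rows(events, compare)
  }
  ggplot2::ggplot(events,
                  ggplot2::aes(xmin = .data$start, xmax = .data$end,
                               ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(~stream, ncol = 1) +
    ggplot2::scale_fill_viridis_d(drop = FALSE) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "activity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
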