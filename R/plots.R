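# ggplot2 display methods for coherence spectra, signed topographies, and
# classifier reports.

# Approximate 2D head-plan coordinates for the channels the synthetic
# montage uses (10-20 system, nose up; unit head radius).
electrode_coords <- function() {
  tibble::tribble(
    ~channel, ~x, ~y,
    "Fz", 0.00, 0.38, "F1", -0.15, 0.39, "F2", 0.15, 0.39,
    "F3", -0.31, 0.41, "F4", 0.31, 0.41,
    "FC1", -0.13, 0.20, "FC2", 0.13, 0.20,
    "FC3", -0.28, 0.21, "FC4", 0.28, 0.21,
    "Cz", 0.00, 0.00, "C1", -0.15, 0.00, "C2", 0.15, 0.00,
    "C3", -0.33, 0.00, "C4", 0.33, 0.00,
    "EOG", 0.25, 0.85)
}

#' Plot a coherence spectrum
#'
#' Region-of-interest mean normalized coherence against frequency, one line
#' per participant/condition present in the spectrum.
#'
#' @param object A `coherence_spectrum`.
#' @param roi Channels to average over.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coherence_spectrum <- function(object, roi = roi_centrofrontal(),
                                        ...) {
  df <- roi_mean_coherence(object, roi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$value,
                                   group = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized phase coherence") +
    ggplot2::theme_minimal()
}

#' Plot a signed topography
#'
#' Electrode-plan view of the signed coherence: point size is magnitude,
#' color the sign relative to the reference electrode.
#'
#' @param object A `signed_topography`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signed_topography <- function(object, ...) {
  df <- dplyr::left_join(tibble::as_tibble(object), electrode_coords(),
                         by = "channel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$signed_coherence),
                                     color = .data$signed_coherence)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), nudge_y = 0.06,
                       size = 3) +
    ggplot2::scale_color_gradient2(low = "#2166ac", mid = "grey85",
                                   high = "#b2182b", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("signed coherence at %g Hz (ref %s)",
                                  attr(object, "frequency"),
                                  attr(object, "reference")),
                  color = "signed\ncoherence", size = "|coherence|") +
    ggplot2::theme_void()
}

#' Plot a classifier report confusion matrix
#'
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classifier_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4393c3") +
    ggplot2::labs(
      title = sprintf("sens %.1f%%, spec %.1f%%, acc %.1f%%, AUC %.1f%%",
                      100 * object$sensitivity, 100 * object$specificity,
                      100 * object$accuracy, 100 * object$auc)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
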