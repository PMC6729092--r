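#' Plot a normalized power spectrum
#'
#' Line plot of the normalized PSD over the analysis band; sharp peaks near
#' the stride and step harmonics indicate smooth, rhythmic movement, a broad
#' band of comparable components the opposite.
#'
#' @param object a `spectral_profile` from [normalized_psd].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot spectral_profile
#' @export
autoplot.spectral_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$freq, .data$norm_psd)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Normalized PSD") +
    ggplot2::theme_minimal()
}

#' Plot a TUG segmentation
#'
#' Phase intervals as coloured spans on the time axis, optionally over a
#' signal trace.
#'
#' @param object a `tug_segmentation`.
#' @param signal optional numeric series (same recording) drawn underneath.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tug_segmentation
#' @export
autoplot.tug_segmentation <- function(object, signal = NULL, ...) {
  fs <- attr(object, "sample_rate")
  spans <- dplyr::mutate(as_tibble(object),
                         start_s = (.data$start - 1) / fs,
                         end_s = (.data$end - 1) / fs,
                         phase = factor(.data$phase, levels = tug_phases()))
  p <- ggplot2::ggplot(spans)
  if (!is.null(signal)) {
    tr <- tibble(t = (seq_along(signal) - 1) / fs, y = signal)
    p <- p + ggplot2::geom_line(data = tr, ggplot2::aes(.data$t, .data$y),
                                colour = "grey30", linewidth = 0.3)
  }
  p +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$phase), alpha = 0.25) +
    ggplot2::labs(x = "Time (s)", y = NULL, fill = "Phase") +
    ggplot2::theme_minimal()
}

#' Plot per-phase SPARC values
#'
#' Boxplots of SPARC by phase and group, faceted by channel; less smooth
#' movement sits lower.
#'
#' @param object a `smoothness_result` (single- or multi-subject).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot smoothness_result
#' @export
autoplot.smoothness_result <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      phase = factor(.data$phase,
                                     levels = c(tug_phases(), "full")))
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$sparc, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "SPARC", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Correlation map between SPARC metrics and clinical scores
#'
#' Tile map of Pearson r per score x phase x channel, with significant
#' (p < 0.05) cells outlined.
#'
#' @param cm output of [correlation_map].
#' @return a ggplot.
#' @export
plot_correlation_map <- function(cm) {
  df <- dplyr::mutate(cm, cell = paste(.data$phase, .data$channel, sep = "\n"))
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$score, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$significant),
                       colour = "red", linewidth = 0.4, fill = NA) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}
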