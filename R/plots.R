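#' Plot a fluorescence distribution with its detected peaks
#'
#' Kernel density of per-cell fluorescence with vertical lines at the
#' detected main peaks — the visual check behind every ploidy call.
#'
#' @param sample Data frame with a `fluorescence` column (one row per cell).
#' @param bandwidth,min_prominence Passed to [density_peaks()].
#' @return A ggplot object.
#' @export
plot_fluorescence <- function(sample, bandwidth = "auto",
                              min_prominence = 0.05) {
  pk <- density_peaks(sample$fluorescence, bandwidth, min_prominence)
  main <- pk[seq_len(min(2, nrow(pk))), ]
  ggplot2::ggplot(sample, ggplot2::aes(x = .data$fluorescence)) +
    ggplot2::geom_density(fill = "grey85", colour = "grey30") +
    ggplot2::geom_vline(data = main,
                        ggplot2::aes(xintercept = .data$position),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Green fluorescence (a.u.)", y = "Density") +
    ggplot2::theme_minimal()
}

#' Plot cumulative WGD counts along the experiment
#'
#' @param cumulative A [wgd_cumulative()] result.
#' @return A ggplot object (step curve per cross).
#' @export
plot_cumulative_wgd <- function(cumulative) {
  ggplot2::ggplot(cumulative,
                  ggplot2::aes(x = .data$generations,
                               y = .data$cumulative_count,
                               colour = .data$cross_id)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(x = "Generations", y = "Cumulative tetraploid lines",
                  colour = "Cross") +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome gain and loss frequencies
#'
#' @param spectrum A [gain_loss_spectrum()] result.
#' @return A ggplot object (gain and loss panels).
#' @export
plot_gain_loss_spectrum <- function(spectrum) {
  long <- spectrum |>
    select(dplyr::any_of(c("cross_id", "group")), "chrom",
           gain = "gain_freq", loss = "loss_freq") |>
    tidyr::pivot_longer(c("gain", "loss"), names_to = "event",
                        values_to = "frequency")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chrom, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~event) +
    ggplot2::labs(x = NULL, y = "Frequency of lines") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot LOH segment size distributions by kind
#'
#' @param segments A [detect_loh()] result.
#' @return A ggplot object (log10 sizes, interstitial vs terminal).
#' @export
plot_loh_sizes <- function(segments) {
  ggplot2::ggplot(filter(segments, .data$size > 0),
                  ggplot2::aes(x = .data$kind, y = .data$size)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "LOH segment size (bp)") +
    ggplot2::theme_minimal()
}

#' Boxplot view of a group comparison
#'
#' Median / quartile / 1.5 IQR whisker boxplots with individual points, the
#' convention used for per-cross rate figures.
#'
#' @param object A [compare_groups()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90",
                          coef = 1.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "Value") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
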