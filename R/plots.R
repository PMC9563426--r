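#' Plot a hypnogram
#'
#' Classic step trace of the vigilance state over time (wake on top, REM
#' at the bottom, as in standard polysomnography displays).
#'
#' @param h A `hypnogram`.
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(h) {
  d <- tibble::tibble(
    time_h = h$epoch_start_s / 3600,
    level = 4 - as.integer(factor(h$state, levels = c("WAKE", "NREM", "REM")))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$level)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = 3:1,
                                labels = c("WAKE", "NREM", "REM"),
                                limits = c(0.8, 3.2)) +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Violin plot of per-animal architecture metrics by genotype
#'
#' @param arch Long table from [cohort_table()].
#' @param metric One of `"total_s"`, `"pct_tst"`, `"n_bouts"`,
#'   `"mean_bout_s"`.
#' @return A ggplot object.
#' @export
plot_architecture <- function(arch, metric = "n_bouts") {
  d <- dplyr::filter(arch, .data$metric == !!metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$value,
                                  fill = .data$genotype)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA) +
    ggplot2::geom_jitter(width = 0.08, size = 1) +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(WT = "grey50", MUT = "firebrick")) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Per-state mean band power by genotype
#'
#' @param band_summary Stacked per-animal [state_band_summary()] rows with
#'   `animal` and `genotype` columns.
#' @param state State panel to show.
#' @return A ggplot object.
#' @export
plot_band_summary <- function(band_summary, state = "REM") {
  d <- dplyr::filter(band_summary, .data$state == !!state,
                     !is.na(.data$mean_norm_power))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$band, band_levels()),
                                  y = .data$mean_norm_power,
                                  fill = .data$genotype)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA,
                         position = ggplot2::position_dodge(0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.05, dodge.width = 0.8), size = 1) +
    ggplot2::facet_wrap(~role) +
    ggplot2::scale_fill_manual(values = c(WT = "grey50", MUT = "firebrick")) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mean normalized power", title = state) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.comparison_suite <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(label = paste(.data$family,
                                dplyr::coalesce(.data$state, ""),
                                dplyr::coalesce(.data$role, ""),
                                dplyr::coalesce(.data$band, "")))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_adj),
                                  y = stats::reorder(.data$label, -.data$p_adj),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha") %||% 0.05),
                        linetype = 2) +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
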