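#' Plot cohort data characteristics
#'
#' Three-panel profile of a cohort's monitoring data quality: per channel,
#' the mean standard deviation as percent of the mean, the mean percent of
#' monitoring time the channel was available, and the fraction of patients
#' with nonstationary data (KPSS p at or below 0.01). Phases, when present,
#' are dodged side by side.
#'
#' @param characteristics Output of [data_characteristics()].
#' @return A ggplot object.
#' @export
plot_characteristics <- function(characteristics) {
  coh <- cohort_characteristics(characteristics)
  long <- coh |>
    tidyr::pivot_longer(
      c("mean_sd_percent", "mean_availability_percent", "nonstationary_fraction"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = factor(.data$metric,
      levels = c(
        "mean_sd_percent", "mean_availability_percent",
        "nonstationary_fraction"
      ),
      labels = c(
        "SD (% of mean)", "Availability (%)",
        "Nonstationary fraction"
      )
    ))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$variable, y = .data$value))
  if (any(!is.na(long$phase))) {
    p <- p + ggplot2::geom_col(
      ggplot2::aes(fill = factor(.data$phase)),
      position = "dodge"
    ) +
      ggplot2::labs(fill = "Phase")
  } else {
    p <- p + ggplot2::geom_col(fill = "grey30")
  }
  p +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a population summary as a relationship dot chart
#'
#' Each row is a cause-state to effect relationship; the dot position gives
#' the percent of measuring patients in which it was significant, and the
#' colour the dominant direction of the effect (an increase or a decrease of
#' the effect variable).
#'
#' @param summary Output of [summarize_population()] (window-collapsed).
#' @param min_percent Hide relationships below this percent.
#' @return A ggplot object.
#' @export
plot_summary <- function(summary, min_percent = 0) {
  edges <- export_graph(summary, min_percent = min_percent)
  edges$label <- sprintf(
    "%s:%s → %s", edges$from, edges$cause_state,
    edges$to
  )
  ggplot2::ggplot(
    edges,
    ggplot2::aes(
      x = .data$percent,
      y = stats::reorder(.data$label, .data$percent),
      colour = .data$dominant_sign
    )
  ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_significant)) +
    ggplot2::scale_colour_manual(
      values = c(INCREASE = "black", DECREASE = "red3", MIXED = "grey50")
    ) +
    ggplot2::labs(
      x = "% of measuring patients", y = NULL,
      colour = "Direction", size = "Patients"
    ) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_bw()
}

#' Gap-statistic curve for a phenotyping result
#'
#' @param object A `nc_phenotype` from [gap_kmeans()].
#' @param ... Unused.
#' @return A ggplot object showing `Gap(k)` with its simulation standard
#'   errors and the chosen `k`.
#' @method autoplot nc_phenotype
#' @export
autoplot.nc_phenotype <- function(object, ...) {
  gc <- object$gap_curve
  ggplot2::ggplot(gc, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$gap - .data$se,
        ymax = .data$gap + .data$se
      )
    ) +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = gc$k) +
    ggplot2::labs(x = "Number of clusters k", y = "Gap statistic") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
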