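# Basic diagnostic plots.

#' Bland-Altman plot
#'
#' RVD of each paired nodule against the average of the two systems'
#' volumes, with the mean difference and limits of agreement as horizontal
#' lines.
#'
#' @param paired Paired tibble with `v_dl`, `v_std` (e.g. a report's
#'   `paired` element).
#' @param z LOA multiplier (default 1.96).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(paired, z = 1.96) {
  pts <- bland_altman_points(paired$v_dl, paired$v_std)
  ba <- bland_altman(pts$rvd, z = z)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$avg_volume_mm3, y = 100 * .data$rvd)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 100 * ba$mean_diff, linetype = 1) +
    ggplot2::geom_hline(
      yintercept = 100 * c(ba$loa_lower, ba$loa_upper), linetype = 2
    ) +
    ggplot2::labs(
      x = "Average volume (mm³)", y = "RVD (%)",
      title = sprintf(
        "Mean %s%%, LOA %s%% / %s%%",
        format_percent(ba$mean_diff),
        format_percent(ba$loa_lower), format_percent(ba$loa_upper)
      )
    ) +
    ggplot2::theme_minimal()
}

#' RVE boxplots by group
#'
#' Distribution of per-measurement RVE by size group, faceted by system and
#' density.
#'
#' @param records Measurement records.
#' @param cohort Cohort tibble.
#' @return A ggplot object.
#' @export
plot_rve_by_group <- function(records, cohort) {
  dat <- records |>
    dplyr::filter(!is.na(.data$measured_volume_mm3)) |>
    dplyr::inner_join(
      dplyr::select(cohort,
        nodule_id = "id", "density", "diameter_mm", "true_volume_mm3"
      ),
      by = "nodule_id"
    ) |>
    dplyr::mutate(rve = rve(.data$measured_volume_mm3, .data$true_volume_mm3))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = factor(.data$diameter_mm), y = 100 * .data$rve)
  ) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$density), ggplot2::vars(.data$system)
    ) +
    ggplot2::labs(x = "Nodule diameter (mm)", y = "RVE (%)") +
    ggplot2::theme_minimal()
}
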