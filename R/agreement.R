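# Agreement statistics: per-nodule RVE/AVD/RVD, group summaries, and
# Bland-Altman limits of agreement.

#' Relative volumetric error
#'
#' `RVE = (measured - GT) / GT`, the per-nodule error of a measured volume
#' against the known ground truth. Returned as a fraction; multiply by 100
#' for the conventional percent display.
#'
#' @param measured_volume_mm3 Measured volumes (>= 0).
#' @param true_volume_mm3 Ground-truth volumes (> 0).
#' @return Numeric vector of fractional errors.
#' @export
rve <- function(measured_volume_mm3, true_volume_mm3) {
  if (any(true_volume_mm3 <= 0, na.rm = TRUE)) {
    abort_domain("ground-truth volume must be strictly positive.")
  }
  if (any(measured_volume_mm3 < 0, na.rm = TRUE)) {
    abort_domain("measured volume must be non-negative.")
  }
  (measured_volume_mm3 - true_volume_mm3) / true_volume_mm3
}

#' Absolute and relative volume difference between two systems
#'
#' `AVD = v_dl - v_std` (mm^3) and `RVD = AVD / v_std` (fraction): the
#' deep-learning system's volume minus the standard system's, normalised by
#' the standard system's volume.
#'
#' @param v_dl Volumes from the deep-learning CAD (mm^3).
#' @param v_std Volumes from the standard CAD (mm^3, > 0).
#' @return Numeric vector.
#' @export
avd <- function(v_dl, v_std) {
  if (any(v_std <= 0, na.rm = TRUE)) {
    abort_domain("standard-system volume must be strictly positive.")
  }
  v_dl - v_std
}

#' @rdname avd
#' @export
rvd <- function(v_dl, v_std) {
  avd(v_dl, v_std) / v_std
}

#' Group summaries of fractional errors
#'
#' Per-group count, mean, and sample SD (n - 1 denominator) of a fractional
#' error column, the building block of RVE-by-group tables. Values stay on
#' the fraction scale; use [format_percent()] for display.
#'
#' @param data Tibble holding the error column and grouping columns.
#' @param value Column to summarise (tidy-eval).
#' @param ... Grouping columns (tidy-eval); none = one overall row.
#' @return Tibble with grouping columns plus `n`, `mean`, `sd` (`sd` is `NA`
#'   for singleton groups).
#' @export
group_summary <- function(data, value, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sd = ifelse(dplyr::n() >= 2, stats::sd({{ value }}), NA_real_),
      .groups = "drop"
    )
}

#' Format a fraction as a percent string
#'
#' @param x Fractions.
#' @param digits Decimals (default 1, the conventional table precision).
#' @return Character vector like `"12.2"`.
#' @export
format_percent <- function(x, digits = 1) {
  formatC(100 * x, format = "f", digits = digits)
}

#' Limits of agreement from a mean and SD
#'
#' The Bland-Altman limits: `mean_diff +/- z * sd_diff`, with `z = 1.96` so
#' the interval spans the central ~95% of between-method differences under
#' normality. Exposed separately so limits can be recomputed from published
#' summary rows.
#'
#' @param mean_diff,sd_diff Mean and SD of the differences (any scale).
#' @param z Normal multiplier (default 1.96; some studies use 2.0).
#' @return Named numeric `c(lower, upper)`.
#' @export
loa <- function(mean_diff, sd_diff, z = 1.96) {
  c(lower = mean_diff - z * sd_diff, upper = mean_diff + z * sd_diff)
}

#' Bland-Altman analysis of paired differences
#'
#' Computes the mean difference, its sample SD, and the limits of agreement
#' `mean +/- z * SD`. Differences are typically relative volume differences
#' (RVD, fractions); the same arithmetic applies to any difference scale.
#'
#' @param diffs Numeric vector of paired differences, `n >= 2`.
#' @param z Normal multiplier for the limits (default 1.96).
#' @return Object of class `bland_altman`: list with `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `n`, `z`, and `degenerate` (TRUE when the
#'   differences have zero spread, in which case the limits collapse onto
#'   the mean).
#' @export
bland_altman <- function(diffs, z = 1.96) {
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2) abort_domain("Bland-Altman limits need at least 2 differences.")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  degenerate <- s == 0
  if (degenerate) {
    warning("zero spread in differences; limits of agreement collapse to the mean.",
      call. = FALSE
    )
  }
  lims <- loa(m, s, z)
  structure(
    list(
      mean_diff = m, sd_diff = s,
      loa_lower = unname(lims["lower"]), loa_upper = unname(lims["upper"]),
      n = n, z = z, degenerate = degenerate
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean %s%%, SD %s%%, LOA %s%% / %s%%\n",
    x$n, format_percent(x$mean_diff), format_percent(x$sd_diff),
    format_percent(x$loa_lower), format_percent(x$loa_upper)
  ))
  invisible(x)
}

#' Bland-Altman point set
#'
#' The (average volume, RVD) pairs conventionally plotted in a Bland-Altman
#' diagram for volume ratios: each nodule's relative volume difference
#' against the mean of the two systems' volumes.
#'
#' @param v_dl,v_std Paired volumes (mm^3).
#' @return Tibble with `avg_volume_mm3` and `rvd`.
#' @export
bland_altman_points <- function(v_dl, v_std) {
  tibble::tibble(
    avg_volume_mm3 = (v_dl + v_std) / 2,
    rvd = rvd(v_dl, v_std)
  )
}

#' Pair the two systems' measurements
#'
#' Applies the study's pairing rule at one acquisition voltage: a nodule
#' enters the paired analysis iff the deep-learning system produced a volume
#' for it (its misses cannot be recovered manually); standard-system volumes
#' are always present because misses are manually added. The result is one
#' row per analysable nodule with both volumes and the nodule's ground
#' truth.
#'
#' @param records Measurement records from [simulate_study()] /
#'   [read_measurements()].
#' @param cohort Cohort tibble (for ground truth and nodule attributes).
#' @param voltage_kv Which acquisition to pair on (default 120).
#' @return Tibble with `nodule_id`, `density`, `diameter_mm`,
#'   `true_volume_mm3`, `v_dl`, `v_std`.
#' @export
pair_records <- function(records, cohort, voltage_kv = 120) {
  wide <- records |>
    dplyr::filter(.data$voltage_kv == !!voltage_kv) |>
    dplyr::select("nodule_id", "system", "measured_volume_mm3") |>
    tidyr::pivot_wider(names_from = "system", values_from = "measured_volume_mm3")
  for (sys in SYSTEMS) if (!sys %in% names(wide)) wide[[sys]] <- NA_real_
  wide |>
    dplyr::filter(!is.na(.data$dl_cad), !is.na(.data$std_cad)) |>
    dplyr::rename(v_dl = "dl_cad", v_std = "std_cad") |>
    dplyr::inner_join(
      cohort |>
        dplyr::select(
          nodule_id = "id", "density", "diameter_mm", "true_volume_mm3"
        ),
      by = "nodule_id"
    ) |>
    dplyr::select(
      "nodule_id", "density", "diameter_mm", "true_volume_mm3",
      "v_dl", "v_std"
    )
}
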