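# Configuration-driven end-to-end pipeline:
# generate -> simulate -> pair -> agreement stats -> classification impact.

#' Assemble a study configuration
#'
#' Bundles everything [run_pipeline()] needs: the phantom design, the
#' per-system error and detection models, the classification threshold
#' table, the pairing voltage, the LOA multiplier, and the seed. Defaults
#' reproduce the benchmark study conditions.
#'
#' @param design A [study_design()].
#' @param error_models,detection_models Named lists of models per system.
#' @param thresholds Lung-RADS threshold table.
#' @param pairing_voltage_kv Acquisition used for the between-system paired
#'   analysis (default 120 kV, the acquisition with the best detection
#'   rate).
#' @param loa_z Multiplier for the limits of agreement (default 1.96).
#' @param seed Integer seed for the whole run.
#' @param rho Between-system error correlation (default 0).
#' @return Object of class `study_config`.
#' @export
study_config <- function(design = study_design(seed = seed),
                         error_models = default_error_models(),
                         detection_models = default_detection_models(),
                         thresholds = lungrads_thresholds(),
                         pairing_voltage_kv = 120,
                         loa_z = 1.96,
                         seed = 1L,
                         rho = 0) {
  structure(
    list(
      design = design,
      error_models = error_models,
      detection_models = detection_models,
      thresholds = thresholds,
      pairing_voltage_kv = pairing_voltage_kv,
      loa_z = loa_z,
      seed = as.integer(seed),
      rho = rho
    ),
    class = "study_config"
  )
}

#' Run the full agreement pipeline
#'
#' Sequences the stages: generate the phantom cohort, simulate detection and
#' measurement for every nodule x system x voltage, apply the pairing rule,
#' compute the agreement statistics (per-group RVE summaries, RVD
#' Bland-Altman limits), run the classification-impact analysis on solid
#' nodules, and collect the hypothesis tests. Fully deterministic under the
#' configured seed. Stage progress (record counts) is reported via
#' `message()` when `verbose = TRUE`.
#'
#' Externally supplied measurements (e.g. exported from real CAD software)
#' can replace the simulation stage via `records`/`cohort`.
#'
#' @param config A [study_config()].
#' @param cohort Optional pre-built cohort tibble (skips generation).
#' @param records Optional measurement records (skips simulation).
#' @param verbose Emit stage messages?
#' @return Object of class `volagree_report`: list with `cohort`, `records`,
#'   `paired`, `detection_summary`, `rve_by_group` (per system x density x
#'   size), `rvd_loa` (per density x size and per density overall),
#'   `crosstab_solid`, `concordance_solid`, `correctness`, `tests`, and a
#'   `provenance` block (seed, pairing voltage, counts).
#' @export
run_pipeline <- function(config = study_config(), cohort = NULL,
                         records = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(cohort)) cohort <- generate_cohort(config$design)
  say("cohort: %d nodules in %d arrangements",
    nrow(cohort), length(unique(cohort$arrangement_id))
  )
  if (is.null(records)) {
    records <- simulate_study(
      cohort,
      error_models = config$error_models,
      detection_models = config$detection_models,
      seed = config$seed,
      rho = config$rho
    )
  }
  validate_measurements(records)
  say("records: %d (%d with volumes)", nrow(records), sum(!is.na(records$measured_volume_mm3)))

  detection_summary <- records |>
    dplyr::group_by(.data$system, .data$voltage_kv) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_detected = sum(.data$detected),
      n_manual = sum(.data$manually_added),
      detection_rate = mean(.data$detected),
      .groups = "drop"
    )

  # Per-system RVE against ground truth, pooling all acquisitions with a
  # measured volume as observations.
  rve_data <- records |>
    dplyr::filter(!is.na(.data$measured_volume_mm3)) |>
    dplyr::inner_join(
      dplyr::select(cohort,
        nodule_id = "id", "density", "diameter_mm", "true_volume_mm3"
      ),
      by = "nodule_id"
    ) |>
    dplyr::mutate(rve = rve(.data$measured_volume_mm3, .data$true_volume_mm3))
  rve_by_group <- group_summary(
    rve_data, .data$rve, .data$system, .data$density, .data$diameter_mm
  )

  paired <- pair_records(records, cohort, voltage_kv = config$pairing_voltage_kv)
  say("paired at %d kV: %d nodules", as.integer(config$pairing_voltage_kv), nrow(paired))
  paired$rvd <- rvd(paired$v_dl, paired$v_std)

  rvd_loa <- dplyr::bind_rows(
    ba_rows(paired, c("density", "diameter_mm"), config$loa_z),
    ba_rows(paired, "density", config$loa_z)
  )

  solid <- paired[paired$density == "solid", ]
  cat_dl <- lungrads_classify(solid$v_dl, "solid", config$thresholds)
  cat_std <- lungrads_classify(solid$v_std, "solid", config$thresholds)
  cat_gt <- lungrads_classify(solid$true_volume_mm3, "solid", config$thresholds)
  crosstab_solid <- cross_tabulate(cat_dl, cat_std)
  concordance_solid <- concordance(crosstab_solid)

  # Correctness denominators differ by design: the DL system is scored on
  # the nodules it produced volumes for (the paired set); the standard
  # system on every solid nodule, since its misses are manually recovered.
  std_all <- std_system_volumes(records, cohort, config$pairing_voltage_kv)
  cat_std_all <- lungrads_classify(std_all$v_std, "solid", config$thresholds)
  cat_gt_all <- lungrads_classify(std_all$true_volume_mm3, "solid", config$thresholds)
  correct <- list(
    dl_cad = correctness(cat_dl, cat_gt, solid$diameter_mm),
    std_cad = correctness(cat_std_all, cat_gt_all, std_all$diameter_mm)
  )

  tests <- dplyr::bind_rows(
    voltage_effect_tests(records, cohort),
    wilcoxon_paired(lungrads_ordinal(cat_dl), lungrads_ordinal(cat_std)) |>
      dplyr::mutate(note = "Lung-RADS categories, DL vs standard (ordinal coding)"),
    mcnemar_counts(
      b = sum(cat_dl == cat_gt & cat_std != cat_gt),
      c = sum(cat_dl != cat_gt & cat_std == cat_gt)
    ) |>
      dplyr::mutate(note = "correct classification, DL vs standard (paired nodules)")
  )

  structure(
    list(
      cohort = cohort,
      records = records,
      paired = paired,
      detection_summary = detection_summary,
      rve_by_group = rve_by_group,
      rvd_loa = rvd_loa,
      crosstab_solid = crosstab_solid,
      concordance_solid = concordance_solid,
      correctness = correct,
      tests = tests,
      provenance = list(
        seed = config$seed,
        pairing_voltage_kv = config$pairing_voltage_kv,
        loa_z = config$loa_z,
        n_nodules = nrow(cohort),
        n_records = nrow(records),
        n_paired = nrow(paired),
        package_version = as.character(utils::packageVersion("volagree"))
      )
    ),
    class = "volagree_report"
  )
}

# Solid nodules with a standard-system volume at the analysis voltage
# (all of them when manual addition is allowed).
std_system_volumes <- function(records, cohort, voltage_kv) {
  records |>
    dplyr::filter(
      .data$system == "std_cad", .data$voltage_kv == !!voltage_kv,
      !is.na(.data$measured_volume_mm3)
    ) |>
    dplyr::inner_join(
      dplyr::select(cohort,
        nodule_id = "id", "density", "diameter_mm", "true_volume_mm3"
      ),
      by = "nodule_id"
    ) |>
    dplyr::filter(.data$density == "solid") |>
    dplyr::rename(v_std = "measured_volume_mm3")
}

ba_rows <- function(paired, by, z) {
  paired |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rvd = mean(.data$rvd),
      sd_rvd = stats::sd(.data$rvd),
      loa_lower = mean(.data$rvd) - z * stats::sd(.data$rvd),
      loa_upper = mean(.data$rvd) + z * stats::sd(.data$rvd),
      .groups = "drop"
    )
}

#' @export
print.volagree_report <- function(x, ...) {
  cat("Volumetric agreement report\n")
  cat(sprintf(
    "  %d nodules, %d records, %d paired at %d kV (seed %d)\n",
    x$provenance$n_nodules, x$provenance$n_records, x$provenance$n_paired,
    as.integer(x$provenance$pairing_voltage_kv), x$provenance$seed
  ))
  cat(sprintf(
    "  solid discordance: %d/%d (%s%%)\n",
    x$concordance_solid$discordant_n, x$crosstab_solid$n,
    format_percent(x$concordance_solid$discordant_rate)
  ))
  cat(sprintf(
    "  correct classification: DL %s%%, standard %s%%\n",
    format_percent(x$correctness$dl_cad$rate),
    format_percent(x$correctness$std_cad$rate)
  ))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Renders the bundle as plain-text artefacts in `dir`: `cohort.csv`,
#' `measurements.csv`, `rve_by_group.csv`, `rvd_loa.csv` (percent columns,
#' 1 decimal), `crosstab_solid.csv` (matrix with margins), `tests.csv`,
#' `detection_summary.csv`, and `report.json` (machine-readable summary
#' including provenance).
#'
#' @param report A `volagree_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "volagree_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  write_cohort(report$cohort, p("cohort.csv"))
  write_measurements(report$records, p("measurements.csv"))

  rve_tab <- report$rve_by_group |>
    dplyr::mutate(
      mean_rve_pct = format_percent(.data$mean),
      sd_rve_pct = format_percent(.data$sd)
    )
  readr::write_csv(rve_tab, p("rve_by_group.csv"))

  loa_tab <- report$rvd_loa |>
    dplyr::mutate(dplyr::across(
      c("mean_rvd", "sd_rvd", "loa_lower", "loa_upper"),
      ~ format_percent(.x),
      .names = "{.col}_pct"
    ))
  readr::write_csv(loa_tab, p("rvd_loa.csv"))

  ct <- report$crosstab_solid
  m <- cbind(ct$counts, Total = ct$row_margins)
  m <- rbind(m, Total = c(ct$col_margins, ct$n))
  utils::write.csv(m, p("crosstab_solid.csv"))

  readr::write_csv(report$tests, p("tests.csv"))
  readr::write_csv(report$detection_summary, p("detection_summary.csv"))

  jsonlite::write_json(
    list(
      provenance = report$provenance,
      concordance = list(
        discordant_n = report$concordance_solid$discordant_n,
        discordant_rate_pct = 100 * report$concordance_solid$discordant_rate
      ),
      correctness = list(
        dl_cad = list(
          correct_n = report$correctness$dl_cad$correct_n,
          n = report$correctness$dl_cad$n,
          rate_pct = 100 * report$correctness$dl_cad$rate
        ),
        std_cad = list(
          correct_n = report$correctness$std_cad$correct_n,
          n = report$correctness$std_cad$n,
          rate_pct = 100 * report$correctness$std_cad$rate
        )
      )
    ),
    p("report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
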