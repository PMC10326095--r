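# CSV round-trips for cohorts and measurement records, and the YAML study
# configuration.

COHORT_COLS <- c(
  "id", "arrangement_id", "diameter_mm", "true_volume_mm3", "density",
  "density_hu", "side", "lobe_segment", "location"
)
MEASUREMENT_COLS <- c(
  "nodule_id", "system", "voltage_kv", "detected", "manually_added",
  "measured_volume_mm3"
)

#' Write / read a nodule cohort as CSV
#'
#' UTF-8, header row, `.` decimal separator; volumes kept at full precision.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_columns(cohort, COHORT_COLS, "cohort")
  readr::write_csv(cohort[COHORT_COLS], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(out, COHORT_COLS, "cohort")
  out
}

#' Write / read measurement records as CSV
#'
#' Absent measured volumes (undetected, non-recoverable) are written as
#' empty fields and read back as `NA`; the round trip is lossless.
#'
#' @param records Measurement record tibble.
#' @param path File path.
#' @return `read_measurements()` returns the validated record tibble.
#' @export
write_measurements <- function(records, path) {
  check_columns(records, MEASUREMENT_COLS, "measurement")
  readr::write_csv(records[MEASUREMENT_COLS], path, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      nodule_id = readr::col_character(),
      system = readr::col_character(),
      voltage_kv = readr::col_integer(),
      detected = readr::col_logical(),
      manually_added = readr::col_logical(),
      measured_volume_mm3 = readr::col_double()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  validate_measurements(out)
}

#' Validate measurement records
#'
#' Schema checks with row-level reporting: a measured volume must be present
#' iff the nodule was detected or manually added, a manual addition implies
#' non-detection, and system labels must be recognised. Violations raise an
#' error listing the offending rows.
#'
#' @param records Measurement record tibble.
#' @return The records, invisibly validated.
#' @export
validate_measurements <- function(records) {
  check_columns(records, MEASUREMENT_COLS, "measurement")
  bad_sys <- which(!records$system %in% SYSTEMS)
  has_vol <- !is.na(records$measured_volume_mm3)
  should <- records$detected | records$manually_added
  bad_vol <- which(has_vol != should)
  bad_add <- which(records$manually_added & records$detected)
  problems <- c(
    if (length(bad_sys)) sprintf("rows %s: unknown system", toString(head(bad_sys, 5))),
    if (length(bad_vol)) {
      sprintf(
        "rows %s: measured_volume_mm3 must be present iff detected or manually added",
        toString(head(bad_vol, 5))
      )
    },
    if (length(bad_add)) {
      sprintf(
        "rows %s: manually_added implies not detected",
        toString(head(bad_add, 5))
      )
    }
  )
  if (length(problems)) {
    stop("invalid measurement records:\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  records
}

check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop(sprintf("%s table lacks columns: %s", what, toString(missing)),
      call. = FALSE
    )
  }
  invisible(x)
}

#' Read / write a study configuration as YAML
#'
#' Serialises a [study_config()] (design, error and detection models,
#' thresholds, pairing voltage, LOA multiplier, seed) to a single YAML file
#' and back.
#'
#' @param config A [study_config()].
#' @param path File path.
#' @return `read_study_config()` returns a [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  d <- config$design
  obj <- list(
    seed = config$seed,
    pairing_voltage_kv = config$pairing_voltage_kv,
    loa_z = config$loa_z,
    design = list(
      n_arrangements = d$n_arrangements,
      density_mix = as.list(d$density_mix),
      size_mix = as.list(d$size_mix),
      n_nodules = d$n_nodules,
      p_peripheral = d$p_peripheral
    ),
    error_models = lapply(config$error_models, function(m) {
      list(
        system = m$system, floor_mm3 = m$floor_mm3,
        entries = lapply(seq_len(nrow(m$entries)), function(i) as.list(m$entries[i, ]))
      )
    }),
    detection_models = lapply(config$detection_models, function(m) {
      list(
        system = m$system, manual_add_allowed = m$manual_add_allowed,
        p_detect = lapply(seq_len(nrow(m$p_detect)), function(i) as.list(m$p_detect[i, ]))
      )
    }),
    thresholds = lapply(
      seq_len(nrow(config$thresholds)),
      function(i) as.list(config$thresholds[i, ])
    )
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  obj <- yaml::read_yaml(path)
  design <- study_design(
    n_arrangements = obj$design$n_arrangements,
    density_mix = unlist(obj$design$density_mix),
    size_mix = unlist(obj$design$size_mix),
    n_nodules = obj$design$n_nodules,
    p_peripheral = obj$design$p_peripheral,
    seed = obj$seed
  )
  ems <- lapply(obj$error_models, function(m) {
    error_model(m$system, dplyr::bind_rows(lapply(m$entries, tibble::as_tibble)),
      floor_mm3 = m$floor_mm3
    )
  })
  names(ems) <- vapply(ems, function(m) m$system, character(1))
  dms <- lapply(obj$detection_models, function(m) {
    detection_model(m$system, dplyr::bind_rows(lapply(m$p_detect, tibble::as_tibble)),
      manual_add_allowed = m$manual_add_allowed
    )
  })
  names(dms) <- vapply(dms, function(m) m$system, character(1))
  thresholds <- dplyr::bind_rows(lapply(obj$thresholds, tibble::as_tibble))
  study_config(
    design = design,
    error_models = ems,
    detection_models = dms,
    thresholds = thresholds,
    pairing_voltage_kv = obj$pairing_voltage_kv,
    loa_z = obj$loa_z,
    seed = obj$seed
  )
}
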