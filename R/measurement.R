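# Measurement simulation: per-system detection and relative-error models,
# the seeded study simulator, and a mechanistic voxelized volumetry option.

#' Construct a volumetric error model
#'
#' A per-system generative model for measured volumes. Each (density, size)
#' cell carries a Gaussian relative volumetric error (RVE):
#' `measured = GT * (1 + RVE)`, `RVE ~ N(mean_rve, sd_rve^2)`. A cell may
#' additionally carry a two-component mixture, emulating the "cluster"
#' behaviour seen with some deep-learning volumetry tools on large solid
#' nodules: with probability `p_accurate` the plain Gaussian applies, and
#' otherwise the same Gaussian shifted by `bias_shift` (a negative fraction,
#' i.e. systematic underestimation).
#'
#' @param system One of `"dl_cad"`, `"std_cad"`.
#' @param entries Tibble/data frame with columns `density`, `diameter_mm`,
#'   `mean_rve`, `sd_rve` and optionally `p_accurate`, `bias_shift`
#'   (`NA` = no mixture). RVE values are fractions, not percent.
#' @param floor_mm3 Lower truncation for simulated volumes (default 1 mm^3);
#'   physical volumes are positive, so extreme negative error draws are
#'   clipped.
#' @return An object of class `error_model`.
#' @export
error_model <- function(system, entries, floor_mm3 = 1) {
  system <- match.arg(system, SYSTEMS)
  entries <- tibble::as_tibble(entries)
  required <- c("density", "diameter_mm", "mean_rve", "sd_rve")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    abort_domain(paste0("error model entries lack columns: ", toString(missing)))
  }
  if (!all(entries$density %in% DENSITIES)) {
    abort_domain("entry densities must be 'solid' or 'ggn'.")
  }
  # sd_rve = 0 is allowed as the degenerate noiseless limit (useful for
  # exactness checks); negative spreads are invalid.
  if (any(entries$sd_rve < 0)) abort_domain("`sd_rve` must be non-negative.")
  if (!"p_accurate" %in% names(entries)) entries$p_accurate <- NA_real_
  if (!"bias_shift" %in% names(entries)) entries$bias_shift <- NA_real_
  mix <- !is.na(entries$p_accurate)
  if (any(mix & (entries$p_accurate < 0 | entries$p_accurate > 1))) {
    abort_domain("`p_accurate` must lie in [0, 1].")
  }
  if (any(mix & is.na(entries$bias_shift))) {
    abort_domain("mixture entries need both `p_accurate` and `bias_shift`.")
  }
  if (anyDuplicated(entries[c("density", "diameter_mm")])) {
    abort_domain("duplicate (density, diameter) entries.")
  }
  structure(
    list(system = system, entries = entries, floor_mm3 = floor_mm3),
    class = "error_model"
  )
}

#' Look up one error-model cell
#'
#' @param model An [error_model()].
#' @param density `"solid"` or `"ggn"`.
#' @param diameter_mm Nodule diameter.
#' @return One-row tibble (the cell), or an error if not configured.
#' @export
error_entry <- function(model, density, diameter_mm) {
  stopifnot(inherits(model, "error_model"))
  hit <- model$entries$density == density &
    abs(model$entries$diameter_mm - diameter_mm) < 1e-9
  if (!any(hit)) {
    abort_domain(sprintf(
      "error model '%s' has no entry for (%s, %g mm).",
      model$system, density, diameter_mm
    ))
  }
  model$entries[which(hit)[1L], ]
}

#' Moments of an error-model cell
#'
#' Mean and SD of the RVE distribution implied by a cell, accounting for the
#' mixture when present: for a two-component mixture with common `sd`,
#' `mean = mean_rve + (1 - p) * shift` and
#' `var = sd_rve^2 + p (1 - p) shift^2`.
#'
#' @param entry One-row cell from [error_entry()].
#' @return Named list `mean`, `sd` (fractions).
#' @export
error_entry_moments <- function(entry) {
  if (is.na(entry$p_accurate)) {
    list(mean = entry$mean_rve, sd = entry$sd_rve)
  } else {
    p <- entry$p_accurate
    s <- entry$bias_shift
    list(
      mean = entry$mean_rve + (1 - p) * s,
      sd = sqrt(entry$sd_rve^2 + p * (1 - p) * s^2)
    )
  }
}

#' Construct a detection model
#'
#' Per-system Bernoulli detection with probabilities by (density, voltage),
#' plus the manual-recovery rule: systems that permit manual addition recover
#' every automatically missed nodule (reader adds it), so a measured volume
#' exists for all nodules; systems without that capability simply lose the
#' missed nodules.
#'
#' @param system One of `"dl_cad"`, `"std_cad"`.
#' @param p_detect Tibble/data frame with columns `density`, `voltage_kv`,
#'   `p_detect` (probabilities in `[0, 1]`).
#' @param manual_add_allowed Logical; whether misses can be added manually.
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(system, p_detect, manual_add_allowed) {
  system <- match.arg(system, SYSTEMS)
  p_detect <- tibble::as_tibble(p_detect)
  missing <- setdiff(c("density", "voltage_kv", "p_detect"), names(p_detect))
  if (length(missing)) {
    abort_domain(paste0("detection model lacks columns: ", toString(missing)))
  }
  if (any(p_detect$p_detect < 0 | p_detect$p_detect > 1)) {
    abort_domain("`p_detect` must lie in [0, 1].")
  }
  structure(
    list(
      system = system, p_detect = p_detect,
      manual_add_allowed = isTRUE(manual_add_allowed)
    ),
    class = "detection_model"
  )
}

detection_prob <- function(model, density, voltage_kv) {
  hit <- model$p_detect$density == density & model$p_detect$voltage_kv == voltage_kv
  if (!any(hit)) {
    abort_domain(sprintf(
      "detection model '%s' has no entry for (%s, %d kV).",
      model$system, density, as.integer(voltage_kv)
    ))
  }
  model$p_detect$p_detect[which(hit)[1L]]
}

#' Sample a detection outcome
#'
#' Draws detection as Bernoulli(`p_detect`); an undetected nodule is manually
#' added if and only if the system allows manual addition (all misses are
#' recovered by the reader, as in the benchmark workflow).
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param density,voltage_kv Nodule density class and acquisition voltage.
#' @param model A [detection_model()].
#' @return List with logical fields `detected` and `manually_added`.
#' @export
sample_detection <- function(density, voltage_kv, model) {
  p <- detection_prob(model, density, voltage_kv)
  detected <- runif(1L) < p
  list(
    detected = detected,
    manually_added = !detected && model$manual_add_allowed
  )
}

# Vectorized RVE draws for one cell; shared by sample_measurement and
# simulate_study. Optionally accepts pre-drawn standard-normal quantiles
# (used for between-system correlation via a Gaussian copula).
sample_rve <- function(n, entry, z = NULL) {
  if (is.null(z)) z <- rnorm(n)
  rve <- entry$mean_rve + entry$sd_rve * z
  if (!is.na(entry$p_accurate)) {
    shifted <- runif(n) >= entry$p_accurate
    rve[shifted] <- rve[shifted] + entry$bias_shift
  }
  rve
}

#' Sample measured volumes for one error-model cell
#'
#' Vectorized over `true_volume_mm3`: one measured volume per element,
#' `GT * (1 + RVE)` with RVE drawn from the cell's (possibly mixture)
#' Gaussian, truncated below at the model floor.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param true_volume_mm3 Ground-truth volumes (mm^3).
#' @param entry One-row cell from [error_entry()].
#' @param floor_mm3 Lower truncation (default 1 mm^3).
#' @return Numeric vector of measured volumes.
#' @export
sample_measurement <- function(true_volume_mm3, entry, floor_mm3 = 1) {
  n <- length(true_volume_mm3)
  rve <- sample_rve(n, entry)
  pmax(floor_mm3, true_volume_mm3 * (1 + rve))
}

# Deterministic 32-bit string hash (djb2 variant, kept inside [0, 2^31 - 2])
# used to derive per-record RNG sub-streams.
hash32 <- function(x) {
  m <- 2147483647
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% m
  as.integer(h)
}

record_seed <- function(seed, nodule_id, system, voltage_kv) {
  key <- paste(nodule_id, system, voltage_kv, sep = "|")
  as.integer((hash32(key) + as.numeric(seed) * 7919) %% 2147483647)
}

#' Simulate a full measurement study
#'
#' Drives the detection and measurement samplers over every
#' nodule x system x voltage combination, producing one measurement record
#' per combination. Randomness is organised as one sub-stream per
#' (nodule, system, voltage) derived deterministically from `seed`, so the
#' records for a given nodule are invariant to adding or removing other
#' nodules.
#'
#' An optional between-system error correlation `rho` couples the two
#' systems' Gaussian RVE quantiles for the same (nodule, voltage) through a
#' Gaussian copula; the default `rho = 0` (independent errors) is the
#' conservative choice when no joint error structure is known.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (or [read_cohort()]).
#' @param error_models,detection_models Named lists (by system label) of
#'   [error_model()] / [detection_model()] objects; defaults are the
#'   benchmark-condition models.
#' @param voltages Acquisition voltages (kV), default 80/100/120.
#' @param seed Integer seed.
#' @param rho Between-system RVE correlation in `[0, 1]` (Gaussian copula).
#' @return Tibble of measurement records: `nodule_id`, `system`,
#'   `voltage_kv`, `detected`, `manually_added`, `measured_volume_mm3`
#'   (`NA` when no volume exists), with `seed` recorded as an attribute.
#' @export
simulate_study <- function(cohort,
                           error_models = default_error_models(),
                           detection_models = default_detection_models(),
                           voltages = VOLTAGES_KV,
                           seed = 1L,
                           rho = 0) {
  stopifnot(rho >= 0, rho <= 1)
  check_model_coverage(cohort, error_models, detection_models, voltages)
  grid <- tidyr::expand_grid(
    nodule_idx = seq_len(nrow(cohort)),
    system = names(error_models),
    voltage_kv = as.integer(voltages)
  )
  n <- nrow(grid)
  detected <- logical(n)
  manually_added <- logical(n)
  measured <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    nod <- cohort[grid$nodule_idx[i], ]
    sys <- grid$system[i]
    kv <- grid$voltage_kv[i]
    em <- error_models[[sys]]
    dm <- detection_models[[sys]]
    entry <- error_entry(em, nod$density, nod$diameter_mm)

    withr_seed(record_seed(seed, nod$id, sys, kv), {
      det <- sample_detection(nod$density, kv, dm)
      z <- measurement_quantile(seed, nod$id, sys, kv, rho)
      vol <- pmax(em$floor_mm3, nod$true_volume_mm3 * (1 + sample_rve(1L, entry, z = z)))
    })
    detected[i] <- det$detected
    manually_added[i] <- det$manually_added
    if (det$detected || det$manually_added) measured[i] <- vol
  }

  out <- tibble::tibble(
    nodule_id = cohort$id[grid$nodule_idx],
    system = grid$system,
    voltage_kv = grid$voltage_kv,
    detected = detected,
    manually_added = manually_added,
    measured_volume_mm3 = measured
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

# Standard-normal quantile for the RVE draw of (nodule, system, voltage).
# With rho > 0 the two systems share a latent pair drawn from a sub-stream
# keyed by (nodule, voltage) only, correlated through a Gaussian copula;
# with rho = 0 the quantile comes from the record's own sub-stream (NULL =
# let sample_rve draw it).
measurement_quantile <- function(seed, nodule_id, system, voltage_kv, rho) {
  if (rho == 0) return(NULL)
  s <- record_seed(seed, nodule_id, "shared", voltage_kv)
  withr_seed(s, {
    z0 <- rnorm(1L)
    e1 <- rnorm(1L)
    e2 <- rnorm(1L)
  })
  e <- if (system == "dl_cad") e1 else e2
  sqrt(rho) * z0 + sqrt(1 - rho) * e
}

check_model_coverage <- function(cohort, error_models, detection_models, voltages) {
  if (!setequal(names(error_models), names(detection_models))) {
    abort_domain("error and detection models must cover the same systems.")
  }
  missing <- character()
  cells <- unique(cohort[c("density", "diameter_mm")])
  for (sys in names(error_models)) {
    for (j in seq_len(nrow(cells))) {
      ok <- tryCatch(
        {
          error_entry(error_models[[sys]], cells$density[j], cells$diameter_mm[j])
          TRUE
        },
        error = function(e) FALSE
      )
      if (!ok) {
        missing <- c(missing, sprintf("%s/%s/%gmm", sys, cells$density[j], cells$diameter_mm[j]))
      }
    }
    for (d in unique(cohort$density)) {
      for (v in voltages) {
        ok <- tryCatch(
          {
            detection_prob(detection_models[[sys]], d, v)
            TRUE
          },
          error = function(e) FALSE
        )
        if (!ok) missing <- c(missing, sprintf("%s/%s/%dkV", sys, d, as.integer(v)))
      }
    }
  }
  if (length(missing)) {
    abort_domain(paste0("model coverage gaps: ", toString(missing)))
  }
  invisible(TRUE)
}

#' Voxelized sphere volumetry
#'
#' Mechanistic alternative to the statistical error model: rasterizes a
#' spherical nodule onto an axis-aligned voxel grid (in-plane spacing
#' `voxel_xy_mm`, slice thickness `slice_mm`) and returns the count of voxels
#' whose centres lie inside the sphere times the voxel volume. Deterministic
#' given the grid offset; partial-volume effects make the result vary with
#' the offset, which is the error mechanism this models.
#'
#' @param diameter_mm Sphere diameter (mm).
#' @param voxel_xy_mm In-plane voxel edge (mm).
#' @param slice_mm Slice thickness (mm).
#' @param grid_offset Numeric length-3 offset of the grid origin relative to
#'   the sphere centre, in voxel units (components in `[0, 1)` typical).
#' @param floor_mm3 Lower clip for the returned volume (default 0; set to
#'   1 to mirror the measurement floor).
#' @return Measured volume in mm^3.
#' @export
voxelized_volumetry <- function(diameter_mm, voxel_xy_mm, slice_mm,
                                grid_offset = c(0, 0, 0), floor_mm3 = 0) {
  stopifnot(voxel_xy_mm > 0, slice_mm > 0, length(grid_offset) == 3)
  r <- diameter_mm / 2
  spacing <- c(voxel_xy_mm, voxel_xy_mm, slice_mm)
  centres <- lapply(1:3, function(a) {
    # voxel centres at (k + offset) * spacing covering [-r, r]
    k <- seq(floor((-r) / spacing[a]) - 1, ceiling(r / spacing[a]) + 1)
    (k + grid_offset[a]) * spacing[a]
  })
  g <- expand.grid(x = centres[[1]], y = centres[[2]], z = centres[[3]])
  inside <- g$x^2 + g$y^2 + g$z^2 <= r^2
  max(floor_mm3, sum(inside) * prod(spacing))
}
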