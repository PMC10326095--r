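# Phantom model: sphere geometry, study design, randomized nodule cohorts.

#' Volume of a spherical nodule
#'
#' The artificial nodules are perfect spheres, so the ground-truth volume of a
#' nodule of diameter \eqn{d} is \eqn{\pi d^3 / 6}. The value is returned at
#' full precision; rounding (e.g. to one decimal for display) is a
#' presentation concern handled by the reporting layer.
#'
#' @param diameter_mm Numeric vector of diameters in millimetres; all values
#'   must be strictly positive.
#' @return Numeric vector of volumes in cubic millimetres.
#' @examples
#' sphere_volume(c(5, 8, 10, 12))   # 65.45, 268.08, 523.60, 904.78
#' @seealso [diameter_from_volume()] for the inverse.
#' @export
sphere_volume <- function(diameter_mm) {
  if (!is.numeric(diameter_mm) || length(diameter_mm) == 0) {
    abort_domain("`diameter_mm` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0)) {
    abort_domain("`diameter_mm` must be finite and strictly positive.")
  }
  pi * diameter_mm^3 / 6
}

#' Presentation rounding for volumes
#'
#' Reference tables quote sphere volumes to one decimal by decimal half-up
#' rounding of the conventionally quoted two-decimal value: the 5-mm sphere
#' (65.4498... mm^3, quoted 65.45) prints as 65.5. Base `round()` uses
#' round-half-to-even on the binary value and yields 65.4, so table
#' rendering goes through this helper instead. Analysis always uses the
#' full-precision volumes.
#'
#' @param volume_mm3 Volumes in mm^3.
#' @param digits Decimals to keep (default 1).
#' @return Rounded volumes.
#' @export
round_volume <- function(volume_mm3, digits = 1) {
  q <- round(volume_mm3, digits + 1) # the quoted value
  f <- 10^digits
  sign(q) * floor(abs(q) * f + 0.5 + 1e-9) / f
}

#' Diameter of a sphere from its volume
#'
#' Exact closed-form inverse of [sphere_volume()]: \eqn{d = (6V/\pi)^{1/3}}.
#' Used to map measured volumes onto diameter-based management rules.
#'
#' @param volume_mm3 Numeric vector of volumes in cubic millimetres; strictly
#'   positive.
#' @return Numeric vector of diameters in millimetres.
#' @export
diameter_from_volume <- function(volume_mm3) {
  if (!is.numeric(volume_mm3) || length(volume_mm3) == 0) {
    abort_domain("`volume_mm3` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(volume_mm3)) || any(volume_mm3 <= 0)) {
    abort_domain("`volume_mm3` must be finite and strictly positive.")
  }
  (6 * volume_mm3 / pi)^(1 / 3)
}

#' Bronchopulmonary segment labels
#'
#' The 19 segment names used as nodule location metadata (10 right, 9 left,
#' with the left apicoposterior segment counted once). Labels are metadata
#' only; no spatial geometry is modelled.
#'
#' @return Tibble with columns `lobe_segment` and `side`.
#' @export
lung_segments <- function() {
  tibble::tibble(
    lobe_segment = c(
      "R apical (S1)", "R posterior (S2)", "R anterior (S3)",
      "R lateral (S4)", "R medial (S5)", "R superior (S6)",
      "R medial basal (S7)", "R anterior basal (S8)",
      "R lateral basal (S9)", "R posterior basal (S10)",
      "L apicoposterior (S1+2)", "L anterior (S3)",
      "L superior lingular (S4)", "L inferior lingular (S5)",
      "L superior (S6)", "L medial basal (S7)", "L anterior basal (S8)",
      "L lateral basal (S9)", "L posterior basal (S10)"
    ),
    side = rep(c("right", "left"), c(10L, 9L))
  )
}

#' Specify a phantom study design
#'
#' Describes the cohort the randomized arrangement generator should produce:
#' the number of phantom arrangements (each holding 0-8 nodules), the density
#' and size composition, and the seed. Composition vectors are interpreted in
#' one of two modes:
#'
#' * **exact-count mode** - integer counts per category (the default emulates
#'   the benchmark design: 178 solid + 148 ground-glass nodules across 59
#'   arrangements); the pooled cohort matches the counts exactly.
#' * **probability mode** - values summing to 1; categories are drawn
#'   independently per nodule and `n_nodules` must be given.
#'
#' @param n_arrangements Number of phantom arrangements (default 59).
#' @param density_mix Named vector over `c("solid", "ggn")`: exact counts or
#'   probabilities.
#' @param size_mix Named vector over diameters in mm (names coercible to
#'   numeric): exact counts or probabilities. Default: uniform over
#'   5/8/10/12 mm.
#' @param n_nodules Total nodule count; required when `density_mix` is given
#'   as probabilities, otherwise inferred as `sum(density_mix)`.
#' @param p_peripheral Probability that a nodule is peripheral rather than
#'   central (default 0.5).
#' @param seed Integer seed for the study-level random stream.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_arrangements = 59L,
                         density_mix = c(solid = 178L, ggn = 148L),
                         size_mix = c(`5` = 0.25, `8` = 0.25, `10` = 0.25, `12` = 0.25),
                         n_nodules = NULL,
                         p_peripheral = 0.5,
                         seed = 1L) {
  stopifnot(length(n_arrangements) == 1L, n_arrangements >= 1)
  if (is.null(names(density_mix)) || !all(names(density_mix) %in% DENSITIES)) {
    abort_domain("`density_mix` must be named with 'solid' and/or 'ggn'.")
  }
  if (is.null(names(size_mix)) || anyNA(suppressWarnings(as.numeric(names(size_mix))))) {
    abort_domain("`size_mix` must be named by numeric diameters (mm).")
  }
  density_mode <- mix_mode(density_mix, "density_mix")
  size_mode <- mix_mode(size_mix, "size_mix")

  if (density_mode == "count") {
    inferred <- sum(density_mix)
    if (!is.null(n_nodules) && n_nodules != inferred) {
      abort_domain("`n_nodules` disagrees with the exact counts in `density_mix`.")
    }
    n_nodules <- inferred
  } else if (is.null(n_nodules)) {
    abort_domain("`n_nodules` is required when `density_mix` is a probability mix.")
  }
  if (size_mode == "count" && sum(size_mix) != n_nodules) {
    abort_domain("exact `size_mix` counts must sum to the total nodule count.")
  }
  if (n_nodules > 8L * n_arrangements) {
    abort_domain(sprintf(
      "infeasible design: %d nodules exceed the capacity of %d arrangements x 8.",
      n_nodules, n_arrangements
    ))
  }
  structure(
    list(
      n_arrangements = as.integer(n_arrangements),
      density_mix = density_mix, density_mode = density_mode,
      size_mix = size_mix, size_mode = size_mode,
      n_nodules = as.integer(n_nodules),
      p_peripheral = p_peripheral,
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

# A mix is exact-count when its entries are non-negative integers not summing
# to 1; it is a probability mix when it sums to 1 (within tolerance).
mix_mode <- function(mix, what) {
  if (any(mix < 0)) abort_domain(sprintf("`%s` must be non-negative.", what))
  if (abs(sum(mix) - 1) < 1e-8) return("prob")
  if (all(abs(mix - round(mix)) < 1e-8)) return("count")
  abort_domain(sprintf("`%s` must be exact integer counts or probabilities summing to 1.", what))
}

draw_categories <- function(mix, mode, n) {
  labels <- names(mix)
  if (mode == "count") {
    sample(rep(labels, times = round(mix)))
  } else {
    sample(labels, n, replace = TRUE, prob = mix)
  }
}

#' Generate a randomized phantom nodule cohort
#'
#' Emulates the randomized arrangement procedure of a phantom benchmark: a
#' random generator decides, for every nodule, its size, density, lung
#' segment (hence side), and peripheral/central location, and allocates
#' nodules to arrangements so that every arrangement carries 0-8 nodules.
#' Allocation is a capacity-weighted sequential assignment: each nodule picks
#' an arrangement with probability proportional to its remaining capacity,
#' which guarantees feasibility whenever the design is feasible.
#'
#' The draw is fully reproducible from `design$seed`.
#'
#' @param design A [study_design()].
#' @return Tibble with one row per nodule: `id`, `arrangement_id`,
#'   `diameter_mm`, `true_volume_mm3`, `density`, `density_hu`, `side`,
#'   `lobe_segment`, `location`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "study_design"))
  n <- design$n_nodules
  segs <- lung_segments()
  withr_seed(design$seed, {
    density <- draw_categories(design$density_mix, design$density_mode, n)
    diameter <- as.numeric(draw_categories(design$size_mix, design$size_mode, n))
    seg_idx <- sample.int(nrow(segs), n, replace = TRUE)
    location <- ifelse(runif(n) < design$p_peripheral, "peripheral", "central")
    arrangement <- allocate_to_arrangements(n, design$n_arrangements, capacity = 8L)
  })
  tibble::tibble(
    id = sprintf("N%03d", seq_len(n)),
    arrangement_id = sprintf("A%02d", arrangement),
    diameter_mm = diameter,
    true_volume_mm3 = sphere_volume(diameter),
    density = density,
    density_hu = unname(DENSITY_HU[density]),
    side = segs$side[seg_idx],
    lobe_segment = segs$lobe_segment[seg_idx],
    location = location
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. Assignments inside propagate to the caller.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Sequential capacity-weighted allocation of n items into k cells of given
# capacity. Feasible whenever n <= k * capacity; cells may stay empty.
allocate_to_arrangements <- function(n, k, capacity = 8L) {
  remaining <- rep(capacity, k)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- sample.int(k, 1L, prob = remaining)
    remaining[out[i]] <- remaining[out[i]] - 1L
  }
  out
}

#' Split a cohort into per-arrangement nodule sets
#'
#' Convenience view of a cohort tibble as a named list of arrangements
#' (including empty ones), mirroring the physical phantom set-up.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param n_arrangements Total number of arrangements, so that arrangements
#'   holding zero nodules are represented; defaults to the number present.
#' @return Named list of tibbles, one per arrangement.
#' @export
arrangements <- function(cohort, n_arrangements = NULL) {
  ids <- sort(unique(cohort$arrangement_id))
  if (!is.null(n_arrangements)) {
    ids <- union(ids, sprintf("A%02d", seq_len(n_arrangements)))
    ids <- sort(ids)
  }
  out <- lapply(ids, function(a) cohort[cohort$arrangement_id == a, ])
  names(out) <- ids
  out
}
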