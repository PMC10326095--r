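# Detection and error-model samplers, the study simulator, and the
# voxelized volumetry option.

toy_cohort <- function(n = 4, density = "solid", diameter = 8) {
  tibble::tibble(
    id = sprintf("N%03d", seq_len(n)),
    arrangement_id = "A01",
    diameter_mm = diameter,
    true_volume_mm3 = sphere_volume(diameter),
    density = density,
    density_hu = ifelse(density == "solid", 100, -630),
    side = "left",
    lobe_segment = "L anterior (S3)",
    location = "peripheral"
  )
}

flat_detection <- function(system, p, manual_add) {
  detection_model(
    system,
    tidyr::expand_grid(
      density = c("solid", "ggn"), voltage_kv = c(80L, 100L, 120L)
    ) |> dplyr::mutate(p_detect = p),
    manual_add_allowed = manual_add
  )
}

flat_error <- function(system, mean_rve = 0, sd_rve = 0) {
  error_model(
    system,
    tidyr::expand_grid(density = c("solid", "ggn"), diameter_mm = c(5, 8, 10, 12)) |>
      dplyr::mutate(mean_rve = mean_rve, sd_rve = sd_rve)
  )
}

test_that("degenerate detection probabilities behave deterministically", {
  always <- flat_detection("dl_cad", 1, manual_add = FALSE)
  never_manual <- flat_detection("std_cad", 0, manual_add = TRUE)
  never_dl <- flat_detection("dl_cad", 0, manual_add = FALSE)

  set.seed(1)
  d1 <- sample_detection("solid", 120, always)
  expect_true(d1$detected)
  expect_false(d1$manually_added)

  d2 <- sample_detection("solid", 120, never_manual)
  expect_false(d2$detected)
  expect_true(d2$manually_added)

  d3 <- sample_detection("ggn", 80, never_dl)
  expect_false(d3$detected)
  expect_false(d3$manually_added)

  expect_error(sample_detection("solid", 140, always), "no entry")
})

test_that("noiseless error model reproduces ground truth exactly", {
  entry <- tibble::tibble(
    density = "solid", diameter_mm = 8, mean_rve = 0, sd_rve = 0,
    p_accurate = NA_real_, bias_shift = NA_real_
  )
  gt <- sphere_volume(8)
  expect_equal(sample_measurement(rep(gt, 10), entry), rep(gt, 10))
})

test_that("degenerate mixture has exactly two atoms at the configured means", {
  entry <- tibble::tibble(
    density = "solid", diameter_mm = 12, mean_rve = -0.05, sd_rve = 0,
    p_accurate = 0.5, bias_shift = -0.25
  )
  gt <- sphere_volume(12)
  set.seed(42)
  v <- sample_measurement(rep(gt, 2000), entry)
  r <- rve(v, gt)
  atoms <- sort(unique(round(r, 10)))
  expect_equal(atoms, c(-0.30, -0.05))
  p_acc <- mean(abs(r - (-0.05)) < 1e-9)
  expect_gt(p_acc, 0.4)
  expect_lt(p_acc, 0.6)
})

test_that("sample moments recover every configured error-model cell", {
  models <- default_error_models(bimodal = TRUE)
  n <- 2e4
  set.seed(99)
  for (sys in names(models)) {
    entries <- models[[sys]]$entries
    for (i in seq_len(nrow(entries))) {
      entry <- entries[i, ]
      gt <- sphere_volume(entry$diameter_mm)
      r <- rve(sample_measurement(rep(gt, n), entry), gt)
      mom <- error_entry_moments(entry)
      se_mean <- mom$sd / sqrt(n)
      expect_lt(
        abs(mean(r) - mom$mean), 4 * se_mean,
        label = sprintf(
          "mean recovery %s/%s/%gmm: |%.4f - %.4f|",
          sys, entry$density, entry$diameter_mm, mean(r), mom$mean
        )
      )
      # SD standard error ~ sd / sqrt(2(n-1)) for Gaussian-like cells
      expect_lt(abs(sd(r) - mom$sd), 6 * mom$sd / sqrt(2 * (n - 1)),
        label = sprintf("sd recovery %s/%s/%gmm", sys, entry$density, entry$diameter_mm)
      )
    }
  }
})

test_that("mixture with p_accurate = 1 matches the plain Gaussian draw for draw", {
  plain <- tibble::tibble(
    density = "ggn", diameter_mm = 5, mean_rve = 0.1, sd_rve = 0.3,
    p_accurate = NA_real_, bias_shift = NA_real_
  )
  mix1 <- dplyr::mutate(plain, p_accurate = 1, bias_shift = -0.25)
  gt <- sphere_volume(5)
  set.seed(7)
  a <- sample_measurement(rep(gt, 5000), plain)
  set.seed(7)
  b <- sample_measurement(rep(gt, 5000), mix1)
  # same normal draws; the mixture only consumes an extra uniform stream
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("simulate_study yields one record per nodule x system x voltage", {
  cohort <- generate_cohort(study_design(seed = 4))
  rec <- simulate_study(cohort, seed = 10)
  expect_equal(nrow(rec), 326 * 2 * 3)
  rec2 <- simulate_study(cohort, seed = 10)
  expect_identical(rec, rec2)
  expect_equal(attr(rec, "seed"), 10L)

  # detection-rate recovery: DL at 120 kV within 3 binomial SD of 0.979
  dl120 <- rec[rec$system == "dl_cad" & rec$voltage_kv == 120, ]
  expect_lt(
    abs(sum(dl120$detected) - 326 * 0.979),
    3 * sqrt(326 * 0.979 * 0.021)
  )

  # manual addition recovers every standard-system miss; DL misses have no volume
  std <- rec[rec$system == "std_cad", ]
  expect_true(all(!is.na(std$measured_volume_mm3)))
  expect_true(all(std$manually_added == !std$detected))
  dl <- rec[rec$system == "dl_cad", ]
  expect_equal(is.na(dl$measured_volume_mm3), !dl$detected)
  expect_true(all(!dl$manually_added))
})

test_that("observed detection frequencies stay inside binomial 99% bands", {
  cohort <- generate_cohort(study_design(seed = 21))
  rec <- simulate_study(cohort, seed = 22)
  dm <- default_detection_models()
  counts <- rec |>
    dplyr::inner_join(
      dplyr::select(cohort, nodule_id = id, density),
      by = "nodule_id"
    ) |>
    dplyr::group_by(system, density, voltage_kv) |>
    dplyr::summarise(n = dplyr::n(), k = sum(detected), .groups = "drop")
  for (i in seq_len(nrow(counts))) {
    p <- dm[[counts$system[i]]]$p_detect
    p <- p$p_detect[p$density == counts$density[i] & p$voltage_kv == counts$voltage_kv[i]]
    ci <- stats::binom.test(counts$k[i], counts$n[i])$conf.int
    ci99 <- stats::binom.test(counts$k[i], counts$n[i], conf.level = 0.99)$conf.int
    expect_true(p >= ci99[1] && p <= ci99[2],
      label = sprintf(
        "detection %s/%s/%dkV: p=%.3f in [%.3f, %.3f]",
        counts$system[i], counts$density[i], counts$voltage_kv[i], p, ci99[1], ci99[2]
      )
    )
  }
})

test_that("per-record sub-streams are stable under cohort growth", {
  small <- toy_cohort(3)
  grown <- dplyr::bind_rows(toy_cohort(4))  # same first 3 ids plus one
  r_small <- simulate_study(small, seed = 5)
  r_grown <- simulate_study(grown, seed = 5)
  keep <- r_grown$nodule_id %in% small$id
  expect_equal(
    as.data.frame(dplyr::arrange(r_grown[keep, ], nodule_id, system, voltage_kv)),
    as.data.frame(dplyr::arrange(r_small, nodule_id, system, voltage_kv))
  )
})

test_that("model coverage gaps are reported with the missing keys", {
  cohort <- toy_cohort(2, density = "ggn", diameter = 5)
  em <- list(
    dl_cad = flat_error("dl_cad"),
    std_cad = error_model(
      "std_cad",
      tibble::tibble(density = "solid", diameter_mm = 5, mean_rve = 0, sd_rve = 0.1)
    )
  )
  dm <- list(
    dl_cad = flat_detection("dl_cad", 1, FALSE),
    std_cad = flat_detection("std_cad", 1, TRUE)
  )
  expect_error(
    simulate_study(cohort, em, dm, seed = 1),
    "std_cad/ggn/5mm"
  )
})

test_that("voxelized volumetry converges on fine grids and clips coarse ones", {
  fine <- voxelized_volumetry(10, 0.1, 0.1, grid_offset = c(0.3, 0.1, 0.7))
  expect_lt(abs(fine - sphere_volume(10)) / sphere_volume(10), 0.01)

  coarse <- voxelized_volumetry(1, 50, 50, grid_offset = c(0.5, 0.5, 0.5), floor_mm3 = 0)
  expect_equal(coarse, 0)
})

test_that("voxelized volumetry is unbiased over random grid offsets", {
  # averaging the rasterized volume over uniform offsets recovers the true
  # volume (the partial-volume error is offset noise, not bias)
  set.seed(8)
  offs <- matrix(runif(3 * 120), ncol = 3)
  v <- apply(offs, 1, function(o) voxelized_volumetry(5, 0.68, 1.5, o))
  r <- rve(v, sphere_volume(5))
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)) + 0.01)
  expect_gt(sd(r), 0) # offsets genuinely perturb the measurement
})

test_that("voxelized volumetry matches a Monte-Carlo oracle", {
  set.seed(12)
  for (k in 1:3) {
    off <- runif(3)
    exact <- voxelized_volumetry(5, 0.68, 1.5, off)
    mc <- mc_voxel_volume(5, 0.68, 1.5, off, n_points = 2e5)
    # MC SE of the covered-volume estimate is ~1.5 mm^3 at this n
    expect_lt(abs(exact - mc), 6)
  }
})

test_that("measurement records round-trip through CSV and are validated", {
  cohort <- toy_cohort(5)
  em <- list(dl_cad = flat_error("dl_cad", 0, 0.1), std_cad = flat_error("std_cad", 0, 0.1))
  dm <- list(
    dl_cad = flat_detection("dl_cad", 0.5, FALSE),
    std_cad = flat_detection("std_cad", 0.5, TRUE)
  )
  rec <- simulate_study(cohort, em, dm, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(rec, path)
  back <- read_measurements(path)
  attr(rec, "seed") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(rec[, names(back)]))

  bad <- rec
  bad$measured_volume_mm3[which(bad$detected)[1]] <- NA
  expect_error(validate_measurements(bad), "iff detected")
  bad2 <- rec
  bad2$system[1] <- "other_cad"
  expect_error(validate_measurements(bad2), "unknown system")
})
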