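# Independent oracles used to freeze expected values. Each deliberately
# takes a different computational route than the implementation it checks.

# Bisection inverse of the sphere-volume map (checks the closed-form
# cube-root inverse).
bisect_diameter <- function(volume, lo = 1e-6, hi = 1e3, tol = 1e-10) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pi * mid^3 / 6 < volume) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments (ties in |d| not supported; zero differences excluded first).
wilcoxon_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  # two-sided: distance of V from its mean n(n+1)/4
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# Exact two-sided McNemar p by enumeration of Binomial(n, 1/2) outcomes.
mcnemar_enum_p <- function(b, c) {
  n <- b + c
  m <- min(b, c)
  k <- 0:n
  sum(stats::dbinom(k[k <= m | k >= n - m], n, 0.5))
}

# Kruskal-Wallis H computed from first principles (no ties assumed).
kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
}

# Permutation p-value for the Kruskal-Wallis test (label reshuffling).
kw_perm_p <- function(values, groups, n_perm = 20000) {
  h_obs <- kw_h(values, groups)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (kw_h(values, sample(groups)) >= h_obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Friedman chi-square from first principles (no within-block ties assumed).
friedman_chisq <- function(m) {
  # m: blocks x treatments matrix
  r <- t(apply(m, 1, rank))
  b <- nrow(m)
  k <- ncol(m)
  12 / (b * k * (k + 1)) * sum(colSums(r)^2) - 3 * b * (k + 1)
}

# Permutation p-value for the Friedman test (within-block label shuffles).
friedman_perm_p <- function(m, n_perm = 20000) {
  s_obs <- friedman_chisq(m)
  k <- ncol(m)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    mp <- t(apply(m, 1, function(row) row[sample.int(k)]))
    if (friedman_chisq(mp) >= s_obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Monte-Carlo estimate of the voxelized sphere volume: sample points
# uniformly in a bounding box and test whether the centre of the voxel
# containing each point lies inside the sphere. Independent route to the
# same quantity as voxelized_volumetry().
mc_voxel_volume <- function(diameter_mm, voxel_xy_mm, slice_mm, grid_offset,
                            n_points = 200000) {
  r <- diameter_mm / 2
  spacing <- c(voxel_xy_mm, voxel_xy_mm, slice_mm)
  half <- r + 2 * max(spacing)
  pts <- matrix(runif(3 * n_points, -half, half), ncol = 3)
  centre <- sapply(1:3, function(a) {
    k <- floor(pts[, a] / spacing[a] - grid_offset[a] + 0.5)
    (k + grid_offset[a]) * spacing[a]
  })
  inside <- rowSums(centre^2) <= r^2
  mean(inside) * (2 * half)^3
}

# Deterministic measurement records for a cohort: every record detected with
# measured volume = ground truth, except DL misses for the given nodule ids
# at every voltage. Standard misses (if any) are manually added.
records_with_dl_misses <- function(cohort, dl_missed_ids,
                                   voltages = c(80L, 100L, 120L)) {
  grid <- tidyr::expand_grid(
    nodule_id = cohort$id,
    system = c("dl_cad", "std_cad"),
    voltage_kv = voltages
  )
  grid <- dplyr::inner_join(
    grid,
    dplyr::select(cohort, nodule_id = id, true_volume_mm3),
    by = "nodule_id"
  )
  miss <- grid$system == "dl_cad" & grid$nodule_id %in% dl_missed_ids
  tibble::tibble(
    nodule_id = grid$nodule_id,
    system = grid$system,
    voltage_kv = grid$voltage_kv,
    detected = !miss,
    manually_added = FALSE,
    measured_volume_mm3 = ifelse(miss, NA_real_, grid$true_volume_mm3)
  )
}

# Reconstruct per-nodule category pairs from cross-table counts
# (rows = system A, cols = system B).
pairs_from_counts <- function(counts, levels) {
  a <- character(0)
  b <- character(0)
  for (i in seq_along(levels)) {
    for (j in seq_along(levels)) {
      k <- counts[i, j]
      if (k > 0) {
        a <- c(a, rep(levels[i], k))
        b <- c(b, rep(levels[j], k))
      }
    }
  }
  list(a = a, b = b)
}
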