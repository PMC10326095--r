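# Nonparametric test wrappers with uniform results and explicit handling of
# degenerate inputs (a degenerate input yields a flagged result, never a
# silent p = 1).

test_result <- function(test, statistic, p_value, n, degenerate = FALSE,
                        note = NA_character_) {
  tibble::tibble(
    test = test,
    statistic = statistic,
    p_value = p_value,
    n = as.integer(n),
    degenerate = degenerate,
    note = note
  )
}

#' Friedman test on complete blocks
#'
#' Rank-based test for a treatment effect with paired (blocked) samples,
#' e.g. the same nodules measured at each tube voltage. Blocks must be
#' complete (every treatment observed in every block).
#'
#' @param values Numeric responses.
#' @param groups Treatment labels (e.g. voltage).
#' @param blocks Block labels (e.g. nodule id).
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n` (blocks),
#'   `degenerate`, `note`.
#' @export
friedman_test <- function(values, groups, blocks) {
  groups <- factor(groups)
  blocks <- factor(blocks)
  tab <- table(blocks, groups)
  if (any(tab != 1)) {
    abort_domain("Friedman test requires complete blocks (one value per group per block).")
  }
  if (nlevels(groups) < 2) abort_domain("need at least 2 treatment groups.")
  if (all(tapply(values, blocks, function(v) length(unique(v)) == 1))) {
    return(test_result("friedman", NA_real_, NA_real_, nlevels(blocks),
      degenerate = TRUE, note = "all within-block values tied"
    ))
  }
  ht <- stats::friedman.test(values, groups, blocks)
  test_result("friedman", unname(ht$statistic), ht$p.value, nlevels(blocks))
}

#' Kruskal-Wallis test
#'
#' Rank-based test for a location difference among independent groups (the
#' unpaired counterpart of [friedman_test()]), with tie correction.
#'
#' @param values Numeric responses.
#' @param groups Group labels.
#' @return One-row tibble as in [friedman_test()]; `n` is the total sample
#'   size.
#' @export
kruskal_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort_domain("need at least 2 groups.")
  if (any(table(groups) == 0)) abort_domain("empty group.")
  if (length(unique(values)) == 1) {
    return(test_result("kruskal_wallis", NA_real_, NA_real_, length(values),
      degenerate = TRUE, note = "all values tied"
    ))
  }
  ht <- stats::kruskal.test(values, groups)
  test_result("kruskal_wallis", unname(ht$statistic), ht$p.value, length(values))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are excluded (the signed-rank convention); the exact
#' distribution is used for up to 25 non-zero differences and the normal
#' approximation (with continuity correction) beyond that. When every
#' difference is zero the result is flagged degenerate.
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble; `n` is the number of non-zero differences.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) abort_domain("paired vectors must have equal length.")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- sum(d != 0)
  if (nz == 0) {
    return(test_result("wilcoxon_signed_rank", NA_real_, NA_real_, 0L,
      degenerate = TRUE, note = "all paired differences are zero"
    ))
  }
  exact <- nz <= 25 && !any(duplicated(abs(d[d != 0])))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE)
  )
  test_result("wilcoxon_signed_rank", unname(ht$statistic), ht$p.value, nz)
}

#' McNemar test from discordant-pair counts
#'
#' Tests marginal homogeneity of two paired binary classifications (e.g.
#' "classified correctly" by each of two systems) from the two discordant
#' cell counts `b` and `c`. Uses the exact two-sided binomial test when
#' `b + c < 25` and the continuity-corrected chi-square statistic
#' `(|b - c| - 1)^2 / (b + c)` otherwise.
#'
#' @param b,c Discordant cell counts.
#' @return One-row tibble; `n` is `b + c`.
#' @export
mcnemar_counts <- function(b, c) {
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  n <- b + c
  if (n == 0) {
    return(test_result("mcnemar", NA_real_, NA_real_, 0L,
      degenerate = TRUE, note = "no discordant pairs"
    ))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    test_result("mcnemar", min(b, c), p, n, note = "exact binomial")
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    test_result("mcnemar", stat, p, n, note = "continuity-corrected chi-square")
  }
}

#' Compare RVE across voltage groups
#'
#' For each system x density stratum, tests whether the RVE distribution
#' differs across tube voltages. Nodules measured at all voltages form
#' complete blocks and are tested with the Friedman test; if blocks are
#' incomplete (some nodules missed at some voltages) the unpaired
#' Kruskal-Wallis test is used instead, mirroring the paired/unpaired
#' selection rule of the benchmark analysis.
#'
#' @param records Measurement records.
#' @param cohort Cohort tibble.
#' @return Tibble with one test row per (system, density).
#' @export
voltage_effect_tests <- function(records, cohort) {
  dat <- records |>
    dplyr::filter(!is.na(.data$measured_volume_mm3)) |>
    dplyr::inner_join(
      dplyr::select(cohort,
        nodule_id = "id", "density", "true_volume_mm3"
      ),
      by = "nodule_id"
    ) |>
    dplyr::mutate(rve = rve(.data$measured_volume_mm3, .data$true_volume_mm3))
  out <- list()
  for (sys in unique(dat$system)) {
    for (den in unique(dat$density)) {
      d <- dat[dat$system == sys & dat$density == den, ]
      n_volt <- length(unique(d$voltage_kv))
      if (n_volt < 2) next
      complete <- d |>
        dplyr::count(.data$nodule_id) |>
        dplyr::filter(.data$n == n_volt)
      res <- if (nrow(complete) == dplyr::n_distinct(d$nodule_id)) {
        friedman_test(d$rve, d$voltage_kv, d$nodule_id)
      } else {
        kruskal_test(d$rve, d$voltage_kv)
      }
      res$system <- sys
      res$density <- den
      out[[paste(sys, den)]] <- res
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate("system", "density")
}
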