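# Lung-RADS classification impact: category assignment from volumes,
# cross-tabulation between systems, concordance and correctness.

LUNGRADS_LEVELS <- c("2", "3", "4A", "4B")
LUNGRADS_ORDINALS <- c(`2` = 2L, `3` = 3L, `4A` = 4L, `4B` = 5L)

#' Baseline Lung-RADS volume thresholds (v1.1)
#'
#' Volume criteria of the ACR Lung-RADS v1.1 baseline-screening categories,
#' as a lower-bound-inclusive interval table per density class:
#' solid nodules `<113 mm^3` are category 2, `113-<268` category 3,
#' `268-<1767` category 4A, `>=1767` category 4B; pure ground-glass nodules
#' below the 30-mm border (`sphere_volume(30)` = 14'137.2 mm^3) are
#' category 2 and category 3 above it. The table is an ordinary tibble and
#' can be replaced by any versioned alternative with the same columns.
#'
#' @return Tibble with columns `density`, `lower_volume_mm3` (inclusive
#'   lower bound), `category`, `ordinal`, and a `version` attribute.
#' @export
lungrads_thresholds <- function() {
  out <- tibble::tribble(
    ~density, ~lower_volume_mm3, ~category,
    "solid", 0, "2",
    "solid", 113, "3",
    "solid", 268, "4A",
    "solid", 1767, "4B",
    "ggn", 0, "2",
    "ggn", sphere_volume(30), "3"
  )
  out$ordinal <- LUNGRADS_ORDINALS[out$category]
  attr(out, "version") <- "v1.1-baseline-volume"
  out
}

#' Assign baseline Lung-RADS categories from volumes
#'
#' Classifies each volume into the unique threshold interval of its density
#' class; lower bounds are inclusive, so a volume exactly on a border takes
#' the higher category (the true 8-mm sphere volume, 268.08 mm^3, sits just
#' above the 268 mm^3 category 3 / 4A border).
#'
#' Baseline (single-timepoint) rules only; growth-based reclassification at
#' follow-up is out of scope and requesting it errors.
#'
#' @param volume_mm3 Volumes (> 0).
#' @param density Density class per volume (`"solid"` / `"ggn"`, recycled if
#'   scalar).
#' @param thresholds Threshold table, default [lungrads_thresholds()].
#' @param timepoint Only `"baseline"` is implemented.
#' @return Ordered factor with levels `2 < 3 < 4A < 4B`.
#' @export
lungrads_classify <- function(volume_mm3, density,
                              thresholds = lungrads_thresholds(),
                              timepoint = "baseline") {
  if (!identical(timepoint, "baseline")) {
    stop("only baseline classification is implemented; ",
      "growth-based follow-up categories are not supported.",
      call. = FALSE
    )
  }
  if (any(volume_mm3 <= 0, na.rm = TRUE)) abort_domain("volumes must be positive.")
  if (length(density) == 1) density <- rep(density, length(volume_mm3))
  stopifnot(length(density) == length(volume_mm3))
  out <- character(length(volume_mm3))
  for (den in unique(density)) {
    rows <- thresholds[thresholds$density == den, ]
    if (nrow(rows) == 0) {
      abort_domain(sprintf("threshold table does not cover density '%s'.", den))
    }
    rows <- rows[order(rows$lower_volume_mm3), ]
    i <- density == den
    out[i] <- rows$category[findInterval(volume_mm3[i], rows$lower_volume_mm3)]
  }
  factor(out, levels = LUNGRADS_LEVELS, ordered = TRUE)
}

#' Ground-truth Lung-RADS category of a nodule
#'
#' [lungrads_classify()] applied to the known true volume; the reference
#' against which a system's category assignment is scored.
#'
#' @param cohort Cohort tibble (needs `true_volume_mm3`, `density`).
#' @param thresholds Threshold table.
#' @return Ordered factor, one category per cohort row.
#' @export
ground_truth_category <- function(cohort, thresholds = lungrads_thresholds()) {
  lungrads_classify(cohort$true_volume_mm3, cohort$density, thresholds)
}

#' Ordinal coding of Lung-RADS categories
#'
#' Minimal monotone integer coding (2, 3, 4A, 4B -> 2, 3, 4, 5) used when
#' categories enter a rank-based test.
#'
#' @param category Factor/character of categories.
#' @return Integer vector.
#' @export
lungrads_ordinal <- function(category) {
  unname(LUNGRADS_ORDINALS[as.character(category)])
}

#' Cross-tabulate paired category assignments
#'
#' Counts of nodules by (system A category, system B category), with
#' margins, ordered by category ordinal.
#'
#' @param cat_a,cat_b Equal-length category vectors (system A = rows,
#'   system B = columns).
#' @param levels Category levels to tabulate over (default: those observed,
#'   in ordinal order).
#' @return Object of class `lungrads_crosstab`: list with `counts` (matrix),
#'   `row_margins`, `col_margins`, `n`.
#' @export
cross_tabulate <- function(cat_a, cat_b, levels = NULL) {
  if (length(cat_a) != length(cat_b)) {
    abort_domain("category vectors must have equal length.")
  }
  if (is.null(levels)) {
    levels <- intersect(LUNGRADS_LEVELS, union(as.character(cat_a), as.character(cat_b)))
  }
  a <- factor(as.character(cat_a), levels = levels)
  b <- factor(as.character(cat_b), levels = levels)
  counts <- table(a, b)
  counts <- matrix(as.integer(counts), nrow = nlevels(a), dimnames = dimnames(counts))
  names(dimnames(counts)) <- c("system_a", "system_b")
  structure(
    list(
      counts = counts,
      row_margins = rowSums(counts),
      col_margins = colSums(counts),
      n = sum(counts)
    ),
    class = "lungrads_crosstab"
  )
}

#' @export
print.lungrads_crosstab <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_margins)
  m <- rbind(m, Total = c(x$col_margins, x$n))
  print(m)
  invisible(x)
}

#' Concordance of a category cross-table
#'
#' Off-diagonal mass of the cross-table: how many nodules the two systems
#' place in different management categories, overall and per cell with the
#' staging direction (system A above system B = "down" move for A->B).
#'
#' @param crosstab A [cross_tabulate()] result.
#' @return List with `discordant_n`, `discordant_rate` (`NA` when `n` is 0,
#'   flagged via `note`), and `per_cell_moves` (tibble: `from`, `to`, `n`,
#'   `direction`).
#' @export
concordance <- function(crosstab) {
  stopifnot(inherits(crosstab, "lungrads_crosstab"))
  cm <- crosstab$counts
  lv <- rownames(cm)
  moves <- list()
  disc <- 0L
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (i != j && cm[i, j] > 0) {
        disc <- disc + cm[i, j]
        moves[[length(moves) + 1L]] <- tibble::tibble(
          from = lv[i], to = lv[j], n = cm[i, j],
          direction = unname(ifelse(
            LUNGRADS_ORDINALS[lv[j]] > LUNGRADS_ORDINALS[lv[i]], "up", "down"
          ))
        )
      }
    }
  }
  list(
    discordant_n = disc,
    discordant_rate = if (crosstab$n > 0) disc / crosstab$n else NA_real_,
    per_cell_moves = if (length(moves)) dplyr::bind_rows(moves) else
      tibble::tibble(
        from = character(), to = character(),
        n = integer(), direction = character()
      ),
    note = if (crosstab$n == 0) "empty table: rate undefined" else NA_character_
  )
}

#' Classification correctness against ground truth
#'
#' Scores assigned categories against ground-truth categories: a nodule is
#' correct iff the categories match exactly. Also breaks misclassifications
#' down by nodule size, since errors concentrate where the true volume sits
#' near a category border.
#'
#' @param assigned,truth Equal-length category vectors.
#' @param diameter_mm Optional nodule diameters for the by-size breakdown.
#' @return List with `correct_n`, `n`, `rate`, and `by_size` (tibble with
#'   `diameter_mm`, `n`, `n_misclassified`; empty when no diameters given).
#' @export
correctness <- function(assigned, truth, diameter_mm = NULL) {
  if (length(assigned) != length(truth)) {
    abort_domain("assigned and ground-truth vectors must have equal length.")
  }
  if (length(assigned) == 0) abort_domain("no classifications to score.")
  ok <- as.character(assigned) == as.character(truth)
  by_size <- if (is.null(diameter_mm)) {
    tibble::tibble(
      diameter_mm = numeric(), n = integer(), n_misclassified = integer()
    )
  } else {
    tibble::tibble(diameter_mm = diameter_mm, ok = ok) |>
      dplyr::group_by(.data$diameter_mm) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_misclassified = sum(!.data$ok),
        .groups = "drop"
      )
  }
  list(
    correct_n = sum(ok),
    n = length(ok),
    rate = mean(ok),
    by_size = by_size
  )
}
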