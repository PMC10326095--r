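---
title: "Volumetric agreement analysis for CAD nodule measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric agreement analysis for CAD nodule measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volagree)
```

## The problem

Lung-cancer screening guidelines base nodule management on volumetry, and an
increasing share of those volumes comes from computer-aided diagnosis (CAD)
software rather than human readers. Two CAD systems measuring the *same*
nodule can disagree enough to move it across a Lung-RADS management border,
changing the follow-up a patient receives. `volagree` implements the analysis
chain used to quantify that risk in anthropomorphic phantom benchmarks, where
artificial spherical nodules provide a perfect ground truth:

1. a **synthetic phantom-study generator** (randomized nodule arrangements,
   per-system detection and measurement-error models),
2. the **agreement statistics** of method-comparison studies (relative
   volumetric error, between-system volume differences, Bland–Altman limits
   of agreement, paired nonparametric tests), and
3. the **classification-impact analysis** (Lung-RADS categories from measured
   vs. true volumes, cross-tabulation between systems, concordance and
   correctness).

## Statistics

For a nodule with ground-truth volume $GT$ and a measured volume $V$, the
relative volumetric error is

$$\mathrm{RVE} = \frac{V - GT}{GT}.$$

Between the two systems (deep-learning CAD volume $V_{DL}$, standard CAD
volume $V_{std}$) the absolute and relative volume differences are

$$\mathrm{AVD} = V_{DL} - V_{std}, \qquad
  \mathrm{RVD} = \frac{\mathrm{AVD}}{V_{std}}.$$

All three are fractions internally; multiplication by 100 and 1-decimal
formatting happen only at the reporting layer (`format_percent()`), which
avoids double-scaling bugs.

Agreement between the systems is summarised with the Bland–Altman method:
the RVD of each nodule is plotted against the average of the two measured
volumes, and the limits of agreement are

$$\mathrm{LOA} = \bar d \pm z\, s_d,$$

with $\bar d$ and $s_d$ the mean and sample SD ($n-1$ denominator) of the
differences and $z = 1.96$ by default ($z$ is configurable because some
studies use 2.0). Under normality the interval covers the central ~95% of
between-method differences; a property test checks empirical coverage on
simulated Gaussian differences stays in $[0.93, 0.97]$.

Group comparisons use the tests conventional in this literature: the
Friedman test when the same nodules appear in every group (complete blocks,
e.g. three voltages of the same acquisition series), the Kruskal–Wallis test
otherwise — `voltage_effect_tests()` selects automatically on block
completeness — the Wilcoxon signed-rank test for paired between-system
comparisons, and McNemar's test for paired correct/incorrect classification
rates (exact binomial for fewer than 25 discordant pairs, continuity-
corrected $\chi^2$ beyond). No multiplicity correction is applied: the
analysis is descriptive, matching practice in this study type.

## The synthetic-data generator

The generator's defaults emulate a published two-system phantom benchmark
and are treated as fixed study conditions, not tuning knobs:

* **Cohort**: 59 phantom arrangements, 0–8 nodules each, 326 nodules in
  total (178 solid at +100 HU, 148 ground-glass at −630 HU), four diameters
  5/8/10/12 mm with exact sphere volumes $\pi d^3/6$ (65.45, 268.08, 523.60,
  904.78 mm³). Size mix, sides, one of 19 bronchopulmonary segment labels,
  and peripheral/central location are randomized per nodule; segments are
  metadata only (no spatial geometry is modelled, since none of the
  downstream statistics uses it).
* **Acquisitions**: tube voltages 80/100/120 kV. Voltage affects detection
  only, not measurement error — the benchmark found no voltage effect on
  volumetry, and building one in would contradict the conditions being
  emulated.
* **Detection**: the DL system detects with per-voltage rates
  0.942/0.972/0.979 (both densities) and cannot recover misses; the standard
  system detects automatically with per-density rates 172/178 (solid) and
  94/148 (ground-glass) — derived from the published automatic-detection
  counts, constant across voltages — and every miss is manually added, so it
  always produces a volume.
* **Measurement error**: per (system, density, size) cell,
  $V = GT(1 + \mathrm{RVE})$ with $\mathrm{RVE} \sim N(\mu, \sigma^2)$ from
  the published per-cell means and SDs (e.g. DL solid 5 mm: 12.2% ± 20.8%;
  standard GGN 5 mm: 81.0% ± 47.6%). Volumes are floored at 1 mm³ — physical
  volumes are positive, and with the configured parameters the floor binds
  with negligible probability (the nearest cell needs a −3.8 SD draw).
* **Cluster artefact**: the DL system's solid 10-mm and 12-mm cells default
  to a two-component mixture — with probability `p_accurate = 0.5` the plain
  Gaussian, otherwise the same Gaussian shifted by `bias_shift = −0.25` —
  emulating the reported behaviour where one cluster of large solid nodules
  is measured accurately and a second is systematically underestimated. The
  benchmark did not quantify the proportion or the offset, so these defaults
  are explicit modelling assumptions (configurable, and disabled with
  `default_error_models(bimodal = FALSE)` when pure per-cell Gaussians are
  wanted). Parameter-recovery checks compare simulated moments against the
  mixture-implied mean $\mu + (1-p)\delta$ and variance
  $\sigma^2 + p(1-p)\delta^2$.
* **Joint error structure**: errors are independent across nodules, systems
  and voltages by default. The dispersion of RVD depends on the unknown
  between-system error correlation; `rho` couples the two systems' Gaussian
  quantiles through a copula if a non-zero value is wanted, and the default
  0 is the conservative documented choice.

What the generator does **not** emulate: CT physics (noise texture, kernels,
partial-volume blur), irregular nodule shapes, vascular/pleural attachment,
or the internals of either commercial CAD system. Passing tests therefore
demonstrate that the analysis chain is correct and that the statistical
structure the benchmark reported is recovered — not that either CAD system
behaves as modelled on real patients. A mechanistic alternative,
`voxelized_volumetry()`, rasterizes a sphere onto a CT-like grid and shows
how partial-volume effects alone produce offset-dependent (zero-mean)
volume errors.

## Randomness and reproducibility

One study-level stream is seeded from the design; `simulate_study()` derives
one sub-stream per (nodule, system, voltage) via a deterministic string
hash, so the records of a given nodule are invariant to adding or removing
other nodules — a property the regression tests rely on. Nodules are
allocated to arrangements by capacity-weighted sequential assignment (each
nodule picks an arrangement with probability proportional to remaining
capacity out of 8), which is feasible by construction at any feasible design
size; naive resampling of unconstrained multinomial allocations has
vanishing acceptance at 326 nodules across 59 arrangements.

## Pairing rule and denominators

The paired between-system analysis is run at one voltage (default 120 kV,
the best-detection acquisition; configurable). A nodule is paired iff the DL
system produced a volume for it; standard-system volumes always exist via
manual addition. Two denominators coexist by design: between-system
comparisons use the paired solid nodules, while standard-system correctness
is scored on *all* solid nodules (its misses were recovered). With the
benchmark's miss pattern (4 solid + 3 GGN DL misses out of 326) the pairing
rule yields 319 analysable nodules (174 solid, 145 GGN), which the tests
reproduce exactly.

## Lung-RADS thresholds

Categories are assigned from volumes directly (the quoted borders are
volumes). The default table is the ACR Lung-RADS v1.1 baseline volume
criteria: solid < 113 mm³ → 2, 113–<268 → 3, 268–<1767 → 4A, ≥1767 → 4B;
ground-glass below the 30-mm border volume ($\pi\,30^3/6 = 14{,}137.2$ mm³)
→ 2, else 3. Lower bounds are inclusive, so the true 8-mm volume
(268.08 mm³) sits in 4A — just 0.03% above the 3/4A border, which is why
classification errors concentrate in the 8-mm group: a ±1% volume
perturbation flips the 8-mm category and none of the others. The table is an
ordinary, versioned tibble and can be replaced; growth-based (follow-up)
classification is deliberately not implemented and errors if requested.
Categories entering the Wilcoxon test are coded by the minimal monotone
integers 2/3/4A/4B → 2/3/4/5.

## Numerical and presentation choices

* Volumes are carried at full precision; reference tables quote them to one
  decimal by half-up rounding of the conventional two-decimal quote
  (65.4498… → 65.45 → 65.5), which `round_volume()` implements. Base
  `round()`'s half-to-even rule would print 65.4.
* `sd_rve = 0` is accepted as the degenerate noiseless limit (useful for
  exactness checks); a Bland–Altman analysis of zero-spread differences is
  flagged `degenerate` rather than silently returning collapsed limits, and
  each test wrapper flags all-tied inputs instead of fabricating p = 1.
* The Friedman/Kruskal–Wallis/Wilcoxon wrappers delegate to the standard
  R implementations; the test suite checks them against independent
  enumeration and permutation oracles. The Friedman p-value is the
  chi-square approximation, whose small-sample error (a few hundredths at a
  dozen blocks) is documented in the oracle test's tolerance.

## Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerances while keeping the default suite fast: 2×10⁴
draws per error-model cell for moment recovery (10⁴ in the headline
recovery check, tolerance 3 standard errors), 10⁴ Gaussian differences for
LOA coverage, 10³ replicates for the Kruskal–Wallis type-I-error check, and
2×10⁴ permutations per oracle comparison. The full pipeline runs at the
study scale (326 nodules × 2 systems × 3 voltages = 1956 records) in about
a second.

## Known limitations

* The error models are per-cell Gaussians (plus the documented mixture);
  real CAD errors can be skewed and volume-dependent within a size group.
* Detection is Bernoulli per record; the benchmark hints its DL misses were
  partly the same nodules across voltages, a dependence not modelled.
* Published per-system correctness rates cannot be reproduced exactly
  without the benchmark's raw per-nodule measurements; the package
  reproduces the printed-count arithmetic and the qualitative signature
  (errors concentrated at the 8-mm border) instead.
* Two published lower limits of agreement are not exactly consistent with
  their own printed mean/SD under $z = 1.96$ (deviations ≈ 0.2 percentage
  points, beyond what input rounding can explain); the tests document the
  discrepancy rather than hiding it.

## A minimal run

```{r example, eval = FALSE}
cfg <- study_config(seed = 7)
report <- run_pipeline(cfg)
report
write_report(report, "report")
plot_bland_altman(subset(report$paired, density == "solid"))
```
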