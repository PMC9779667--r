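---
title: "Decision phenotyping of hypocotyl-root growth trade-offs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision phenotyping of hypocotyl-root growth trade-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decisionscreen)
```

## The phenotyping problem

A dark-grown seedling faces a budget allocation problem: hypocotyl
elongation (reaching for light) and primary root growth (reaching for
water) compete for the same limited reserves. Combining darkness with
water deficit — the `darkW` condition, a PEG-infused medium at about
-0.4 MPa water potential — creates a conflict-of-interest scenario in
which the wild type re-allocates growth from the hypocotyl to the root.
A genotype that cannot arbitrate this trade-off is a *decision mutant*:
it perceives both cues but fails to integrate them.

`decisionscreen` implements the quantitative readout of such a screen:
normalized response quotients with their significance cascade, the
classification of genotypes into response classes and "confused"
decision phenotypes, the decomposition of hypocotyl growth into cellular
contributions, and the root-apical-meristem zonation analysis. A seeded
synthetic-data generator reproduces the statistical structure of the
screen so every stage is testable without raw measurements.

## The response-quotient model

For an organ with per-seedling lengths $L$ measured in the dark and
under darkW, the organ response is the ratio of group means,

$$R_{\text{organ}} = \frac{\overline{L}_{\text{dark}}}{\overline{L}_{\text{darkW}}},$$

and the trade-off readout is the ratio adjustment

$$R_{\text{ratio}} = \frac{(\overline{H}/\overline{R})_{\text{dark}}}{(\overline{H}/\overline{R})_{\text{darkW}}}
                   = \frac{R_{\text{hypocotyl}}}{R_{\text{root}}},$$

with $H$ the hypocotyl and $R$ the root length. Seedlings are not paired
across conditions, so per-seedling responses are undefined; the ratio of
group means is the only computable reading of the formula, and the
factorization above is asserted as an algebraic identity in the test
suite.

PEG lots and plates vary substantially, so raw responses are not
comparable across experiments. Every response is therefore normalized to
the wild-type ecotype grown *on the same plate*:

$$RQ = \frac{R_{\text{mutant}}}{R_{\text{wild type}}},$$

giving $RQ = 1$ for a wild-type-like response. The per-genotype summary
is the mean RQ over at least three biological replicates together with
the median of the per-replicate response p-values (with an even number
of replicates, the median is the mean of the two central values; fewer
than three replicates are flagged `"insufficient"`).

### Significance cascade

Each response's p-value compares the per-seedling measurements between
dark and darkW; `p_ratio` compares per-seedling hypocotyl/root ratios,
the quantity whose distribution the screen actually inspects. The test
is selected per comparison:

1. Shapiro-Wilk on each group at $\alpha = 0.05$; if either rejects,
   the two-sided Mann-Whitney U test is used. The screen verified
   normality only for selected samples; automation requires a uniform
   rule, and 0.05 is the conventional gate.
2. Otherwise a Brown-Forsythe (median-centred Levene) test at
   $\alpha = 0.05$ decides between Student's (equal variances) and
   Welch's (unequal) two-tailed t test. The variance gate is not named
   in the source protocol; the median-centred variant is chosen for its
   robustness to mild non-normality.

Two identical constant samples return $p = 1$ with a warning. Across a
declared comparison family (e.g. a wavelength series) p-values are
corrected with the Benjamini-Hochberg step-up (`bh_adjust()`, a thin
wrapper over `stats::p.adjust`; the test suite checks it against an
independent brute-force implementation of the step-up definition).

### Classification thresholds

* RQ: attenuated $< 0.8$, normal $0.8$–$1.2$ (both boundaries
  inclusive), exaggerated $> 1.2$.
* p-value: insignificant $\ge 0.05$, attenuated significance
  $[10^{-5}, 0.05)$, significant $< 10^{-5}$.

The volcano plot places the mean $RQ_{\text{ratio}}$ on the x-axis
against $-\log_{10}$ median $P_{\text{ratio}}$ on the y-axis. A genotype
is **confused** when it sits in the lower-left quadrant: mean
$RQ_{\text{ratio}} < 0.8$ *and* median $P_{\text{ratio}} \ge 10^{-5}$.
The quadrant's p-boundary is deliberately the attenuated-significance
threshold rather than 0.05: genotypes with median ratio p-values of
0.003–0.02 belong in the confused quadrant, and only this boundary
reproduces that membership. This is an inference from quadrant
membership, not a printed rule, and is configurable.

A **decision mutant** must meet all three criteria:

1. *ratio failure* — attenuated $RQ_{\text{ratio}}$, or any organ
   responding in the inverse direction (both the mutant's and the wild
   type's responses significantly different from 1 at 0.05 but on
   opposite sides of it);
2. *weak significance* — median $P_{\text{ratio}}$ insignificant or of
   attenuated significance;
3. *organ exceedance* — one organ significantly longer than the paired
   wild type under darkW (mean greater and cascade p < 0.05).

## Hypocotyl geometry

Hypocotyl volume uses the screen's working formula $V = \pi W L$ (width
times length), implemented verbatim despite its dimensional oddity; the
conventional cylinder volume $\pi (W/2)^2 L$ sits behind
`proper_cylinder = TRUE`, default off. Cell anisotropy is the 2D ratio
length/width. `contribution_table()` computes fold changes (FC) of group
means relative to a reference condition (light, by default) and reports
the cellular contribution as $100 \cdot FC_{\text{cell}} /
FC_{\text{organ}}$ for matched length and width pairs. The straight FC
ratio is adopted because reported contributions can exceed 100%, which a
$(FC - 1)$-based share could not produce; the exact arithmetic behind
the published tabulation is not stated, so this is a documented package
choice.

## Root meristem zonation

### Two-Gaussian mixture by EM

Cell lengths along an epidermal file from the quiescent centre (QC) fall
into a short meristematic population and a long elongating population.
`fit_two_gaussian_em()` fits the two-component Gaussian mixture by
expectation maximization, pooled per condition (per-root fitting sits
behind `per_root = TRUE`). Numerical choices:

* **Initialization**: the sample is split at its median and each half
  seeds one component — deterministic and robust when the zones are
  separated. Seeded random restarts (`init = "random"`) are available
  for pathological inputs.
* **Convergence**: relative log-likelihood change below $10^{-8}$, at
  most 500 iterations. The log-likelihood trace is retained and its
  monotone non-decrease is asserted on every fit in the test suite.
* **Degeneracy**: variances are floored at $10^{-6}\ \mu m^2$ and a
  vanishing component or floored variance flags the fit degenerate with
  a warning rather than an error.
* Components are labelled by mean order, the smaller mean being
  "short".

A cell is **meristematic** when its posterior probability of belonging
to the short component strictly exceeds 0.8. The meristem size from the
GMM is reported two ways — the total count of meristematic cells and the
contiguous run from the QC — because published figures are compatible
with either reading.

### Rule-based counts

* **Isodiametric cells**: the initial run from the QC of cells not
  longer than wide (length $\le$ width), stopping at the first cell
  longer than wide. A whole-file count sits behind
  `contiguous = FALSE`.
* **Transition cells**: from the first cell longer than wide, extended
  while each next cell is under 150% of its predecessor's length; the
  scan stops at the first ratio $\ge 1.5$ (the contiguous-run reading of
  the rule).
* **Mature cell length**: mean of the ten most elongated cells, pooled
  per condition (the per-condition pooling follows the wording of the
  source legend; note the top-10 of a pooled sample is an order
  statistic, so it exceeds the mature-population mean).
* **First elongated cell**: length of the lowest-index cell labelled
  elongating; all-meristematic files return `NA` with a warning.

Both scan rules are checked against exhaustive brute-force oracles on
random files in the test suite.

### Positional curves and mitotic index

`positional_curve()` pools (cell index, value) points across roots and
smooths them with local polynomial regression (`stats::loess`, tricube
weights; defaults span 0.75, degree 2 — the method's conventional
defaults). When a neighbourhood has too few points for the polynomial
degree the span is widened by 50% with a warning rather than failing.
The confidence band is a seeded bootstrap over whole roots (200
resamples by default, pointwise quantiles), which preserves the
within-file correlation of consecutive cells. The maximum fitted
per-cell slope and its index are reported as diagnostics of the
elongation ramp ("steep slope") and its onset ("kink").

`mitotic_summary()` reduces per-root counts of an M-phase marker to
per-condition means and pairwise fold changes, tested by Mann-Whitney U
with Benjamini-Hochberg correction across the requested pairs.

## What the synthetic generator emulates

The generator is the package's stand-in for the screen's raw
measurements; its defaults encode the study conditions and are the
fixtures all tests run against.

* **Conditions** (`default_conditions()`): dark — long hypocotyl
  (Normal(10, 1.5) mm), short root (Normal(3, 0.8) mm); darkW — the
  trade-off flipped (hypocotyl Normal(5, 1), root Normal(9, 3), i.e.
  root variance inflated about three-fold, reflecting the high
  wild-type root variance under combined stress); light and lightW
  complete the vocabulary. No per-seedling dispersion is printed in the
  source, so the sds are generator choices shaped to the published
  distributions' qualitative form.
* **Plate effects**: multiplicative log-normal (sd 0.1) per plate and
  organ; lot-to-lot variation is reported but unquantified, so the
  magnitude is a package choice. Each mutant cohort shares its plate
  with a wild-type cohort, which is what the same-plate normalization
  consumes.
* **Response classes**: a multiplier $m$ on an organ divides that
  organ's darkW mean, so the configured multiplier *is* the expected
  organ RQ; mutant dispersions scale with the shifted mean (constant
  coefficient of variation), keeping the multiplier's meaning free of
  truncation bias from the positivity resampling. Presets: normal
  (1, 1), attenuated (hypocotyl 0.5), exaggerated (1.5), confused (both
  organ adjustments cancelled, noise doubled — so the ratio response is
  attenuated *and* erratic), inverse (root response driven above 1,
  i.e. roots shorter under darkW than dark, with a non-adjusting
  hypocotyl that exceeds the wild type — the decision-mutant archetype
  on all three counts), perception-null (wild-type-like darkW
  adjustment; its defining light-response defect lies outside the
  dark/darkW contrast).
* **Cell files** (`default_cell_file_specs()`): meristem cells
  Normal(8, 1.5) µm long against widths around 11–12 µm (so the zone
  nearest the QC is isodiametric on average), then geometric growth per
  cell position until a per-root mature length is reached. darkW has
  the smallest meristem (18 cells vs 25 dark / 30 light), the steepest
  elongation ramp (rate 2.0 per cell vs 1.35/1.30) and hence the
  longest first elongated cell, while mature length peaks in the dark
  (220 µm) — the condition ordering the zonation stage exists to
  detect. Elongation-zone noise is half the meristem's coefficient of
  variation: positional growth is more regular than meristem cell size,
  and the contrast in exit length would otherwise be blurred.
* **Mitotic counts**: Poisson with means light 4, dark 1, darkW 8 —
  an eight-fold dark-to-darkW increase.

What it does **not** emulate: germination timing, root system
architecture, any biomechanics, 3D cell geometry, or measurement error
models beyond Gaussian/Poisson noise. Passing tests therefore
demonstrate that the statistics recover known structure under the
model's assumptions, not that the assumptions hold for any particular
real dataset.

## Problem sizes and reproducibility

Monte-Carlo checks run at the sizes a desk-scale validation needs: 200
simulated screens at 40 seedlings per group for calibration and
confused-call sensitivity, 2,000 null simulations for the type-I error
of the test cascade, 50 replicate mixture fits for EM parameter
recovery, 20 roots per condition for zonation ordering and 100 for the
mitotic fold change. All generators are pure functions of
(configuration, seed); `run_pipeline()` writes a manifest with the seed
and a configuration hash, and identical configuration and seed yield
byte-identical outputs.

## Known limitations

* Plate effects are normalized away by the paired wild type, not
  modelled; there is no mixed-effects decomposition of variance.
* The confused-quadrant p-boundary ($10^{-5}$) reproduces published
  quadrant memberships but is an inference; both thresholds are
  arguments, not constants.
* Whether group locations should be means or medians is not stated in
  the source protocol; means are used throughout.
* The EM fit assumes exactly two Gaussian components; files with a
  prominent transition population can inflate the short component. The
  rule-based counts provide an independent, model-free estimate.
* With small groups (n per group below ~20) the significance cascade
  loses power and attenuated lines drift into the confused quadrant —
  an honest property of the readout, visible in the demo configuration.

## A minimal session

```{r example, eval = FALSE}
gts <- list(
  genotype_spec("Ws2", "Ws2", "normal"),
  genotype_spec("bin2like", "Ws2", "inverse"),
  genotype_spec("confused_line", "Ws2", "confused")
)
screen <- generate_screen_dataset(gts, n_per_group = 40, seed = 1)
calls <- classify_screen(screen)
volcano_plot(calls)

files <- generate_cell_files(default_cell_file_specs(), n_roots = 8, seed = 2)
zonation <- zonation_summary(files)
zonation$per_condition
plot(positional_curve(subset(files, condition == "darkW"), "length", seed = 3))
```
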