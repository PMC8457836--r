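---
title: "Methods: heat-stress phenotyping of reef corals with reefheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-stress phenotyping of reef corals with reefheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefheat)
```

## The measurement model

`reefheat` analyses a standardized coral heat-stress ("bleaching") assay.
Each tagged colony contributes five nubbins: two controls held at ambient
temperature (30 degC) and three heated along a daily ramp-hold-cool profile
(3 h ramp to 34, 34.5 or 35 degC, 3 h hold, 1 h cool-down, repeated on two
days; `assay_design()` / `ramp_setpoint()`). After the assay, tissue
homogenate is run on a flow cytometer in triplicate.

Three phenotypes per colony come out of the pipeline:

* **Symbiont load** -- the fraction of counted cells that are
  symbiont-containing. Events are gated by two strict thresholds: chlorophyll
  fluorescence above `chl_threshold` marks a symbiont-containing cell; of the
  rest, forward scatter above `fsc_threshold` marks a symbiont-free coral
  cell; everything else is debris. The load is
  `n_symbiont / (n_symbiont + n_coral)`: "total cell count" is read as total
  *cells*, so debris is excluded from the denominator. Because gating
  protocols are instrument-specific and no universal channel units exist,
  thresholds are mandatory configuration for real data; for simulated data
  they default to the log-scale midpoints between the generating populations.
  An alternative `load = symbiont cells / all events` mode exists behind
  `load_denominator = "events"` for sensitivity analysis only.
* **Retention** -- mean heated-nubbin load (pooled across the three target
  temperatures, since the assay reports a single heated proportion per
  colony) divided by mean control-nubbin load. Retention above 1 is real
  (some colonies gain symbionts relative to controls) and never capped.
  Colonies with mean control load below 0.005 are excluded from the ratio as
  numerically unstable, and logged.
* **Growth** -- annual linear extension `(d1 - d0) * 365.25 / interval` and
  percent growth `100 (d1 - d0) / d0` from repeat diameter surveys. Size
  *decreases exceeding 10%* are attributed to damage or disease and excluded
  (strictly below -10%; exactly -10% is retained, reading "exceeding"
  literally).

Thermal microhabitat is summarized from 10-minute logger series as the
number of sampling intervals *strictly above* a threshold (31-35 degC by
default). Counts are averaged over a reef's loggers, not pooled, and are not
normalized by deployment length (raw interval counts are what the field
reports); colonies inherit their reef's logger mean because loggers were
only attached to half of them.

Colonies in the top quartile of retention (linear-interpolation percentile,
ties included at the threshold) are classified bleaching-resistant; the
Table-1-style contrast compares trait means between the top and bottom
`floor(n/4)` colonies by retention.

## The statistical layer

All statistics are computed by the package itself and cross-checked in the
test-suite against independent oracles:

* **Spearman rank correlation** reports the S statistic (sum of squared rank
  differences) with average ranks for ties; rho uses the classical
  `1 - 6S/(n(n^2-1))` without ties and the Pearson correlation of ranks with
  them. Two-sided p-values use the t approximation with `n - 2` df; exact
  permutation enumeration is available for `n <= 9`.
* **OLS** (QR factorization) reports coefficients, R-squared and the overall
  F-test; rows with missing values are dropped listwise with counts logged.
* **One-way ANOVA** is the classical between/within decomposition; a design
  with zero within-group variance is flagged degenerate and reported at the
  limit.
* **Variance decomposition**: the within-reef component is the unweighted
  mean of per-reef sample standard deviations over reefs with at least two
  colonies; no weighting by reef size, matching how the assay reports it.
* No multiple-testing correction is applied anywhere; raw p-values are
  reported.

### The dip test

The dip statistic is the smallest sup-norm distance between the empirical
CDF and any *unimodal* CDF (convex then concave). `reefheat` implements it
from scratch with two routes that agree to numerical precision:

* For samples with distinct values (the Monte-Carlo hot path), an iterative
  modal-interval algorithm: fit the greatest convex minorant of the ECDF
  left limits and the least concave majorant of its right limits over the
  current interval; find the largest vertical gap between the two hulls at
  their knots; if it no longer exceeds the accumulated one-sided fit error,
  stop, otherwise accumulate the ECDF deviation from the convex hull left of
  the gap and from the concave hull right of it and recurse into the gap.
* For tied samples, bisection on the sup-error with an exact feasibility
  test: a compliant unimodal CDF exists iff, for some data point taken as
  the mode, a convex nondecreasing path through the ECDF band corridor left
  of it and a concave one right of it can hand over monotonically -- either
  sharing a value there, or jumping (an atom at the mode). Convex band
  feasibility reduces to "the greatest convex minorant of the upper bounds
  stays above the lower bounds"; the attainable endpoint extremes come from
  an inner bisection.

Two non-obvious facts shaped this design, and the test-suite encodes both.
First, the naive decomposition "convex prefix, concave suffix, any monotone
hand-over" is *wrong*: slope continuity across the modal region binds, and
ignoring it underestimates the dip on roughly half of uniform samples at
n > 50. Second, the dip is **not** invariant under arbitrary strictly
increasing transforms -- it depends on spacings, not just ranks (this is also
why the conventional null is specifically the uniform, the asymptotically
least-favourable unimodal distribution, rather than "any continuous null").
The invariance that does hold exactly, and is property-tested, is positive
affine. One convention: for a sample with a single unique value the
mathematical infimum is 0 (a point mass is unimodal), but the statistic is
floored at `1/(2n)`, the value every perfectly unimodal configuration
attains, keeping the classical bounds `1/(2n) <= D <= 0.25`.

P-values are Monte-Carlo: `(1 + #{D_b >= D_obs}) / (B + 1)` over `B`
uniform(0,1) null samples of the same size (default `B = 9999`; `B < 999` is
rejected as too coarse), seeded for reproducibility. The acceptance suite
calibrates the type-I error at 5% over 1,000 null samples of n = 221 with
fresh `B = 999` nulls each -- a million dip evaluations, which is why the
distinct-value route is compiled.

## The synthetic world

The generators provide data with known ground truth so every estimator in
the pipeline has a recovery test. They emulate the *statistical structure*
the analysis assumes -- not reef physics.

* **Colony population** (`simulate_colony_population()`): control load is a
  two-component Beta mixture re-parameterized by mode and concentration
  (`shape1 = 1 + m c`, `shape2 = 1 + (1-m) c`), chosen for bounded support
  on [0,1] with an exact mode at `m`. Defaults: modes 0.055 and 0.15 (the
  "5-6%" and "11-20%" load groups), equal weights, concentration 150.
  Retention is `clip(0.95 - 4 * load + N(0, 0.66), lower = 0)` -- truncated
  at zero (a colony cannot retain negative symbionts) but not capped at 1.
  Percent growth is `4.6 + 12.5 * load + N(0, 4.3)`.
* **Cytometry events** (`simulate_cytometry_sample()`): log-normal channels
  (standard for cytometry intensities, strictly positive), debris split
  first, then cells symbiont vs. coral by the true load; the realized counts
  are returned as truth.
* **Logger series** (`simulate_temperature_series()`): a sinusoid around a
  baseline plus non-overlapping warm spikes at seeded random positions.
  There is deliberately no measurement noise, so "count of samples above a
  threshold between the diurnal ceiling and the spike floor equals
  `n_spikes * spike_duration`" is an exact invariant, not a statistical one.
  Tidal harmonics are out of scope.

**Calibration.** The retention and growth noise standard deviations (0.66
and 4.3) were derived once from
`R^2 = s^2 Var(load) / (s^2 Var(load) + sigma^2)` with a small Monte-Carlo
correction for the truncation at zero, so that default populations of
n = 221 colonies reproduce the weak-coupling regime of the field data
(mean sample R^2 of about 0.087 for load-retention and 0.027 for
load-growth; dip-test rejection of unimodality in about 90% of seeds). They
were frozen before the acceptance tests were written. One knowingly
accepted discrepancy: with the modes fixed at 0.055/0.15 and equal weights,
the overall load standard deviation is about 0.053, somewhat above the
0.045 typical of field data -- matching it would require moving the modes,
which are fixed by design.

**What a green test does not establish.** Colonies are independent draws:
there is no reef-level random effect (within-reef and overall variability
coincide by construction), no spatial autocorrelation, no coupling between
reef thermal history and resistance (the reef-level exposure-vs-resistance
correlation is near-null in synthetic data), no symbiont-genus structure,
and no mortality. Tests on this world validate *estimators and plumbing*,
not ecological conclusions.

## Numerical and design choices

* Strict `>` everywhere a threshold is compared ("above 32 degC" excludes
  32.0 exactly; events at the gating threshold are non-symbiont; growth of
  exactly -10% is retained): determinism at boundaries.
* The resistance threshold uses the type-7 (linear interpolation) quantile,
  the default of mainstream statistical environments; classification is
  invariant under strictly monotone transforms of retention.
* Quartile-contrast groups use `floor(n/4)` members each, selected by sorted
  order, so top and bottom counts are balanced regardless of ties.
* Duplicate logger timestamps collapse to the first record with a warning;
  gaps are never imputed, only reflected in the coverage fraction.
* One master seed fans out to per-stage streams by hashing the stage name
  (`stage_seed()`), so any stage can be rerun independently and the whole
  pipeline is bit-reproducible; every output carries a config hash.
* The reef-level exposure regression is emitted with both raw and `log1p`
  exceedance predictors, since the appropriate scale for extreme-event
  counts is genuinely ambiguous.

## Limitations

Gating is two thresholds, not a learned gate: no compensation, doublet
discrimination or spectral unmixing. Per-reef exceedance counts assume the
logger-mean convention (isolated in `summarize_reef_thermal()` for easy
change). Growth uses the largest diameter only, not planar area. The
Monte-Carlo dip null is the uniform; for strongly skewed unimodal
alternatives the test is conservative.
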