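---
title: "Methods: tachometric estimation and resampling inference for urgent cognitive control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tachometric estimation and resampling inference for urgent cognitive control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experimental situation the package models

A participant fixates; the fixation point's disappearance is the go-signal,
and a response must be made within 1 s. The informative target appears only
after a variable gap (0–950 ms), so on long-gap trials the motor decision
must be prepared before the evidence arrives. The target demands a left or
right response; a task-irrelevant attribute (the target's location in the
spatial Stroop task, flanker direction in the flanker task) is either
congruent or incongruent with it.

The analysis variable is the raw processing time, `rpt = rt - gap`: how long
the target was actually visible before the response. Plotting proportion
correct against RPT — the *tachometric function* — reveals when, in
processing time, the target (rather than the irrelevant attribute or a
guess) starts controlling the response.

```{r}
library(urgetach)
trials <- simulate_trials(build_design(design_spec(sessions = 5L), seed = 1),
                          generator_config(), seed = 2)
fit <- tachometric(trials, trials$congruency == "incongruent",
                   condition_label = "incongruent", min_trials = 100)
summary(fit)
```

## Design construction

`design_spec()` describes the factorial: 3 fixation durations × 11 gaps × 2
target directions × 2 congruency levels = 132 combinations. Each block holds
exactly one full crossing in seeded-random order, nine blocks per session,
five sessions: 1188 trials per session, 5940 per participant. The design
convention — all combinations occurring equally often within the nine blocks
of a session — does not fix the per-block granularity; one-crossing-per-block
is the minimal scheme consistent with those counts, and
`randomize = "session"` is available for the weaker reading (equally often
per session, blocks being arbitrary cuts).

`prev_congruency`, the label that carries the sequence (conflict-adaptation)
analysis, refers to the immediately preceding trial *within the same block*;
the first trial of a block is tagged `undefined` and excluded from sequence
analyses. Blocks are separated by pauses, so not carrying the sequence
across the boundary is the conservative choice.

## The synthetic generator

The generator exists so that every downstream stage has a known ground
truth. Its accuracy law is the simplest shape consistent with the
phenomenon:

* a logistic rise from chance `c = 0.5` to asymptote `A` with midpoint
  `mu_rise` and scale `sigma_rise`, shifted right by `delta` for incongruent
  trials;
* for incongruent trials only, a subtracted Gaussian dip centred at
  `mu_dip` with width `sigma_dip`, whose depth is `D_c` after a congruent
  predecessor, `D_i` after an incongruent one (`D_c >= D_i`), and their mean
  when the predecessor is undefined;
* clipping to `[clip_eps, 1 - clip_eps]`.

Because the law is linear in the dip depth, a curve fitted to a *mixture* of
previous-congruency groups equals the law with the mixture-averaged depth —
which is what the oracle comparisons in the test suite use.

Defaults (all in ms unless stated): `A = 0.98`, `mu_rise = 300`,
`sigma_rise = 60`, `delta = 80`, `mu_dip = 250`, `sigma_dip = 50`,
`D_c = 0.25`, `D_i = 0.12`, chosen to place the dip near 250 ms and the
rightward shift near 80–120 ms, the magnitudes reported for these paradigms.
They are generator choices that produce realistic-looking curves, not
estimates fitted to any dataset.

Reaction time is a race, `rt = min(T_u, gap + T_v)`, between an urgent,
deadline-driven process `T_u ~ Normal(900, 120)` truncated at zero
(triggered by the go-signal) and a target-driven visual process
`T_v ~ Gamma(shape 9, scale 40)` (starting at target onset). This
reproduces the one property the analysis depends on — longer gaps yield
stochastically shorter RPTs, with guesses at negative and small RPTs — and
nothing more. A 2% miss rate produces no-response trials. What the
generator does **not** emulate: participant heterogeneity (every simulated
participant shares one law), RT autocorrelation and fatigue, post-error
slowing, the arousal covariates of real urgency, and any realistic RT
distribution per gap. Tests passing on synthetic data therefore validate
the estimator and its inferential calibration, not the psychology.

## Tachometric estimation

1. `compute_rpt()` sets `rpt = rt - gap`; no-response trials get missing
   RPT.
2. `filter_rpt()` keeps the closed interval [−200, 1000] ms; everything
   else, including no-response trials, counts toward the exclusion
   fraction.
3. `binned_performance()` averages correctness at each integer grid point
   (trials assigned by rounding). "1-ms bin" is read as 1-ms-wide bins on a
   1-ms grid; a `bin_width` option (odd widths, overlapping sliding bins)
   covers the wider-bin reading.
4. `local_regression()` smooths the populated bins: for each of the 1201
   grid points, the `ceiling(span * N)` nearest populated bins are weighted
   by a tricube kernel of scaled distance *times the bin's trial count*,
   and a quadratic is fitted by weighted least squares. Count weighting
   makes the smoother consistent with trial-level averaging; degree 2 and
   tricube match the documented defaults of R's `loess`, which this
   implementation follows (an option allows degree 1). Span 0.2 is the
   analysis default.
5. The smooth is evaluated on the full grid and clipped to [0, 1].

Numerical choices: the local systems are solved on distance-rescaled
predictors (condition numbers stay near 1); a window whose quadratic system
is singular (e.g. all points at one x) falls back to a lower degree, down to
the weighted mean; a span giving fewer than three points per window is an
error suggesting a larger span. Ties at the window boundary are immaterial
because the tricube weight vanishes at the maximal distance.

`min_drop()` reports the minimum of the smooth and its RPT. The search
window defaults to the central 95% quantile range of the observed RPTs:
outside it the local regression is extrapolating from few bins and its
excursions are artifacts. The window is configurable; the pipeline records
it in the report.

`shift_estimate()` operationalizes the "rightward shift" as the median over
performance levels {0.6, 0.7, 0.8, 0.9} of the horizontal distance between
the *last upward crossings* of each level by the two smoothed curves
(linear interpolation between grid points). Last crossings put the measure
on the post-dip rising limb; the median makes it robust to a level grazed
by noise; levels never crossed by one curve are skipped. Shift magnitudes
for these paradigms are conventionally quoted without a defining procedure,
so this is the package's own definition; it is validated against exact
translations and against dense evaluation of the generator law.

## Resampling inference

Effects are differences of curve minima: incongruent − congruent
(`congruency_effect()`), and among incongruent trials
previous-congruent − previous-incongruent (`sequence_effect()`). Inference
is by relabeling: `permutation_test()` shuffles the label column within
each participant (preserving per-participant label counts, since the pooled
"aggregate participant" still has participant structure), recomputes the
effect, and reports the add-one two-sided p-value
`(1 + #{|null| >= |obs|}) / (B + 1)`, which cannot be zero and is the
standard Monte-Carlo convention. For the sequence test only the incongruent
trials' `prev_congruency` labels are shuffled. The study-scale permutation
count is 2000; the pipeline default is 500, which resolves p down to
1/501 ≈ 0.002.

`bootstrap_se()` resamples trials with replacement, stratified by condition
label so each condition keeps its size, and reports the standard deviation
of the replicate statistics. The resampling unit (trials) and replicate
count (1000 study-scale, 200 pipeline default) are package choices, since
"bootstrap standard errors" alone pins down neither.

## Problem sizes in the test suite

The suite validates: exact design counts; bit-exact CSV round trips;
the smoother against a brute-force weighted-least-squares oracle (25-point
fixtures, 1e−8) and loosely against `loess`; dip location and shift against
dense evaluation of the generator law (±5 ms; exact translations); dip
recovery at ~20,000 incongruent trials (±30 ms, depth ±0.05);
type-I calibration of the permutation test on 200 null-generator datasets
of ~5,000 trials at 500 permutations (rejection rate 0.05 ± 0.03, p-value
uniformity by Kolmogorov–Smirnov distance < 0.1); and power at the default
dip size on ~23,760-trial datasets with 1999 permutations. These sizes were
picked so the full suite is a routine desk run while each check retains
statistical resolution; the qualitative monotonicity check of the congruent
curve evaluates its supremum-deviation statistic as a median over five
replicate datasets because a single draw of a supremum over 601 correlated
grid points fluctuates on the same scale as the tolerance.

## Known limitations

* The pooled-aggregate analysis ignores participant heterogeneity by
  design; no hierarchical pooling or per-participant curves are provided.
* The smoother's variance grows near the RPT range edges; statistics are
  therefore windowed, and values of the smooth outside the central quantile
  window should be read as extrapolation.
* The generator's RT race is a stand-in; its parameters must not be
  interpreted as estimates of any experiment's timing.
* Permutation inference assumes exchangeability of labels within
  participant under the null; designs with strong label–sequence
  confounds would need a design-aware relabeling scheme.
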