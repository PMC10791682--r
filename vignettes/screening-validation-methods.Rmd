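---
title: "Validating a composite well-being screen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a composite well-being screen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbiscreen)
```

## The problem

A 9-item composite well-being index (WBI) is used to screen health
professionals for distress. Seven dichotomous items each flag a distress
domain (burnout, depression, stress, fatigue, mental and physical quality of
life); two favorably worded Likert items capture meaning in work and
satisfaction with work–life integration. The composite is

$$\mathrm{WBI} = \sum_{j=1}^{7} \mathbf{1}[\text{item}_j = \text{yes}]
  + d(\text{meaning}) + d(\text{work–life}),$$

where $d$ maps agree/strongly agree $\to -1$, neutral $\to 0$,
disagree/strongly disagree $\to +1$, so the score is an integer in
$[-2, 9]$ with higher values indicating more distress. The commercial
instrument's own item-scoring table is distributed with the licensed survey;
the additive rule above is the published expanded-index variant, the unique
simple additive scheme consistent with the instrument's stated range and
direction, and `score_wbi()` exposes the Likert contribution map as a
configurable table so a different rule can be dropped in.

Validation asks how well each score level separates respondents with and
without a set of reference-standard outcomes, and what a given score implies
for an individual's outcome probability.

## Reference-standard outcomes

Seven binary outcomes are derived per respondent
(`classify_outcomes()`):

* **Low / high overall QOL** and **extreme fatigue** use the half-SD rule on
  0–10 single-item linear-analogue scales: a clinically meaningful
  difference is half a standard deviation from the gender-matched mean.
  Low status is *at or below* `mean − 0.5·SD` (inclusive), high status
  *strictly above* `mean + 0.5·SD`; the two can therefore never hold
  simultaneously. The fatigue scale's high end is favorable, so extreme
  fatigue uses its low cutoff. Means and SDs (sample SD, $n-1$) are computed
  per gender by default; respondents with missing gender are evaluated
  against whole-cohort moments, and an `"overall"` mode applies the
  whole-cohort moments to everyone. A subgroup with zero SD is flagged
  degenerate and classifies nobody.
* **Burnout** is a symptom frequency of weekly or more often on either of
  two single-item burnout-domain measures (emotional exhaustion,
  depersonalization) — the top three levels of the standard 7-level
  frequency scale.
* **Suicidal ideation** and **recent major error** are item pass-throughs.
* **Intent to leave** is positive from "moderate" upward. The response
  scale's published option list is ordered oddly in places; this package
  fixes the ordinal order as none < slight < moderate < likely < definite,
  which is the only order under which "moderately or greater" is a
  contiguous upper set.

Two published pretest-probability presets ship alongside the empirical
prevalences (`pretest_presets()`): the stratification-table footnote values
and the slightly different narrative-text values (they disagree for high QOL,
fatigue, error and intent to leave — e.g. 45.1% vs 46.1% for high QOL, 33.2%
vs 40.0% for fatigue — and the source gives no reconciliation, so both are
shipped verbatim and the footnote preset is the reproduction default).

## Stratum-specific statistics

For each score level $s$ (scores $\ge 7$ pooled into an open top stratum by
the display convention; the AUC always uses unbinned scores):

* **Exact-score likelihood ratio**
  $LR_s = \Pr(S = s \mid D^+)/\Pr(S = s \mid D^-)$, the multi-level
  stratum-specific LR — distinct from the threshold
  $LR^+ = \mathrm{sens}/(1-\mathrm{spec})$. Its 95% interval is the Katz
  log-method interval for a ratio of two binomial proportions. A zero
  numerator or denominator is continuity-adjusted by half an event and
  flagged. Note the identity $\sum_s LR_s \Pr(S=s \mid D^-) = 1$: the LRs
  of a table average to 1 over the negative-class score distribution, which
  the property tests exploit, and which implies no table can have all
  strata above (or all below) 1.
* **Stratum odds ratio**, contrasting one score level against all others:
  $OR = ad/bc$ with the Woolf log-method interval and the Haldane–Anscombe
  $+0.5$ correction when a cell is zero. For a stratum that is rare in both
  classes, $OR \to LR$.
* **Posttest probability** by the Bayes odds update
  $p' = \mathrm{odds} \cdot LR / (1 + \mathrm{odds} \cdot LR)$.
* **Sensitivity/specificity** at each threshold $t$ (test-positive means
  score $\ge t$), with the Katz interval on $LR^+$.
* **Empirical AUC**: the probability a random case outscores a random
  control with ties counting one half (the normalized Mann–Whitney
  statistic), computed in closed form from the stratum counts. For the
  favorable high-QOL outcome the score is reversed so an informative test
  has AUC above 0.5.
* **Risk threshold** (`select_threshold()`): the smallest score from which
  every stratum at or above it has $LR > 1$, optionally across several
  outcomes at once.

The interval methods deserve a note: the source report's printed OR
intervals match Woolf exactly, which fixes that choice, but its LR intervals
match neither the Katz nor the Simel log method computed from the printed
counts, and the generating method is not identifiable from the text. Katz is
the standard default for a ratio of proportions and is used here; LR point
estimates reproduce the published values exactly while LR interval bounds
are expected to differ.

Sparse strata are pooled by `combine_sparse_strata()`: each maximal run of
two or more *adjacent* strata with fewer than `min_events` (default 5)
outcome-positive respondents is merged into one range-labelled stratum.
An isolated sparse stratum between well-populated neighbours is left alone —
merging it into a dense neighbour would dilute the neighbour's estimate —
which mirrors how the reference analysis pooled only its contiguous sparse
low-score run for the rare suicidal-ideation outcome while leaving isolated
thin strata elsewhere untouched. `run_pipeline()` applies this pooling
policy uniformly to every outcome; the fixture-reproduction path
(`reproduce_tables()`) works on the unpooled embedded counts.

## Contingency and group-difference tests

The bivariate layer is implemented from first principles at desk scale, with
the base-R equivalents used as independent cross-checks in the test suite:

* **Fisher exact** (2×2): two-sided by the probability-mass rule — sum the
  hypergeometric probabilities of all tables, margins fixed, whose point
  probability does not exceed the observed one (relative tolerance
  $10^{-12}$ on the comparison).
* **Pearson chi-square** without continuity correction, df = 1. The
  conventional dispatch applies: Fisher when any expected cell is below 5
  (strictly below — an expected count of exactly 5 stays with chi-square).
* **Wilcoxon rank-sum**: exact enumeration of rank assignments for
  $n_1+n_2 \le 12$ without ties (two-sided p = twice the smaller tail,
  capped at 1); otherwise midranks with tie-corrected variance and a 0.5
  continuity correction.
* **Kruskal–Wallis** with the standard tie correction; with two groups the
  statistic equals the squared uncorrected normal deviate of the rank-sum
  test.
* **Welch t** with Satterthwaite df (chosen over the pooled-variance test
  as the safer default for unequal spreads). Degenerate inputs (zero
  variance everywhere) return p = 1 for equal means and a warned p = 0
  otherwise.

The source analysis does not say which of these produced each narrative
p-value, so printed p-values are only reproduced as "< 0.001" bounds; the
per-stratum p-values in the published odds-ratio table mix methods in a way
that cannot be traced row by row, and are therefore recomputed with the
dispatch rule above rather than asserted against print.

## The synthetic cohort generator

No respondent-level data were deposited with the source study, so the
package ships a latent-trait generator (`generate_cohort()`) that emulates
the cohort's statistical structure: a single standard-normal distress factor
$z$ drives every indicator. Dichotomous items are Bernoulli with
$\mathrm{logit}^{-1}(a_j + b_j z)$; ordinal items (Likert, symptom
frequency, intent to leave) follow proportional-odds models on $z$; the QOL
and fatigue scales are $\mathrm{clamp}(\mathrm{round}(\mathrm{base} +
\mathrm{slope}\cdot z + \varepsilon), 0, 10)$; demographics are drawn
independently of $z$ (no gender–distress association is encoded, since none
is reported). The single-factor form is the minimal model consistent with
the monotone stratified LR tables being emulated; no claim is made that it
matches the true joint distribution of the unavailable data.

Parameters are specified as *marginal prevalence targets* plus loadings;
intercepts and cutpoints are derived by integrating the logistic link over
the latent normal (`cohort_params()`), so setting a loading to zero — the
null generator, `null_cohort_params()` — changes the dependence structure
without moving any marginal. The shipped calibration targets the published
marginals: mean composite 2.3, low QOL 27.3%, high QOL ≈45%, extreme
fatigue ≈33%, burnout 44.1% (EE 37.5%, DP 26.5%), suicidal ideation 6.2%,
recent error ≈20.5%, moderate-plus intent to leave 23.5%; at n = 20,000 the
realized values sit within about one percentage point of these and the
low-QOL AUC lands near 0.80, close to the published 0.79.

Two deliberate departures from the emulated survey's surface statistics are
worth knowing:

* The half-SD outcome definitions interact with a *discrete* 0–10 scale: a
  symmetric integer distribution with the published mean 7.1 and SD 1.6
  yields roughly 35% low / 40% high QOL, not the published 27.3% / 45–46%.
  Reproducing the published prevalence pattern requires a left-skewed scale
  concentrated at 8–10, which the calibration adopts (realized QOL mean
  ≈8.3, SD ≈1.3). The generator therefore matches the outcome prevalences,
  not the scale moments; both cannot hold at once for any integer-valued
  distribution under the inclusive/exclusive cutoff semantics used here.
* Random numbers are consumed vectorized field-by-field in the
  respondent-record field order (latent trait, gender, demographics, items,
  scales, outcomes), not respondent-by-respondent. This is the natural R
  idiom, gives the identical joint distribution, and remains fully
  reproducible from the seed; seeds are not portable to a
  respondent-by-respondent implementation.

What passing the synthetic checks does and does not show: the generator
shares the analysis pipeline's own structural assumption (one monotone
distress continuum), so recovery tests validate the *computations* —
calibration of marginals, null behaviour of LRs and AUC, monotone
stratification, direction of parameter effects — not the instrument itself,
and say nothing about real survey phenomena such as response styles,
differential item functioning, or informative non-response.

## Numerical and testing choices

* **Rounding**: all printed-table comparisons use round-half-up at the
  displayed precision (`round_half_up()`), with a $10^{-8}$ guard for
  binary representation; base R's half-to-even `round()` is never used for
  display.
* **Problem sizes**: property tests run on a few hundred random small
  tables (N ≤ 40–60) against brute-force enumeration oracles; generator
  recovery tests use single cohorts of n = 20,000, sizes at which the whole
  suite completes in well under a minute on one core.
* **Null-recovery pooling**: checking "all per-score LRs ≈ 1" under the
  null generator needs strata large enough that the LR's sampling error is
  small against the ±0.15 acceptance band. At n = 20,000 a tail score level
  holds only tens of events (LR sampling SD 0.2–0.4), so a true null would
  fail the band regularly; the check therefore pools to at least 2.5% of
  the cohort per stratum (≈500 events, LR SD ≈ 0.05, making the band a
  ≈3σ check). The band itself is untouched.
* **Degenerate inputs** are first-class: zero-SD threshold groups warn and
  classify nobody; all-positive or all-negative outcomes make stratum
  statistics undefined and raise a typed error; zero cells trigger flagged
  continuity corrections; a threshold one past the top score is allowed
  (sensitivity 0, specificity 1).

## Known limitations

* The instrument's licensed item-level scoring table is not distributed
  here; the implemented additive rule is the published expanded variant and
  is configurable, but per-item normative feedback is out of scope.
* LR confidence intervals use Katz and will not match the source report's
  printed LR intervals (method unidentifiable there).
* No smoothed/parametric ROC, no DeLong AUC variance, no multivariable
  modelling, and no multiple-testing adjustment — none are part of the
  emulated analysis.
* The analysis is cross-sectional throughout; nothing here supports causal
  interpretation.
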