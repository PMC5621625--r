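---
title: "Modelling conflict exposure and child undernutrition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling conflict exposure and child undernutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the tunable parameters and
their defaults, what the synthetic-data generator emulates, the
numerical choices, and the places where the design was genuinely open
and a decision had to be made. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. From conflict events to exposure

A conflict event stream (ACLED-style: dated, geocoded, one of nine
event-type labels) is reduced to per-(cluster, survey date) exposure
indicators in three steps.

**Classification.** The nine event types collapse to four analysis
classes: the three battle subtypes → `battle`; `remote violence` and
`violence against civilians` → their own classes; the remaining four
types (headquarters/base established, strategic development, riots or
protests, non-violent transfer of territory) → `other`. The authoritative
nine-to-four table used in the original analysis is not public; this
partition is the only one consistent with the four class names, and it is
overridable per run (`classify_event_type(x, class_map = ...)`).

**Windowing.** "Within 3 months" and "3–12 months before the survey"
are operationalised as day counts with half-open intervals: an event
`delta = survey_date − event_date` days old is *recent* exposure if
`delta ∈ [0, 91)` and *longer-term* if `delta ∈ [91, 366)`.
Calendar-month arithmetic is ambiguous (months differ in length and the
boundary month would be split); day counts are exact, reproducible, and
make the boundary cases testable (`delta = 91` is longer-term, a future
event is nothing). The boundaries are configurable (`windows =`).

**Linkage.** An event is linked to a cluster if both carry the same
district (default), or, optionally, if the cluster centroid lies within
`r` km of the event (`linkage = "buffer"`). District linkage is the
default because administrative geography is the most reliably recorded
field on both sides; the buffer is offered for sensitivity analysis.
Exposure enters the model as a binary any-event indicator per window —
consistent with a single reported odds ratio per window — with event
counts and per-class indicators carried alongside for descriptive use.

## 2. Anthropometry

Growth z-scores use the LMS transform
`z = ((x/M)^L − 1)/(L·S)`, with the `log(x/M)/S` limit at `L = 0`;
below `|L| = 1e-5` the implementation switches to the log branch, which
keeps the transform continuous (the two expressions agree to
`O(L·z²·S)` there). An optional restricted tail adjustment rescales
`|z| > 3` linearly using the reference's ±2/±3 SD gap, as is standard
with growth references. Wasting/stunting are *strictly* below the −2
cutoff (a z-score of exactly −2.00 is not a case).

The package ships a **synthetic** LMS reference
(`inst/extdata/lms_synthetic.csv`): plausible monotone curves, clearly
not the WHO 2006 standard, so that every test runs offline. Real
analyses should supply the WHO tables in the same CSV schema
(indicator, sex, key, L, M, S); interpolation between reference keys is
linear in the key.

## 3. The hierarchical spatio-temporal model

For child *i* in cluster *c(i)*, district *dist(i)*, survey round
*t(i)*:

    y_i ~ Bernoulli(p_i)
    logit p_i = x_i'β + u_c(i) + v_c(i) + w_t(i) + d_dist(i)

* `u` — intrinsic CAR (ICAR) on the cluster adjacency graph: each
  cluster's effect is conditionally Gaussian around the mean of its
  neighbours with precision `τ_u · n_neighbours`. The prior is improper
  (rank deficiency = number of graph components) and is identified by a
  sum-to-zero constraint per component, enforced by re-centring after
  every update.
* `v` — iid Gaussian cluster effects. `u + v` is the
  Besag–York–Mollié convolution: structured plus unstructured
  heterogeneity.
* `d` — iid Gaussian district effects.
* `w` — first-order random walk over survey rounds, sum-to-zero. The
  temporal structure was described only as "structured (spatial and
  temporal)"; RW1 over rounds is the minimal structured choice and is
  the one implemented.
* Priors: `β ~ N(0, 1e4)` elementwise (precision `1e-4`, weakly
  informative; configurable); all precisions `τ ~ Gamma(1, 5e-4)`, a
  common latent-Gaussian-model default, chosen because the original
  hyperpriors are in an unavailable supplement. Both are `prior_spec()`
  arguments.

**Design matrix.** Reference levels: agro-pastoral (livelihood), Deyr
(season), under-12-months (age). Continuous covariates are standardised
(mean 0, sd 1) and the transform is recorded so `summarize_effects()`
can back-report per-unit odds ratios; whether the original analysis
standardised is not stated, so a `standardize = FALSE` switch exists.
Variant A omits all conflict columns; variant B adds the two exposure
indicators and the interaction set (conflict × food access, conflict ×
EVI, conflict × rainfall, food × environment, EVI × temperature), each
interaction the elementwise product of mean-centred parents. December
belongs to two quoted season ranges; it resolves to Jilal by default
(configurable), matching "harsh dry season December–March".

**Inference.** The original analysis used a nested Laplace
approximation; the target of this package is the posterior itself, so it
is fitted by an exact MCMC scheme instead: Pólya-Gamma data
augmentation, under which every conditional is conjugate — Gaussian for
`β` and each random-effect block, Gamma for each precision. The PG(1,z)
sampler is the exact alternating-series rejection method, implemented in
C++ on R's RNG stream so that `set.seed()` governs every draw. Defaults
(`mcmc_control()`): 4 chains × 5000 iterations, 2000 burn-in, thinning
2; the tests run much shorter chains and say so. Convergence is
summarised by split-R̂ and a crude initial-sequence effective sample
size per fixed effect; they are reported with the fit and never
silently truncated.

**Collinearity.** Before fitting, `screen_collinearity()` computes all
pairwise Pearson correlations; pairs with `|r| ≥ 0.6` (the conventional
threshold below which all predictors are retained) are flagged with a
warning but do not abort — mirroring the screening step of the original
analysis.

## 4. Sequential attributable fractions

For a removed-factor subset `S`, expected cases are
`E_S = Σ_i p̂_i(S)` where `p̂_i(S)` is the posterior-mean probability
with the columns of every factor in `S` (and every interaction column
containing them) set to the reference state. The attributable fraction
is `AF(S) = (O − E_S)/O` with `O` the observed case count. Sequential
AFs are the increments of `AF` along an ordering; averaging over all
orderings of the chosen factors (3 factors → 6 orderings) yields the
Shapley value per factor, whose sum equals the combined AF of removing
everything — an identity the tests assert to 1e-10.

Three design points were genuinely open:

* **Counterfactual for a continuous factor.** Binary exposures are set
  to 0 (unexposed). For vegetation cover, whose *low* values are the
  hazard (drought), "removal" sets EVI to its sample 90th percentile — a
  protective reference — configurable via `evi_quantile`. No text
  defines this counterfactual; the choice is explicit and switchable.
* **Baseline.** Inside `sequential_af()` all subset AFs are measured
  against the no-removal baseline `AF(∅)`. For a calibrated model
  `E_∅ = O` and the baseline is exactly zero, recovering the plain
  formula; under plug-in Monte-Carlo miscalibration the baseline keeps
  two properties simultaneously that would otherwise conflict: a factor
  with zero coefficient gets AF exactly 0, and Shapley efficiency holds
  exactly.
* **Explained-variation scaling.** The source description — multiply
  each predicted probability by the proportion of explained variation —
  taken literally destroys calibration (`E_∅ ≠ O` even for a perfect
  model). The default is no scaling; `scaling = "blend"` implements the
  calibrated reading `p̂ ← ȳ + R²(p̂ − ȳ)` with `R²` the latent-scale
  variance-partition coefficient, and `scaling = "literal"` the literal
  multiply, for comparability.

## 5. WAIC

`waic()` computes `lppd = Σ_i log mean_s exp(ll_si)` with a
per-observation max shift for numerical safety, and
`p_waic = Σ_i var_s(ll_si)`. The variance is the unbiased (n−1) sample
variance by default — the common implementation of the cited
formulation — with a `"population"` option dividing by n; the
distinction matters because exact draw-duplication invariance holds only
under the population convention, and the tests assert that invariance
under that convention explicitly. Degenerate fitted probabilities are
clamped at 1e-12 with a logged count. The WAIC magnitudes printed in the
source analysis (~hundreds for ~74k observations) are not on the
standard per-observation deviance scale and are not reproduced; the
package reports standard WAIC and compares variants by its difference.

## 6. The synthetic world

The generator draws from exactly the model of §3, so parameter-recovery
tests are well-posed. What it emulates, and its fixed defaults:

* **Geography** — districts on a grid, jittered clusters,
  k-nearest-neighbour symmetric adjacency (k = 4); environmental fields
  are low-rank random cosine expansions (spatially smooth, verified by a
  Moran's-I-vs-permutation test) with seasonal offsets: rain peaking in
  the Gu and Deyr rains, EVI following rain, temperature peaking in the
  dry seasons.
* **Conflict** — district-month counts Poisson with rate
  `base × district multiplier × season multiplier`; base 0.5
  events/district-month (the scale of the observed national stream:
  1395 events / 74 districts / 48 months ≈ 0.4); season multipliers
  (Jilal 1.3, Gu 0.7, Hagaa 1.1, Deyr 0.9) reflecting more recorded
  events in dry seasons; class mixture 0.54/0.08/0.28/0.10, the
  observed class shares. District multipliers are Gamma(0.35, 0.35):
  observed event tables are extremely concentrated (one region held 594
  of 1395 events), and without this overdispersion every district would
  see an event in any 9-month window, making longer-term exposure a
  constant — a degenerate world in which no exposure effect is
  estimable.
* **Children** — allocated to clusters with equal probabilities
  (multinomial; the real surveys' sampling weights are unpublished),
  rounds uniform. Covariate marginals are fixed plausible defaults
  (illness flags Bernoulli(0.15), vaccination 0.6–0.7, household size
  4 + Poisson(2), maternal MUAC N(25, 2) cm, food-access flags 0.4–0.8):
  any reasonable marginals suffice for recovery testing, which is their
  only job.
* **Truth** — fixed-effect defaults are the published adjusted odds
  ratios of the conflict-adjusted model (recent 1.37/1.21, longer-term
  1.76/1.88 for wasting/stunting, etc.); the intercept is the logit of
  the national prevalence (21% wasting, 31% stunting). Interaction
  coefficients default to zero: the published interaction ORs are on a
  raw measurement scale the standardised generator does not reproduce,
  and most are not distinguishable from 1. Random-effect precisions
  default to `τ_u = 4`, `τ_v = τ_d = 16`, `τ_w = 100` — modest
  cluster-level heterogeneity of the size cluster surveys typically
  show. Setting any precision to `Inf` switches that block off exactly,
  reducing the generator to plain logistic simulation (asserted in the
  tests).
* **Anthropometry** — z-scores are drawn from truncated normals
  consistent with the simulated binary outcome, then inverted through
  the synthetic LMS reference into raw weight/height, so the
  z-score–classification–LMS pathway round-trips.

**What a green test does not establish.** The synthetic world has no
survey stratification weights, no displacement of populations (IDP
status is a fixed cluster attribute, not a response to conflict), no
measurement error in anthropometry or event geocoding, no missing data,
and conflict that is exogenous by construction — outcomes never feed
back into event rates. Recovery of the generating odds ratios here
validates the estimation machinery, not the causal interpretation of
any real-data estimate.

## 7. Numerical and degenerate-input choices

* ICAR updates add 1e-8 jitter to the conditional precision diagonal
  before Cholesky (guards empty clusters); sum-to-zero re-centring per
  component after every draw; `τ_u`'s Gamma shape uses the ICAR rank
  `K − #components`.
* PG draws, all Gaussian draws and all Gamma draws come from R's RNG:
  byte-identical artefacts under equal config and seed (asserted).
* Exposure of a record depends only on events strictly before its
  survey date; shifting all dates by a common offset leaves the
  exposure matrix unchanged (asserted).
* Quarantine, not abort: invalid survey/event rows are set aside with
  row numbers and reasons; accepted + quarantined always partitions the
  input. Missing mandatory columns and empty files are hard errors.
* Empty groups in descriptive tables report blank percentages, not 0.
* More than 6 attribution factors is refused (factorial growth).
* A single-node graph is rejected (ICAR undefined); single-draw WAIC
  warns and sets `p_waic = 0`.

## 8. Known limitations

* The Gibbs sampler is exact but serial; at the published data scale
  (~74k children, ~1000 clusters) a fit is hours, not minutes. The
  acceptance suite therefore runs at reduced scale and says so.
* Split-R̂ at short test-scale chains routinely exceeds 1.05; the
  acceptance tests report the excess rather than hide it, and the
  full-scale defaults are the configuration intended to meet it.
* The exposure–outcome linkage for displaced children uses their survey
  location, as in the source data; origin-tracking is out of scope.
* WAIC comparisons at small n can prefer the no-conflict model because
  the conflict variant carries 13 extra interaction columns
  (≈ +13 p_waic); the advantage of the conflict model is a
  large-sample property, which is why the model-comparison acceptance
  test runs at n = 10 000.
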