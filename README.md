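# conflictnutr

Armed conflict and child undernutrition: Bayesian spatio-temporal
modelling and attributable fractions for cluster-survey data.

## The problem

In protracted crises such as Somalia's, childhood wasting
(weight-for-height z-score < −2) and stunting (height-for-age z-score
< −2) are driven by a tangle of individual, household, environmental and
conflict-related factors. Quantifying the *independent* effect of armed
conflict requires linking geocoded conflict events to survey clusters in
time windows before each survey, and adjusting for everything else in a
model that respects the spatial and temporal structure of cluster
surveys. This package implements that analysis end to end for analysts
working with FSNAU-style nutrition surveys and ACLED-style event data:

1. **Exposure construction** — events are classified into four classes
   (battle, remote violence, violence against civilians, other) and
   windowed per survey date: *recent* exposure for events 0–90 days
   before the survey, *longer-term* for 91–365 days; linkage to clusters
   is by shared district (default) or a distance buffer.
2. **Anthropometry** — LMS growth z-scores
   (`z = ((x/M)^L − 1)/(L·S)`, `log(x/M)/S` at `L = 0`), undernutrition
   classification, and descriptive prevalence tables.
3. **Model** — a Bayesian hierarchical logistic regression

   `logit p_i = x_i'β + u_c(i) + v_c(i) + w_t(i) + d_dist(i)`

   with a Besag–York–Mollié convolution prior at cluster level
   (intrinsic CAR `u` on the cluster adjacency graph plus iid `v`),
   first-order random-walk survey-round effects `w`, iid district
   effects `d`, Gaussian priors on `β` and Gamma hyperpriors on all
   precisions. Fitting is by exact Pólya-Gamma augmented Gibbs sampling
   (conjugate updates throughout; the PG(1,z) sampler is implemented in
   C++). Effects are reported as posterior-median odds ratios with 95%
   equal-tailed credible intervals.
4. **Attribution** — permutation-averaged sequential attributable
   fractions: `AF(S) = (O − E_S)/O` for each removed risk-factor subset,
   sequential increments along every ordering of the chosen factors
   (recent conflict, longer-term conflict, vegetation cover), averaged
   across orderings (the Shapley value). Averaged AFs sum exactly to the
   combined AF of removing all factors.
5. **Assessment** — WAIC (`−2(lppd − p_waic)` from pointwise posterior
   log-likelihoods) comparing the model with and without conflict, and
   observed-versus-fitted cluster prevalence calibration.
6. **Synthetic data** — a first-class generator drawing geography with
   adjacency, seasonally varying overdispersed conflict streams,
   spatially smooth environmental fields and outcomes from the model
   above with known parameters, so the whole pipeline is testable
   offline with parameter-recovery guarantees.

## Worked example

```r
library(conflictnutr)

# a synthetic study: 10 districts x 6 clusters, 4 survey rounds
gg  <- generate_geography(10, 6, seed = 1)
tp  <- truth_params("wasting")          # recent OR 1.37, longer OR 1.76
ev  <- simulate_conflict_events(gg$geography, tp, "2008-01-01", "2009-12-31", 101)
sim <- simulate_survey(gg$geography, gg$adjacency, ev, tp, 3000,
                       as.Date(c("2009-01-15","2009-05-15",
                                 "2009-08-15","2009-11-15")), 201)

d   <- build_design(sim$data, sim$exposure, gg$geography,
                    variant = "B", outcome = "wasted")
fit <- fit_model(d, gg$adjacency,
                 mcmc = mcmc_control(chains = 1, iter = 800, burnin = 300,
                                     thin = 2), seed = 301)
s   <- summarize_effects(fit)
s[s$term %in% c("conflict_recent", "conflict_longer"), c("term","or","lo","hi")]
#>             term       or       lo       hi
#>  conflict_recent 1.722123 1.042004 2.585851
#>  conflict_longer 2.824192 1.809049 4.737089
```

The generating odds ratios are 1.37 (recent) and 1.76 (longer-term). At
this scale conflict exposure varies across only ~40 district-round
units, so single-seed estimates are noisy: here the recent-conflict
interval covers its truth while the longer-term interval just misses
(lower bound 1.81 vs 1.76). Across repeated seeds the 95% intervals
cover the truth at close to nominal rate — that, not any single seed, is
what the acceptance suite measures. Attribution:

```r
af <- sequential_af(fit, d)  # 3 factors -> 6 orderings
round(af$averaged, 4)        # per-factor Shapley-averaged AFs
#> recent longer    evi
#> 0.0599 0.2797 0.4260
sum(af$averaged) - af$combined[["evi+longer+recent"]]  # 0 (exact efficiency)
```

A full pipeline run (simulate → exposure → fit → af → waic → report),
writing CSV/JSON artefacts to `artifacts/`:

```r
run_pipeline(read_run_config(NULL, list(seed = 1)))
```

or from the shell via the launcher:

```sh
Rscript inst/cli/conflictnutr.R run-all --seed 1 --out artifacts
```

## Layout

- `R/` — exposure (`build_exposure_matrix`), anthropometry
  (`lms_zscore`), design (`build_design`), sampler (`fit_model`),
  attribution (`sequential_af`), assessment (`waic`), synthetic data
  (`simulate_survey`), IO and pipeline.
- `src/rpg.cpp` — exact Pólya-Gamma PG(1,z) sampler.
- `inst/extdata/` — synthetic LMS reference (not the WHO standard) and
  the re-entered published regional summary tables.
- `vignettes/conflict-undernutrition.Rmd` — model, assumptions, design
  decisions, and what the synthetic world does and does not establish.
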