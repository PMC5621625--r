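# Shared fixtures, built in code.  make_world() gives a small synthetic
# study; cached_fit() memoises one moderate fitted model for the tests
# that only need *a* posterior (attribution, assessment).

make_world <- function(seed = 7, n_districts = 3, clusters_per_district = 4,
                       n_children = 500,
                       truth = list(wasting = truth_params("wasting")),
                       events = NULL) {
  gg <- generate_geography(n_districts, clusters_per_district, seed = seed)
  tp <- truth[[1]]
  if (is.null(events))
    events <- simulate_conflict_events(gg$geography, tp,
                                       "2008-01-01", "2009-12-31",
                                       seed = seed + 1)
  dates <- as.Date(c("2009-01-15", "2009-05-15", "2009-08-15", "2009-11-15"))
  sim <- simulate_survey(gg$geography, gg$adjacency, events, truth,
                         n_children, dates, seed = seed + 2)
  list(geography = gg$geography, adjacency = gg$adjacency,
       events = events, sim = sim, dates = dates)
}

# overwrite exposure indicators with a deterministic alternating pattern
# so conflict columns are guaranteed non-constant in tiny worlds
force_exposure_variation <- function(exposure) {
  n <- nrow(exposure)
  exposure$recent_any <- as.integer(seq_len(n) %% 2 == 0)
  exposure$longer_any <- as.integer(seq_len(n) %% 3 == 0)
  exposure$recent_n <- exposure$recent_any
  exposure$longer_n <- exposure$longer_any
  exposure
}

.fit_cache <- new.env(parent = emptyenv())

# one shared moderate fit of the conflict model (variant B, wasting)
cached_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    w <- make_world(seed = 31, n_districts = 4, clusters_per_district = 5,
                    n_children = 900)
    design <- build_design(w$sim$data, w$sim$exposure, w$geography,
                           variant = "B", outcome = "wasted")
    post <- fit_model(design, w$adjacency,
                      mcmc = mcmc_control(chains = 2, iter = 500,
                                          burnin = 200, thin = 2),
                      seed = 99)
    .fit_cache$fit <- list(world = w, design = design, posterior = post)
  }
  .fit_cache$fit
}

# minimal hand-made posterior: fixed coefficient draws, no random effects;
# lets attribution tests work with exactly known probabilities
plugin_posterior <- function(design, beta, n_draws = 4) {
  p <- ncol(design$X)
  stopifnot(length(beta) == p)
  K <- length(design$cluster_ids); D <- length(design$district_ids)
  T <- length(design$round_dates)
  structure(list(
    beta = matrix(rep(beta, each = n_draws), n_draws, p,
                  dimnames = list(NULL, colnames(design$X))),
    u = matrix(0, n_draws, K), v = matrix(0, n_draws, K),
    d = matrix(0, n_draws, D), w = matrix(0, n_draws, T),
    tau = matrix(NA_real_, n_draws, 4), chain = rep(1L, n_draws),
    design_cols = colnames(design$X), meta = design$meta,
    cluster_ids = design$cluster_ids, district_ids = design$district_ids,
    round_dates = design$round_dates, variant = design$variant,
    outcome = design$outcome, n_obs = nrow(design$X)),
    class = "cn_posterior")
}

region_summary_path <- function() {
  system.file("extdata", "somalia_region_summary.csv", package = "conflictnutr")
}

region_conflict_path <- function() {
  system.file("extdata", "somalia_region_conflict.csv", package = "conflictnutr")
}
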