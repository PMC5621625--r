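# The generator: geography/adjacency invariants, spatial smoothness,
# conflict stream distribution, and the outcome model's identities.

test_that("generate_geography satisfies its structural invariants", {
  gg <- generate_geography(2, 3, seed = 7)
  geo <- gg$geography; adj <- gg$adjacency
  expect_equal(nrow(geo), 6)
  expect_equal(length(unique(geo$cluster_id)), 6)
  expect_equal(as.vector(table(geo$district_id)), c(3, 3))
  # symmetric neighbour lists, no self loops
  for (i in seq_along(adj$nbs)) {
    expect_false(i %in% adj$nbs[[i]])
    for (j in adj$nbs[[i]]) expect_true(i %in% adj$nbs[[j]])
  }
  # seasonal covariate tables complete
  for (s in season_levels())
    for (v in c("rainfall", "evi", "temperature"))
      expect_true(all(is.finite(geo[[paste0(v, "_", s)]])))
  # determinism
  gg2 <- generate_geography(2, 3, seed = 7)
  expect_identical(gg, gg2)
  expect_error(generate_geography(1, 1, seed = 1), "ICAR")
})

test_that("generated EVI fields are spatially smooth (Moran's I beats permutation)", {
  wins <- 0L
  for (s in 1:100) {
    gg <- generate_geography(10, 10, seed = s)
    x <- gg$geography$evi_Gu
    i_obs <- moran_i(x, gg$adjacency)
    set.seed(s + 5000)
    i_perm <- moran_i(sample(x), gg$adjacency)
    wins <- wins + (i_obs > i_perm)
  }
  expect_gte(wins, 95)
})

test_that("zero conflict intensity gives an empty event table; dates bounded", {
  gg <- generate_geography(2, 3, seed = 1)
  tp <- truth_params("wasting")
  tp$conflict_base_rate <- 0
  ev <- simulate_conflict_events(gg$geography, tp, "2009-01-01", "2009-12-31", 1)
  expect_equal(nrow(ev), 0)
  expect_error(simulate_conflict_events(gg$geography, tp,
                                        "2009-12-31", "2009-01-01", 1),
               "before")
  tp$conflict_base_rate <- 1
  ev <- simulate_conflict_events(gg$geography, tp, "2009-03-05", "2009-10-20", 1)
  expect_true(all(ev$event_date >= as.Date("2009-03-05")))
  expect_true(all(ev$event_date <= as.Date("2009-10-20")))
})

test_that("event class mixture matches the stated 54/8/28/10 split", {
  gg <- generate_geography(10, 2, seed = 2)
  tp <- truth_params("wasting")
  tp$district_dispersion <- Inf      # homogeneous rates for a clean count
  tp$conflict_base_rate <- 22        # ~10k events over 10 districts x 4 years
  ev <- simulate_conflict_events(gg$geography, tp, "2007-01-01", "2010-12-31", 11)
  n <- nrow(ev)
  expect_gt(n, 8000)
  share <- mean(classify_event_type(ev$acled_type) == "battle")
  se <- sqrt(0.54 * 0.46 / n)
  expect_lt(abs(share - 0.54), 3 * se)
})

test_that("district-month counts are Poisson (chi-square GOF across seeds)", {
  gg <- generate_geography(10, 2, seed = 3)
  tp <- truth_params("wasting")
  tp$district_dispersion <- Inf
  tp$conflict_base_rate <- 1.5
  lambda <- 1.5 * tp$season_multipliers[["Hagaa"]]
  ok <- 0L
  for (s in 1:20) {
    ev <- simulate_conflict_events(gg$geography, tp, "2007-01-01", "2010-12-31",
                                   seed = 100 + s)
    # Hagaa cells: same rate everywhere; 12 months x 10 districts
    ev$month <- format(ev$event_date, "%Y-%m")
    hagaa_months <- format(seq(as.Date("2007-01-01"), as.Date("2010-12-01"),
                               by = "month"), "%Y-%m")
    hagaa_months <- hagaa_months[as.integer(substr(hagaa_months, 6, 7)) %in% 7:9]
    cells <- expand.grid(d = unique(gg$geography$district_id), m = hagaa_months)
    counts <- mapply(function(d, m) sum(ev$district_id == d & ev$month == m),
                     cells$d, cells$m)
    obs <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
             sum(counts >= 3))
    p <- c(dpois(0:2, lambda), ppois(2, lambda, lower.tail = FALSE))
    pval <- suppressWarnings(chisq.test(obs, p = p)$p.value)
    ok <- ok + (pval > 0.01)
  }
  expect_gte(ok, 18)
})

test_that("null model gives 50% prevalence; intercept-only calibrates to 21%", {
  gg <- generate_geography(4, 5, seed = 4)
  null_tp <- truth_params("wasting")
  null_tp$beta[] <- 0
  null_tp$tau_u <- Inf; null_tp$tau_v <- Inf; null_tp$tau_d <- Inf; null_tp$tau_w <- Inf
  dates <- as.Date(c("2009-01-15", "2009-05-15", "2009-08-15", "2009-11-15"))
  sim <- simulate_survey(gg$geography, gg$adjacency, NULL, null_tp,
                         10000, dates, seed = 5)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(sim$data$wasted) - 0.5), 3 * se)

  cal <- null_tp
  cal$beta["intercept"] <- qlogis(0.21)
  sim2 <- simulate_survey(gg$geography, gg$adjacency, NULL, cal,
                          10000, dates, seed = 6)
  se2 <- sqrt(0.21 * 0.79 / 10000)
  expect_lt(abs(mean(sim2$data$wasted) - 0.21), 3 * se2)
})

test_that("empirical log-odds gap between exposed and unexposed approaches the truth", {
  gg <- generate_geography(8, 8, seed = 8)
  tp <- truth_params("wasting")
  tp$beta[] <- 0
  tp$beta["intercept"] <- qlogis(0.25)
  tp$beta["conflict_longer"] <- log(1.76)
  tp$tau_u <- Inf; tp$tau_v <- Inf; tp$tau_d <- Inf; tp$tau_w <- Inf
  ev <- simulate_conflict_events(gg$geography, tp, "2008-01-01", "2009-12-31", 9)
  dates <- as.Date(c("2009-05-15", "2009-11-15"))
  sim <- simulate_survey(gg$geography, gg$adjacency, ev, tp, 20000, dates, seed = 10)
  d <- merge(sim$data, sim$exposure[, c("cluster_id", "survey_date", "longer_any")],
             by = c("cluster_id", "survey_date"))
  tab <- table(d$longer_any, d$wasted)
  expect_true(all(dim(tab) == c(2, 2)))
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(lor - log(1.76)), 3 * se)
})

test_that("generated data passes IO invariants and ICAR draws sum to zero", {
  w <- make_world(seed = 12, n_children = 400,
                  truth = list(wasting = truth_params("wasting"),
                               stunting = truth_params("stunting")))
  res <- validate_survey(w$sim$data)
  expect_equal(nrow(res$quarantine), 0)
  u <- w$sim$latent$wasting$u
  for (cmp in unique(w$adjacency$component))
    expect_lt(abs(sum(u[w$adjacency$component == cmp])), 1e-8)
  # z-scores and raw anthropometry are mutually consistent at the cutoff
  expect_equal(w$sim$data$wasted,
               classify_undernutrition(w$sim$data$whz))
  expect_equal(w$sim$data$stunted,
               classify_undernutrition(w$sim$data$haz))
  # inverting the shipped LMS reference reproduces the z-scores
  lms <- read_lms_reference()
  wfh <- lms_lookup(lms, "wfh", w$sim$data$sex, w$sim$data$height_cm)
  z <- lms_zscore(w$sim$data$weight_kg, wfh$L, wfh$M, wfh$S)
  expect_lt(max(abs(z - w$sim$data$whz)), 0.02)  # rounding of weight to 10 g
})

test_that("with all variances zero the generator is a plain logistic model", {
  w <- make_world(seed = 13, n_children = 300,
                  truth = list(wasting = local({
                    tp <- truth_params("wasting")
                    tp$tau_u <- Inf; tp$tau_v <- Inf; tp$tau_d <- Inf; tp$tau_w <- Inf
                    tp
                  })))
  lat <- w$sim$latent$wasting
  expect_true(all(lat$u == 0) && all(lat$v == 0) &&
              all(lat$d == 0) && all(lat$w == 0))
  # independently rebuild the linear predictor from the truth vector
  tp <- w$sim$truth$wasting
  design <- build_design(w$sim$data, w$sim$exposure, w$geography,
                         variant = "B", outcome = "wasted", keep_constant = TRUE)
  beta <- setNames(numeric(ncol(design$X)), colnames(design$X))
  beta[names(tp$beta)] <- tp$beta
  expect_equal(as.vector(design$X %*% beta), lat$linpred, tolerance = 1e-10)
  expect_equal(plogis(lat$linpred), lat$prob, tolerance = 1e-12)
})

test_that("unknown truth coefficients raise a dimension error naming them", {
  gg <- generate_geography(2, 3, seed = 14)
  tp <- truth_params("wasting", overrides = c(not_a_column = 0.5))
  expect_error(simulate_survey(gg$geography, gg$adjacency, NULL, tp, 50,
                               as.Date("2009-05-15"), seed = 1),
               "not_a_column")
})
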