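# Sequential attributable fractions: arithmetic, counterfactuals,
# permutation averaging and the Shapley properties.

test_that("attributable fraction arithmetic", {
  expect_equal(attributable_fraction(100, 92.4), 0.076)
  expect_equal(attributable_fraction(57, 57), 0)
  expect_lt(attributable_fraction(50, 60), 0)   # negative AFs are reported
  expect_error(attributable_fraction(0, 10), "positive")
})

test_that("counterfactual removal zeroes indicators and their interactions", {
  w <- make_world(seed = 81, n_children = 300)
  d <- build_design(w$sim$data, force_exposure_variation(w$sim$exposure), w$geography,
                    variant = "B", outcome = "wasted")
  factors <- af_factors(d)
  Xcf <- conflictnutr:::counterfactual_X(d, "recent", factors)
  expect_true(all(Xcf[, "conflict_recent"] == 0))
  # interactions containing the removed factor are recomputed
  m <- d$meta[["conflict_recent:evi"]]
  hand <- (0 - m$parent_means[1]) * (Xcf[, "evi"] - m$parent_means[2])
  expect_equal(unname(Xcf[, "conflict_recent:evi"]), unname(hand))
  # untouched columns stay untouched
  expect_equal(Xcf[, "conflict_longer"], d$X[, "conflict_longer"])
  # EVI removal sets the standardised column to the 90th percentile level
  Xev <- conflictnutr:::counterfactual_X(d, "evi", factors)
  me <- d$meta[["evi"]]
  ref <- (quantile(d$raw$evi, 0.9) - me$center) / me$scale
  expect_true(all(abs(Xev[, "evi"] - ref) < 1e-12))
  expect_error(predict_counterfactual(plugin_posterior(d, rep(0, ncol(d$X))),
                                      d, removed = "nope"),
               "unknown factor")
})

test_that("4-individual toy: expected cases match a hand-computed sigmoid sum", {
  w <- make_world(seed = 82, n_children = 200)
  d <- build_design(w$sim$data, force_exposure_variation(w$sim$exposure), w$geography,
                    variant = "B", outcome = "wasted")
  d$X <- d$X[1:4, , drop = FALSE]
  d$y <- c(1L, 0L, 1L, 1L)
  d$cluster <- d$cluster[1:4]; d$district <- d$district[1:4]; d$round <- d$round[1:4]
  beta <- setNames(rep(0, ncol(d$X)), colnames(d$X))
  beta["intercept"] <- -1; beta["conflict_recent"] <- 0.8
  post <- plugin_posterior(d, beta)
  eta <- -1 + 0.8 * d$X[, "conflict_recent"]
  expect_equal(predict_counterfactual(post, d, removed = character(0)),
               sum(1 / (1 + exp(-eta))), tolerance = 1e-12)
  # removal: recent column -> 0, its interaction columns recomputed; the
  # plug-in coefficients on interactions are 0 so only the main effect acts
  expect_equal(predict_counterfactual(post, d, removed = "recent"),
               sum(rep(plogis(-1), 4)), tolerance = 1e-12)
})

test_that("a factor with zero coefficient changes nothing; empty set is calibrated", {
  f <- cached_fit()
  post <- f$posterior; d <- f$design
  E0 <- predict_counterfactual(post, d, character(0))
  # model calibration: E_empty near observed cases (posterior plug-in)
  expect_lt(abs(E0 - sum(d$y)) / sum(d$y), 0.15)
  # force a null factor: zero out the coefficient draws for longer + interactions
  post0 <- post
  null_cols <- grepl("conflict_longer", colnames(post0$beta))
  post0$beta[, null_cols] <- 0
  E_null <- predict_counterfactual(post0, d, "longer")
  E_base <- predict_counterfactual(post0, d, character(0))
  expect_equal(E_null, E_base, tolerance = 1e-10)
})

test_that("three factors enumerate six orderings with exact Shapley efficiency", {
  f <- cached_fit()
  rep3 <- sequential_af(f$posterior, f$design, max_draws = 60)
  expect_equal(nrow(rep3$per_permutation), 6)
  full_key <- paste(sort(rep3$factors), collapse = "+")
  full_af <- unname(rep3$combined[full_key])
  # every permutation's sequential AFs sum to the combined AF
  for (r in seq_len(6))
    expect_lt(abs(sum(rep3$per_permutation[r, ]) - full_af), 1e-10)
  expect_lt(abs(sum(rep3$averaged) - full_af), 1e-10)
  # order-insensitivity: permuting the factor list permutes labels only
  rep_rev <- sequential_af(f$posterior, f$design,
                           factor_names = rev(rep3$factors), max_draws = 60)
  expect_equal(rep_rev$averaged[names(rep3$averaged)], rep3$averaged,
               tolerance = 1e-12)
  expect_error(sequential_af(f$posterior, f$design,
                             factor_names = letters[1:7]),
               "orderings")
})

test_that("all-zero factor coefficients give all-zero AFs", {
  w <- make_world(seed = 83, n_children = 250)
  d <- build_design(w$sim$data, force_exposure_variation(w$sim$exposure), w$geography,
                    variant = "B", outcome = "wasted")
  beta <- setNames(rep(0, ncol(d$X)), colnames(d$X))
  beta["intercept"] <- -1.2
  post <- plugin_posterior(d, beta)
  rep0 <- sequential_af(post, d, factor_names = c("recent", "longer"))
  expect_true(all(abs(rep0$per_permutation) < 1e-12))
  expect_true(all(abs(rep0$combined) < 1e-12))
})

test_that("2-factor averaged AFs equal an independent brute-force Shapley", {
  w <- make_world(seed = 84, n_children = 350)
  d <- build_design(w$sim$data, force_exposure_variation(w$sim$exposure), w$geography,
                    variant = "B", outcome = "wasted")
  set.seed(85)
  beta <- setNames(rnorm(ncol(d$X), 0, 0.2), colnames(d$X))
  post <- plugin_posterior(d, beta)
  factors <- af_factors(d)
  rep2 <- sequential_af(post, d, factor_names = c("recent", "longer"),
                        factors = factors)
  # independent enumeration: recompute E via raw sigmoid sums
  E <- function(removed) {
    X <- conflictnutr:::counterfactual_X(d, removed, factors)
    sum(plogis(as.vector(X %*% beta)))
  }
  O <- sum(d$y)
  af <- function(removed) (O - E(removed)) / O - (O - E(character(0))) / O
  # orderings (r, l) and (l, r)
  seq_r <- c(af("recent"), af(c("recent", "longer")) - af("recent"))
  seq_l <- c(af(c("longer", "recent")) - af("longer"), af("longer"))
  brute <- c(recent = mean(c(seq_r[1], seq_l[1])),
             longer = mean(c(seq_r[2], seq_l[2])))
  expect_equal(rep2$averaged[c("recent", "longer")], brute, tolerance = 1e-10)
})

test_that("symmetric factors receive equal averaged AFs", {
  w <- make_world(seed = 86, n_children = 300)
  exp_m <- force_exposure_variation(w$sim$exposure)
  exp_m$longer_any <- exp_m$recent_any    # identical exposure columns
  exp_m$longer_n <- exp_m$recent_n
  d <- build_design(w$sim$data, exp_m, w$geography,
                    variant = "B", outcome = "wasted")
  beta <- setNames(rep(0, ncol(d$X)), colnames(d$X))
  beta["intercept"] <- -1
  beta["conflict_recent"] <- 0.5
  beta["conflict_longer"] <- 0.5
  post <- plugin_posterior(d, beta)
  rep_s <- sequential_af(post, d, factor_names = c("recent", "longer"))
  expect_equal(unname(rep_s$averaged["recent"]),
               unname(rep_s$averaged["longer"]), tolerance = 1e-12)
})

test_that("explained-variation scaling: blend preserves the case total, literal does not", {
  f <- cached_fit()
  d <- f$design
  E_none <- predict_counterfactual(f$posterior, d, character(0), scaling = "none")
  E_blend <- predict_counterfactual(f$posterior, d, character(0), scaling = "blend")
  E_lit <- predict_counterfactual(f$posterior, d, character(0), scaling = "literal")
  n <- length(d$y); ybar <- mean(d$y)
  r2 <- conflictnutr:::explained_variation(f$posterior, d)
  expect_true(r2 > 0 && r2 < 1)
  # blend: E = n*ybar + r2*(E_none - n*ybar), exactly
  expect_equal(E_blend, n * ybar + r2 * (E_none - n * ybar), tolerance = 1e-8)
  # literal multiplication deflates the total
  expect_lt(E_lit, E_none)
})
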