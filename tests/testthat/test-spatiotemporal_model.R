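# Seasons, collinearity screen, design construction, ICAR correctness,
# the Gibbs sampler against its oracles, and effect summaries.

test_that("every month maps to exactly one season; December is configurable", {
  dates <- as.Date(sprintf("2009-%02d-15", 1:12))
  s <- season_of(dates)
  expect_equal(s[5], "Gu")       # May
  expect_equal(s[8], "Hagaa")    # August
  expect_equal(s[12], "Jilal")   # December tie-break
  expect_equal(season_of(as.Date("2009-12-15"), december = "Deyr"), "Deyr")
  expect_true(all(s %in% season_levels()))
  expect_equal(unname(table(s)["Jilal"]), 4L)  # Dec-Mar
})

test_that("collinearity screen flags duplicates, not independent noise", {
  set.seed(2)
  x <- data.frame(a = rnorm(500), b = rnorm(500))
  x$c <- x$a
  expect_warning(res <- screen_collinearity(x), "pair")
  expect_equal(nrow(res$flagged), 1)
  expect_equal(res$flagged$r, 1)
  expect_equal(sort(c(res$flagged$var1, res$flagged$var2)), c("a", "c"))
  # default threshold is 0.6; constant columns reported as undefined
  x$k <- 1
  expect_warning(res2 <- screen_collinearity(x))
  expect_equal(res2$constant, "k")

  flags <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    xx <- as.data.frame(matrix(rnorm(10000 * 4), ncol = 4))
    flags <- flags + (nrow(screen_collinearity(xx)$flagged) > 0)
  }
  expect_lte(flags, 1)   # independent columns: no flags in >= 99/100 seeds
})

test_that("design variants, reference levels and centred interactions", {
  w <- make_world(seed = 41, n_children = 300)
  dA <- build_design(w$sim$data, force_exposure_variation(w$sim$exposure), w$geography,
                     variant = "A", outcome = "wasted")
  expect_false(any(grepl("conflict", colnames(dA$X))))
  dB <- build_design(w$sim$data, force_exposure_variation(w$sim$exposure), w$geography,
                     variant = "B", outcome = "wasted")
  expect_true(all(c("conflict_recent", "conflict_longer") %in% colnames(dB$X)))
  expect_false(anyDuplicated(colnames(dB$X)) > 0)
  # agro-pastoral rows have all four livelihood indicators at zero
  agro <- w$sim$data$livelihood[complete.cases(w$sim$data)] == "agro-pastoral"
  liv_cols <- grep("^livelihood_", colnames(dB$X))
  if (any(agro)) expect_true(all(dB$X[agro, liv_cols] == 0))
  # standardised continuous columns have mean 0, sd 1, recorded transform
  for (col in c("evi", "rainfall", "temperature")) {
    expect_lt(abs(mean(dB$X[, col])), 1e-10)
    expect_equal(sd(dB$X[, col]), 1, tolerance = 1e-10)
    m <- dB$meta[[col]]
    expect_equal((dB$raw[[col]] - m$center) / m$scale, unname(dB$X[, col]))
  }
  # interaction columns are products of mean-centred parents
  nm <- "conflict_longer:evi"
  expect_true(nm %in% colnames(dB$X))
  m <- dB$meta[[nm]]
  hand <- (dB$X[, "conflict_longer"] - mean(dB$X[, "conflict_longer"])) *
          (dB$X[, "evi"] - mean(dB$X[, "evi"]))
  expect_equal(unname(dB$X[, nm]), unname(hand), tolerance = 1e-12)
})

test_that("3-record toy interaction equals hand computation", {
  # conflict_recent = (1,0,1), carbohydrate = (1,1,0)
  # centred parents: (2/3,-1/3,2/3) and (1/3,1/3,-2/3)
  cr <- c(1, 0, 1); cb <- c(1, 1, 0)
  hand <- (cr - mean(cr)) * (cb - mean(cb))
  expect_equal(hand, c(1/9, -2/9, -2/9), tolerance = 1e-12)
})

test_that("ICAR structure: conditional mean is the neighbour average", {
  adj <- make_adjacency(c("a", "b", "c"), c("b", "c", "d"))  # path a-b-c-d
  Q <- icar_precision(adj)
  set.seed(3)
  u <- rnorm(4)
  for (k in 1:4) {
    cond_mean <- -sum(Q[k, -k] * u[-k]) / Q[k, k]
    expect_equal(cond_mean, mean(u[adj$nbs[[k]]]), tolerance = 1e-12)
  }
  # conditioning through the sampler's own linear algebra: clamp nodes
  # 1, 3, 4 with enormous observation precision and read node 2's mean
  B <- 1e10; tau <- 2.7
  fixed <- c(0.3, NA, -1.1, 0.6)
  P <- tau * Q + diag(c(B, 0, B, B))
  b <- c(B * fixed[1], 0, B * fixed[3], B * fixed[4])
  mu <- solve(P, b)
  expect_equal(mu[2], (fixed[1] + fixed[3]) / 2, tolerance = 1e-6)
  # prior draws: mean-zero per component to 1e-8, quadform matches Q
  set.seed(4)
  for (i in 1:20) {
    u <- icar_sample(adj, tau = 1.5)
    expect_lt(abs(sum(u)), 1e-8)
    expect_equal(icar_quadform(adj, u), as.vector(t(u) %*% Q %*% u),
                 tolerance = 1e-10)
  }
})

test_that("intercept-only fit recovers the simulated prevalence", {
  set.seed(5)
  n <- 5000
  df <- data.frame(child_id = as.character(1:n), cluster_id = "c1",
                   district_id = "d1", region_id = "r1",
                   survey_date = as.Date("2009-05-15"),
                   age_months = 24, sex = "male", livelihood = "pastoral",
                   diarrhoea = 0, ari = 0, fever = 0, suspected_measles = 0,
                   vitamin_a = 1, measles_vax = 1, polio_vax = 1,
                   household_size = 5, n_under5 = 1, female_head = 0,
                   mother_age = 30, mother_muac = 25,
                   carbohydrate = 1, protein = 0, fats = 0, fruits_veg = 0,
                   y = rbinom(n, 1, 0.3))
  geo <- data.frame(cluster_id = "c1", district_id = "d1", region_id = "r1")
  for (s in season_levels())
    for (v in c("evi", "rainfall", "temperature"))
      geo[[paste0(v, "_", s)]] <- 1
  geo$distance_to_water <- 1; geo$urbanisation <- 0
  exp0 <- build_exposure_matrix(NULL, geo,
                                data.frame(cluster_id = "c1",
                                           survey_date = as.Date("2009-05-15")))
  d <- build_design(df, exp0, geo, variant = "A", outcome = "y")
  expect_equal(colnames(d$X), "intercept")   # everything else is constant
  fit <- fit_model(d, adjacency = NULL,
                   mcmc = mcmc_control(chains = 2, iter = 400, burnin = 150,
                                       thin = 1),
                   seed = 6, use_spatial = FALSE, use_iid_cluster = FALSE,
                   use_district = FALSE, use_temporal = FALSE)
  p_hat <- mean(plogis(fit$beta[, "intercept"]))
  expect_lt(abs(p_hat - mean(df$y)), 0.02)
})

test_that("flat-prior fixed-effects posterior matches the ML (IRLS) oracle", {
  w <- make_world(seed = 51, n_districts = 3, clusters_per_district = 5,
                  n_children = 2500)
  d <- build_design(w$sim$data, force_exposure_variation(w$sim$exposure), w$geography,
                    variant = "A", outcome = "wasted")
  fit <- fit_model(d, adjacency = NULL,
                   priors = prior_spec(beta_precision = 1e-6),
                   mcmc = mcmc_control(chains = 2, iter = 700, burnin = 250,
                                       thin = 1),
                   seed = 7, use_spatial = FALSE, use_iid_cluster = FALSE,
                   use_district = FALSE, use_temporal = FALSE)
  ml <- suppressWarnings(glm.fit(d$X, d$y, family = binomial()))
  pm <- colMeans(fit$beta)
  psd <- apply(fit$beta, 2, sd)
  expect_true(all(abs(pm - ml$coefficients) < 2 * psd))
  expect_true(all(fit$diag_rhat < 1.1, na.rm = TRUE))
})

test_that("posterior is invariant to cluster relabelling (within MC error)", {
  w <- make_world(seed = 61, n_districts = 3, clusters_per_district = 4,
                  n_children = 600)
  w$sim$exposure <- force_exposure_variation(w$sim$exposure)
  d1 <- build_design(w$sim$data, w$sim$exposure, w$geography,
                     variant = "B", outcome = "wasted")
  mc <- mcmc_control(chains = 1, iter = 500, burnin = 200, thin = 1)
  f1 <- fit_model(d1, w$adjacency, mcmc = mc, seed = 8)

  # relabel clusters (reverse order) consistently everywhere
  relab <- setNames(rev(w$geography$cluster_id), w$geography$cluster_id)
  geo2 <- w$geography; geo2$cluster_id <- unname(relab[geo2$cluster_id])
  geo2 <- geo2[order(geo2$cluster_id), ]
  dat2 <- w$sim$data; dat2$cluster_id <- unname(relab[dat2$cluster_id])
  exp2 <- w$sim$exposure; exp2$cluster_id <- unname(relab[exp2$cluster_id])
  adj2 <- make_adjacency(unname(relab[w$adjacency$ids[w$adjacency$edges[, 1]]]),
                         unname(relab[w$adjacency$ids[w$adjacency$edges[, 2]]]),
                         ids = sort(unname(relab)))
  d2 <- build_design(dat2, exp2, geo2, variant = "B", outcome = "wasted")
  f2 <- fit_model(d2, adj2, mcmc = mc, seed = 8)
  for (term in c("conflict_recent", "conflict_longer", "evi")) {
    mcse <- function(f) sd(f$beta[, term]) / sqrt(max(f$diag_ess[term], 5))
    bound <- 5 * sqrt(mcse(f1)^2 + mcse(f2)^2)
    expect_lt(abs(mean(f1$beta[, term]) - mean(f2$beta[, term])), bound)
  }
})

test_that("summarize_effects: degenerate draws, published-style grid, quantile oracle", {
  w <- make_world(seed = 71, n_children = 200)
  d <- build_design(w$sim$data, force_exposure_variation(w$sim$exposure), w$geography,
                    variant = "B", outcome = "wasted")
  post <- plugin_posterior(d, rep(0, ncol(d$X)), n_draws = 120)
  s <- summarize_effects(post)
  expect_true(all(s$or == 1) && all(s$lo == 1) && all(s$hi == 1))
  expect_false(any(s$significant))

  grid <- log(seq(1.71, 1.81, length.out = 101))
  post$beta[, "conflict_longer"] <- rep_len(grid, nrow(post$beta))
  post$beta <- post$beta[order(runif(nrow(post$beta))), , drop = FALSE]
  post$beta[, "conflict_longer"] <- sort(post$beta[, "conflict_longer"])
  s2 <- summarize_effects(post)
  row <- s2[s2$term == "conflict_longer", ]
  expect_equal(row$or, 1.76, tolerance = 0.01)
  expect_equal(row$lo, 1.71, tolerance = 0.01)
  expect_equal(row$hi, 1.81, tolerance = 0.01)

  # independent sort-based quantile oracle (type-7 interpolation by hand)
  set.seed(9)
  draws <- rnorm(nrow(post$beta), 0.2, 0.4)
  post$beta[, "evi"] <- draws
  s3 <- summarize_effects(post)
  manual_q <- function(x, p) {
    xs <- sort(x); h <- (length(xs) - 1) * p
    lo <- floor(h) + 1
    xs[lo] + (h - floor(h)) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  row3 <- s3[s3$term == "evi", ]
  expect_equal(row3$lo, exp(manual_q(draws, 0.025)), tolerance = 1e-10)
  expect_equal(row3$hi, exp(manual_q(draws, 0.975)), tolerance = 1e-10)
})

test_that("posterior round-trips through its columnar CSV persistence", {
  f <- cached_fit()
  stem <- tempfile("post")
  write_posterior(f$posterior, stem)
  back <- read_posterior(stem)
  expect_equal(back$beta, f$posterior$beta, tolerance = 1e-12)
  expect_equal(back$u, f$posterior$u, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$cluster_ids, f$posterior$cluster_ids)
  expect_equal(back$round_dates, f$posterior$round_dates)
})
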