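# Bayesian hierarchical spatio-temporal logistic regression fitted by
# Polya-Gamma augmented Gibbs sampling.
#
# Model:  y_i ~ Bernoulli(p_i)
#   logit p_i = x_i' beta + u_{c(i)} + v_{c(i)} + w_{t(i)} + d_{dist(i)}
# with u ~ ICAR(tau_u) on the cluster graph (sum-to-zero per component),
# v, d iid Gaussian, w a first-order random walk over survey rounds
# (sum-to-zero), Gaussian prior on beta and Gamma hyperpriors on the
# precisions.  Augmenting each observation with omega_i ~ PG(1, eta_i)
# makes every conditional conjugate (Polson, Scott & Windle 2013).

#' Prior specification
#'
#' @param beta_precision Gaussian prior precision for fixed effects
#'   (mean 0); default 1e-4, weakly informative.
#' @param tau_shape,tau_rate Gamma hyperprior for all random-effect
#'   precisions; default Gamma(1, 5e-4), a common latent-Gaussian choice.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(beta_precision = 1e-4, tau_shape = 1, tau_rate = 5e-4) {
  stopifnot(beta_precision > 0, tau_shape > 0, tau_rate > 0)
  structure(list(beta_precision = beta_precision,
                 tau_shape = tau_shape, tau_rate = tau_rate),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param chains number of chains (run sequentially).
#' @param iter iterations per chain (must exceed `burnin`).
#' @param burnin discarded initial iterations per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iter = 5000, burnin = 2000, thin = 2) {
  if (iter <= burnin) stop("iterations must exceed burn-in")
  stopifnot(chains >= 1, thin >= 1)
  structure(list(chains = chains, iter = iter, burnin = burnin, thin = thin),
            class = "mcmc_control")
}

# draw from N(P^{-1} b, P^{-1}) given precision P (dense) and linear term b
draw_gaussian_canonical <- function(P, b) {
  R <- chol(P)                       # P = R'R, R upper
  mu <- backsolve(R, forwardsolve(t(R), b))
  mu + backsolve(R, stats::rnorm(length(b)))
}

#' Fit the hierarchical spatio-temporal logistic model
#'
#' Gibbs sampler with Polya-Gamma augmentation: conjugate Gaussian
#' updates for the fixed effects and every random-effect block, Gamma
#' updates for precisions.  The ICAR block and the random walk are
#' re-centred (sum-to-zero, per graph component) after every update.
#' Random-effect blocks can be switched off individually, giving plain
#' logistic regression in the limit.
#'
#' @param design a `cn_design` with a non-null `y` (see [build_design()]).
#' @param adjacency adjacency object covering all `design$cluster_ids`;
#'   may be `NULL` when `use_spatial = FALSE`.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed; chain `c` uses `seed + 1000 * (c - 1)`.
#' @param use_spatial,use_iid_cluster,use_district,use_temporal logical
#'   toggles for the u, v, d, w blocks.
#' @param verbose print progress.
#' @return object of class `cn_posterior`: draw matrices `beta`
#'   (draws x p), `u`, `v` (draws x K), `d` (draws x D), `w`
#'   (draws x T), `tau` (draws x 4), `chain` id per draw, plus design
#'   metadata and convergence summaries (`diag_rhat`, `diag_ess` per
#'   fixed effect).
#' @export
fit_model <- function(design, adjacency = NULL, priors = prior_spec(),
                      mcmc = mcmc_control(), seed = 1L,
                      use_spatial = TRUE, use_iid_cluster = TRUE,
                      use_district = TRUE, use_temporal = TRUE,
                      verbose = FALSE) {
  stopifnot(inherits(design, "cn_design"))
  y <- design$y
  if (is.null(y)) stop("design has no outcome; rebuild with `outcome =`")
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  ci <- design$cluster; di <- design$district; ti <- design$round
  K <- length(design$cluster_ids)
  D <- length(design$district_ids)
  T <- length(design$round_dates)
  kappa <- y - 0.5

  if (use_spatial) {
    if (is.null(adjacency)) stop("spatial block requested but no adjacency given")
    idx <- match(design$cluster_ids, adjacency$ids)
    if (anyNA(idx)) stop("adjacency does not cover all clusters in the design")
    # reorder graph structures to the design's cluster order
    Q <- icar_precision(adjacency)[idx, idx]
    comp <- adjacency$component[idx]
    icar_rank <- K - length(unique(comp))
    edges <- adjacency$edges
    edges <- cbind(match(adjacency$ids[edges[, 1]], design$cluster_ids),
                   match(adjacency$ids[edges[, 2]], design$cluster_ids))
  }
  if (use_temporal) { Rw <- rw1_precision(T); rw_rank <- max(T - 1, 0) }

  a0 <- priors$tau_shape; b0 <- priors$tau_rate
  B0 <- diag(priors$beta_precision, p)

  n_keep <- (mcmc$iter - mcmc$burnin) %/% mcmc$thin
  total <- n_keep * mcmc$chains
  S <- list(beta = matrix(NA_real_, total, p, dimnames = list(NULL, colnames(X))),
            u = matrix(0, total, K), v = matrix(0, total, K),
            d = matrix(0, total, D), w = matrix(0, total, T),
            tau = matrix(NA_real_, total, 4,
                         dimnames = list(NULL, c("tau_u", "tau_v", "tau_d", "tau_w"))),
            chain = integer(total))
  slot <- 0L

  for (chain in seq_len(mcmc$chains)) {
    set.seed(as.integer(seed) + 1000L * (chain - 1L))
    beta <- stats::rnorm(p, 0, 0.1)
    u <- numeric(K); v <- numeric(K); d <- numeric(D); w <- numeric(T)
    tau_u <- 1; tau_v <- 1; tau_d <- 1; tau_w <- 1

    for (it in seq_len(mcmc$iter)) {
      Xb <- as.vector(X %*% beta)
      re <- u[ci] + v[ci] + w[ti] + d[di]
      eta <- Xb + re
      omega <- .rpg_vec(eta)
      if (any(!is.finite(omega)))
        stop("non-finite Polya-Gamma draw at iteration ", it)

      # fixed effects
      P <- crossprod(X, X * omega) + B0
      b <- crossprod(X, kappa - omega * re)
      beta <- draw_gaussian_canonical(P, b)
      if (any(!is.finite(beta))) stop("non-finite beta update at iteration ", it)
      Xb <- as.vector(X %*% beta)

      # spatial ICAR block
      if (use_spatial) {
        off <- Xb + v[ci] + w[ti] + d[di]
        Sw <- rowsum_safe(omega, ci, K)
        bu <- rowsum_safe(kappa - omega * off, ci, K)
        Pu <- tau_u * Q; diag(Pu) <- diag(Pu) + Sw + 1e-8
        u <- draw_gaussian_canonical(Pu, bu)
        u <- center_by_component(u, comp)
        tau_u <- stats::rgamma(1, a0 + icar_rank / 2,
                               b0 + icar_quadform(list(edges = edges), u) / 2)
      }

      # iid cluster block
      if (use_iid_cluster) {
        off <- Xb + u[ci] + w[ti] + d[di]
        Sw <- rowsum_safe(omega, ci, K)
        bv <- rowsum_safe(kappa - omega * off, ci, K)
        pv <- tau_v + Sw
        v <- stats::rnorm(K, bv / pv, 1 / sqrt(pv))
        tau_v <- stats::rgamma(1, a0 + K / 2, b0 + sum(v * v) / 2)
      }

      # district block
      if (use_district) {
        off <- Xb + u[ci] + v[ci] + w[ti]
        Sw <- rowsum_safe(omega, di, D)
        bd <- rowsum_safe(kappa - omega * off, di, D)
        pd <- tau_d + Sw
        d <- stats::rnorm(D, bd / pd, 1 / sqrt(pd))
        tau_d <- stats::rgamma(1, a0 + D / 2, b0 + sum(d * d) / 2)
      }

      # temporal RW1 block
      if (use_temporal && T > 1) {
        off <- Xb + u[ci] + v[ci] + d[di]
        Sw <- rowsum_safe(omega, ti, T)
        bw <- rowsum_safe(kappa - omega * off, ti, T)
        Pw <- tau_w * Rw; diag(Pw) <- diag(Pw) + Sw + 1e-8
        w <- draw_gaussian_canonical(Pw, bw)
        w <- w - mean(w)
        dw <- diff(w)
        tau_w <- stats::rgamma(1, a0 + rw_rank / 2, b0 + sum(dw * dw) / 2)
      }

      if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0L) {
        slot <- slot + 1L
        S$beta[slot, ] <- beta
        S$u[slot, ] <- u; S$v[slot, ] <- v
        S$d[slot, ] <- d; S$w[slot, ] <- w
        S$tau[slot, ] <- c(if (use_spatial) tau_u else NA,
                           if (use_iid_cluster) tau_v else NA,
                           if (use_district) tau_d else NA,
                           if (use_temporal && T > 1) tau_w else NA)
        S$chain[slot] <- chain
      }
    }
    if (verbose) message("chain ", chain, " done")
  }

  post <- structure(c(S, list(
    design_cols = colnames(X), meta = design$meta,
    cluster_ids = design$cluster_ids, district_ids = design$district_ids,
    round_dates = design$round_dates, variant = design$variant,
    outcome = design$outcome, n_obs = n,
    mcmc = mcmc, priors = priors, seed = seed,
    blocks = c(spatial = use_spatial, iid_cluster = use_iid_cluster,
               district = use_district, temporal = use_temporal && T > 1))),
    class = "cn_posterior")
  post$diag_rhat <- apply_split_rhat(S$beta, S$chain)
  post$diag_ess <- apply_ess(S$beta, S$chain)
  post
}

# rowsum over an index with a fixed number of groups, zeros for empty ones
rowsum_safe <- function(x, index, ngroups) {
  out <- numeric(ngroups)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# split-Rhat (Gelman et al.): split each chain in half, compare
# between-half and within-half variances
split_rhat <- function(x, chain) {
  halves <- list()
  for (cid in unique(chain)) {
    xs <- x[chain == cid]
    m <- length(xs) %/% 2
    if (m < 2) return(NA_real_)
    halves <- c(halves, list(xs[1:m], xs[(m + 1):(2 * m)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size via initial positive sequence of autocovariances
ess_one <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

apply_split_rhat <- function(draws, chain) {
  apply(draws, 2, split_rhat, chain = chain)
}

apply_ess <- function(draws, chain) {
  out <- vapply(seq_len(ncol(draws)), function(j)
    sum(vapply(split(draws[, j], chain), ess_one, numeric(1)), na.rm = TRUE),
    numeric(1))
  stats::setNames(out, colnames(draws))
}

#' Posterior odds-ratio table
#'
#' Per fixed effect: posterior-median odds ratio, equal-tailed 95%
#' credible interval, and a significance flag (interval excludes 1).
#' Standardised continuous covariates are additionally back-transformed
#' to the per-unit scale (`or_unit`) using the recorded scaling.
#'
#' @param posterior a `cn_posterior`.
#' @param level credible level (default 0.95).
#' @return data frame: `term`, `or`, `lo`, `hi`, `significant`, `scale`,
#'   `or_unit`, `lo_unit`, `hi_unit`.
#' @export
summarize_effects <- function(posterior, level = 0.95) {
  if (nrow(posterior$beta) < 100)
    stop("need at least 100 retained draws to summarise")
  a <- (1 - level) / 2
  terms <- colnames(posterior$beta)
  out <- lapply(terms, function(tm) {
    b <- posterior$beta[, tm]
    q <- unname(stats::quantile(b, c(a, 0.5, 1 - a)))
    sc <- posterior$meta[[tm]]
    scale <- if (!is.null(sc$scale)) sc$scale else 1
    data.frame(term = tm,
               or = exp(q[2]), lo = exp(q[1]), hi = exp(q[3]),
               significant = exp(q[1]) > 1 | exp(q[3]) < 1,
               scale = scale,
               or_unit = exp(q[2] / scale),
               lo_unit = exp(q[1] / scale),
               hi_unit = exp(q[3] / scale),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# per-draw linear predictor matrix (draws x n); X_cf overrides the design
# matrix (counterfactual prediction); draws may be subsampled
posterior_linpred <- function(posterior, design, X = design$X,
                              draw_idx = NULL) {
  if (is.null(draw_idx)) draw_idx <- seq_len(nrow(posterior$beta))
  ci <- design$cluster; di <- design$district; ti <- design$round
  eta <- tcrossprod(posterior$beta[draw_idx, , drop = FALSE], X)
  eta + posterior$u[draw_idx, ci, drop = FALSE] +
        posterior$v[draw_idx, ci, drop = FALSE] +
        posterior$w[draw_idx, ti, drop = FALSE] +
        posterior$d[draw_idx, di, drop = FALSE]
}

#' Write/read posterior draws as columnar CSV + JSON metadata
#'
#' @param posterior a `cn_posterior`.
#' @param stem path stem; writes `<stem>.csv` (one column per parameter,
#'   one row per draw) and `<stem>.json` (dimensions, ids, settings).
#' @return the stem, invisibly.
#' @export
write_posterior <- function(posterior, stem) {
  df <- data.frame(chain = posterior$chain,
                   posterior$beta,
                   stats::setNames(as.data.frame(posterior$u),
                                   paste0("u.", posterior$cluster_ids)),
                   stats::setNames(as.data.frame(posterior$v),
                                   paste0("v.", posterior$cluster_ids)),
                   stats::setNames(as.data.frame(posterior$d),
                                   paste0("d.", posterior$district_ids)),
                   stats::setNames(as.data.frame(posterior$w),
                                   paste0("w.", seq_along(posterior$round_dates))),
                   posterior$tau, check.names = FALSE)
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  meta <- list(design_cols = posterior$design_cols,
               cluster_ids = posterior$cluster_ids,
               district_ids = posterior$district_ids,
               round_dates = format(posterior$round_dates),
               variant = posterior$variant, outcome = posterior$outcome,
               n_obs = posterior$n_obs, seed = posterior$seed,
               blocks = as.list(posterior$blocks),
               meta = posterior$meta)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix, "\\."), names(df))
    as.matrix(df[, cols, drop = FALSE])
  }
  post <- list(beta = as.matrix(df[, meta$design_cols, drop = FALSE]),
               u = grab("u"), v = grab("v"), d = grab("d"), w = grab("w"),
               tau = as.matrix(df[, c("tau_u", "tau_v", "tau_d", "tau_w")]),
               chain = df$chain,
               design_cols = meta$design_cols,
               meta = meta$meta,
               cluster_ids = meta$cluster_ids,
               district_ids = meta$district_ids,
               round_dates = as.Date(meta$round_dates),
               variant = meta$variant, outcome = meta$outcome,
               n_obs = meta$n_obs, seed = meta$seed,
               blocks = unlist(meta$blocks))
  class(post) <- "cn_posterior"
  post
}
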