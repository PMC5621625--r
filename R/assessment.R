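# Model assessment: WAIC and observed-versus-fitted calibration.

#' Pointwise Bernoulli log-likelihood over posterior draws
#'
#' Entry `(s, i)` is `y_i log p_i^(s) + (1 - y_i) log(1 - p_i^(s))`
#' with `p^(s)` the fitted probability under draw `s`.  Probabilities of
#' exactly 0 or 1 that contradict the outcome are clamped at 1e-12 and
#' the clamp count is attached as an attribute.
#'
#' @param posterior a `cn_posterior`.
#' @param design the matching `cn_design` (with outcome).
#' @param max_draws posterior draws used (evenly thinned).
#' @return draws x observations matrix, attribute `n_clamped`.
#' @export
pointwise_loglik <- function(posterior, design, max_draws = 1000) {
  y <- design$y
  if (is.null(y)) stop("design has no outcome")
  idx <- thin_draws(nrow(posterior$beta), max_draws)
  eta <- posterior_linpred(posterior, design, draw_idx = idx)
  p <- stats::plogis(eta)
  n_clamped <- sum(p[, y == 1] < 1e-12) + sum(p[, y == 0] > 1 - 1e-12)
  if (n_clamped) message("pointwise_loglik: clamped ", n_clamped,
                         " degenerate probabilities at 1e-12")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sweep(log(p), 2, y, `*`) + sweep(log1p(-p), 2, 1 - y, `*`)
  attr(ll, "n_clamped") <- n_clamped
  ll
}

# column-wise log(mean(exp(x))) with max shift
log_mean_exp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colMeans(exp(sweep(m, 2, mx))))
}

#' Widely applicable information criterion
#'
#' `lppd = sum_i log mean_s exp(ll_si)` (computed with a per-observation
#' max shift), `p_waic = sum_i var_s(ll_si)`, and
#' `waic = -2 (lppd - p_waic)`.  The variance defaults to the unbiased
#' (n-1) sample variance; `var_type = "population"` divides by n, the
#' convention under which exact draw duplication leaves WAIC unchanged.
#'
#' @param loglik draws x observations log-likelihood matrix.
#' @param var_type `"unbiased"` (default) or `"population"`.
#' @return list of class `waic_result`: `lppd`, `p_waic`, `waic`,
#'   `pointwise` (data frame of per-observation contributions).
#' @export
waic <- function(loglik, var_type = c("unbiased", "population")) {
  var_type <- match.arg(var_type)
  S <- nrow(loglik)
  lppd_i <- log_mean_exp(loglik)
  if (S < 2) {
    warning("single posterior draw: p_waic is 0")
    p_i <- rep(0, ncol(loglik))
  } else {
    mu <- colMeans(loglik)
    ss <- colSums(sweep(loglik, 2, mu)^2)
    p_i <- ss / if (var_type == "unbiased") (S - 1) else S
  }
  lppd <- sum(lppd_i); p_waic <- sum(p_i)
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic),
                 pointwise = data.frame(lppd = lppd_i, p_waic = p_i),
                 var_type = var_type),
            class = "waic_result")
}

#' Compare two WAIC results
#' @param waic_a,waic_b `waic_result` objects (e.g. without / with
#'   conflict covariates).
#' @return list: `waic_a`, `waic_b`, `delta` (`waic_a - waic_b`; positive
#'   favours model B).
#' @export
compare_waic <- function(waic_a, waic_b) {
  list(waic_a = waic_a$waic, waic_b = waic_b$waic,
       delta = waic_a$waic - waic_b$waic)
}

#' Observed versus fitted prevalence by group
#'
#' Per group (clusters by default): observed outcome prevalence and
#' posterior-mean fitted prevalence, plus the intercept, slope and
#' squared correlation of fitted on observed across groups.  With
#' constant fitted values the correlation is undefined and reported as
#' `NA`.
#'
#' @param posterior a `cn_posterior`.
#' @param design matching `cn_design`.
#' @param group `"cluster"` or `"district"`.
#' @param max_draws posterior draws used.
#' @return list: `table` (group, n, observed, fitted), `intercept`,
#'   `slope`, `r_squared`.
#' @export
observed_vs_fitted <- function(posterior, design, group = c("cluster", "district"),
                               max_draws = 400) {
  group <- match.arg(group)
  idx <- thin_draws(nrow(posterior$beta), max_draws)
  p_hat <- colMeans(stats::plogis(posterior_linpred(posterior, design,
                                                    draw_idx = idx)))
  g <- if (group == "cluster") design$cluster else design$district
  ids <- if (group == "cluster") design$cluster_ids else design$district_ids
  obs <- tapply(design$y, g, mean)
  fit <- tapply(p_hat, g, mean)
  n_g <- tapply(design$y, g, length)
  tab <- data.frame(group = ids[as.integer(names(obs))],
                    n = as.integer(n_g), observed = as.numeric(obs),
                    fitted = as.numeric(fit), stringsAsFactors = FALSE)
  if (nrow(tab) >= 2 && stats::sd(tab$fitted) > 0 && stats::sd(tab$observed) > 0) {
    co <- stats::coef(stats::lm(fitted ~ observed, data = tab))
    r2 <- stats::cor(tab$observed, tab$fitted)^2
    list(table = tab, intercept = unname(co[1]), slope = unname(co[2]),
         r_squared = r2)
  } else {
    list(table = tab, intercept = NA_real_, slope = NA_real_,
         r_squared = NA_real_)
  }
}
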