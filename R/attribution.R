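# Adjusted sequential attributable fractions by counterfactual
# prediction and permutation (Shapley) averaging.

#' Risk-factor definitions for attribution
#'
#' A factor names a design column plus the counterfactual reference it is
#' set to under "removal".  Binary exposure indicators are set to 0 (the
#' unexposed state).  For the continuous vegetation index, whose hazard
#' is *low* values (drought), removal sets the raw EVI to its sample
#' `evi_quantile` (default the 90th percentile, a "protective" level);
#' this choice is explicit and configurable because no counterfactual
#' level for a continuous factor is canonical.
#'
#' @param design a `cn_design`.
#' @param evi_quantile reference quantile for the EVI counterfactual.
#' @return named list of factor definitions (`column`, `reference` on the
#'   raw scale).
#' @export
af_factors <- function(design, evi_quantile = 0.9) {
  defs <- list(
    recent = list(column = "conflict_recent", reference = 0),
    longer = list(column = "conflict_longer", reference = 0))
  if ("evi" %in% names(design$raw))
    defs$evi <- list(column = "evi",
                     reference = unname(stats::quantile(design$raw$evi,
                                                        evi_quantile)))
  defs
}

# rebuild the design matrix with the given factors at their reference,
# recomputing standardised main columns and every interaction column that
# involves a removed factor
counterfactual_X <- function(design, removed, factors) {
  X <- design$X
  changed <- character(0)
  for (f in removed) {
    if (!f %in% names(factors)) stop("unknown factor: ", f)
    col <- factors[[f]]$column
    if (!col %in% colnames(X))
      stop("factor ", f, " has no matching design column ", col)
    m <- design$meta[[col]]
    ref <- factors[[f]]$reference
    X[, col] <- (ref - m$center) / m$scale
    changed <- c(changed, col)
  }
  for (nm in names(design$meta)) {
    m <- design$meta[[nm]]
    if (m$kind != "interaction" || !any(m$parents %in% changed)) next
    X[, nm] <- (X[, m$parents[1]] - m$parent_means[1]) *
               (X[, m$parents[2]] - m$parent_means[2])
  }
  X
}

# evenly spaced draw subsample indices
thin_draws <- function(n_draws, max_draws) {
  if (n_draws <= max_draws) seq_len(n_draws)
  else unique(round(seq(1, n_draws, length.out = max_draws)))
}

#' Expected cases under counterfactual removal of risk factors
#'
#' Sets each removed factor (and every interaction column containing it)
#' to its reference state, computes the posterior-mean predicted
#' probability per child, optionally applies explained-variation scaling,
#' and sums: `E_S = sum_i p_hat_i`.
#'
#' @param posterior a `cn_posterior`.
#' @param design the `cn_design` the posterior was fitted to.
#' @param removed character vector of factor names (may be empty).
#' @param factors factor definitions from [af_factors()].
#' @param scaling `"none"` (default), `"blend"`
#'   (`p <- ybar + R2 * (p - ybar)` with `R2` the latent-scale
#'   variance-partition coefficient of the fixed effects), or
#'   `"literal"` (`p <- R2 * p`, the uncalibrated literal reading).
#' @param max_draws posterior draws used (evenly thinned).
#' @return scalar expected case count `E_S`.
#' @export
predict_counterfactual <- function(posterior, design, removed = character(0),
                                   factors = af_factors(design),
                                   scaling = c("none", "blend", "literal"),
                                   max_draws = 400) {
  scaling <- match.arg(scaling)
  Xcf <- counterfactual_X(design, removed, factors)
  idx <- thin_draws(nrow(posterior$beta), max_draws)
  eta <- posterior_linpred(posterior, design, X = Xcf, draw_idx = idx)
  p_hat <- colMeans(stats::plogis(eta))
  if (scaling != "none") {
    r2 <- explained_variation(posterior, design, draw_idx = idx)
    ybar <- mean(design$y)
    p_hat <- if (scaling == "blend") ybar + r2 * (p_hat - ybar) else r2 * p_hat
  }
  sum(p_hat)
}

# latent-scale variance-partition coefficient: fixed-effect variance over
# fixed + random + logistic residual variance (pi^2/3)
explained_variation <- function(posterior, design, draw_idx = NULL) {
  if (is.null(draw_idx)) draw_idx <- thin_draws(nrow(posterior$beta), 400)
  bbar <- colMeans(posterior$beta[draw_idx, , drop = FALSE])
  fix <- as.vector(design$X %*% bbar)
  re <- colMeans(posterior$u[draw_idx, design$cluster, drop = FALSE] +
                 posterior$v[draw_idx, design$cluster, drop = FALSE] +
                 posterior$w[draw_idx, design$round, drop = FALSE] +
                 posterior$d[draw_idx, design$district, drop = FALSE])
  vf <- stats::var(fix)
  vf / (vf + stats::var(re) + pi^2 / 3)
}

#' Attributable fraction from observed and expected cases
#'
#' `AF = (O - E_S) / O`; negative values are legitimate (a protective
#' removal) and are reported as computed.
#'
#' @param observed observed case count `O` (> 0).
#' @param expected expected case count `E_S` under removal.
#' @return scalar AF.
#' @export
attributable_fraction <- function(observed, expected) {
  if (!is.finite(observed) || observed <= 0)
    stop("attributable fraction undefined: observed cases must be positive")
  (observed - expected) / observed
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

#' Permutation-averaged sequential attributable fractions
#'
#' For every ordering of the chosen risk factors, removes them
#' cumulatively, computes the combined AF of each nested removed set, and
#' attributes to the factor at step `k` the increment
#' `AF(first k) - AF(first k-1)`.  Averaging the per-factor increments
#' over all orderings gives the adjusted sequential AF (the Shapley
#' value); by construction the averages sum exactly to the combined AF of
#' removing all factors.
#'
#' @inheritParams predict_counterfactual
#' @param factor_names factors to attribute (1-6; factorial growth).
#' @return object of class `af_report`: `factors`, `observed`,
#'   `expected` (named per removed subset), `combined` (AF per subset:
#'   singletons, pairs, full set), `per_permutation` (matrix orderings x
#'   factors), `averaged` (named), `scaling`, `r2` (when scaled).
#' @export
sequential_af <- function(posterior, design,
                          factor_names = names(af_factors(design)),
                          factors = af_factors(design),
                          scaling = c("none", "blend", "literal"),
                          max_draws = 400) {
  scaling <- match.arg(scaling)
  k <- length(factor_names)
  if (k < 1) stop("need at least one factor")
  if (k > 6) stop("more than 6 factors means ", factorial(k),
                  " orderings; restrict the factor list")
  missing_f <- setdiff(factor_names, names(factors))
  if (length(missing_f)) stop("unknown factor(s): ", paste(missing_f, collapse = ", "))

  O <- sum(design$y)
  subset_key <- function(s) paste(sort(s), collapse = "+")
  E_cache <- new.env(parent = emptyenv())
  E_of <- function(s) {
    key <- if (length(s)) subset_key(s) else "(none)"
    if (is.null(E_cache[[key]]))
      E_cache[[key]] <- predict_counterfactual(posterior, design, removed = s,
                                               factors = factors,
                                               scaling = scaling,
                                               max_draws = max_draws)
    E_cache[[key]]
  }

  perms <- all_permutations(factor_names)
  per_perm <- matrix(NA_real_, length(perms), k,
                     dimnames = list(NULL, factor_names))
  # AFs are measured against the model's own no-removal baseline AF(0):
  # for a calibrated fit E_0 = O and this is exactly (O - E_S)/O, but the
  # baseline keeps null factors at AF 0 even under plug-in miscalibration
  base_af <- attributable_fraction(O, E_of(character(0)))
  for (pi_ in seq_along(perms)) {
    ord <- perms[[pi_]]
    prev_af <- 0
    for (step in seq_len(k)) {
      s <- ord[seq_len(step)]
      af_s <- attributable_fraction(O, E_of(s)) - base_af
      per_perm[pi_, ord[step]] <- af_s - prev_af
      prev_af <- af_s
    }
  }
  averaged <- colMeans(per_perm)

  subsets <- list()
  for (f in factor_names) subsets[[subset_key(f)]] <- f
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      subsets[[subset_key(c(factor_names[i], factor_names[j]))]] <-
        c(factor_names[i], factor_names[j])
  subsets[[subset_key(factor_names)]] <- factor_names
  combined <- vapply(subsets, function(s)
    attributable_fraction(O, E_of(s)) - base_af, numeric(1))

  expected <- vapply(ls(E_cache), function(key) E_cache[[key]], numeric(1))
  structure(list(factors = factor_names, observed = O,
                 expected = expected, combined = combined,
                 per_permutation = per_perm, averaged = averaged,
                 scaling = scaling,
                 r2 = if (scaling != "none")
                   explained_variation(posterior, design) else NULL),
            class = "af_report")
}

#' Tabulate an AF report in percent
#'
#' @param report an `af_report`.
#' @return data frame `predictors`, `af_pct` (rounded to 2 decimals),
#'   singletons first, then pairs, then the full set.
#' @export
af_table <- function(report) {
  nm <- names(report$combined)
  size <- lengths(strsplit(nm, "+", fixed = TRUE))
  af <- ifelse(size == 1, report$averaged[nm], report$combined[nm])
  ord <- order(size)
  data.frame(predictors = nm[ord],
             af_pct = round(100 * unname(af[ord]), 2),
             stringsAsFactors = FALSE)
}
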