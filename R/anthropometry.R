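# LMS growth z-scores, undernutrition classification and descriptive
# prevalence tables.

#' LMS z-score transform
#'
#' Converts a measurement into a z-score relative to an LMS growth
#' reference point: `z = ((x/M)^L - 1)/(L*S)` for `L != 0` and
#' `z = log(x/M)/S` for `L = 0`.  With `tail_adjust = TRUE`, z-scores
#' beyond +/-3 are rescaled onto the restricted scale used with growth
#' standards: `z = 3 + (x - sd3)/(sd3 - sd2)` above +3 and symmetrically
#' below -3, where `sd_k` is the reference value at z-score `k`.
#'
#' @param measure positive measurement (vectorised).
#' @param L,M,S LMS parameters (vectorised; `M > 0`, `S > 0`).
#' @param tail_adjust apply the restricted rescaling beyond |z| = 3.
#' @return numeric z-score vector.
#' @export
lms_zscore <- function(measure, L, M, S, tail_adjust = FALSE) {
  if (any(!is.finite(measure)) || any(measure <= 0))
    stop("measure must be positive and finite")
  stopifnot(all(M > 0), all(S > 0))
  n <- max(length(measure), length(L), length(M), length(S))
  measure <- rep_len(measure, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  # |L| below 1e-5 uses the log (L = 0) branch: the two expressions agree
  # to O(L * z^2 * S) there and the switch keeps the transform continuous
  near0 <- abs(L) < 1e-5
  z <- ifelse(near0,
              log(measure / M) / S,
              ((measure / M)^ifelse(near0, 1, L) - 1) /
                (ifelse(near0, 1, L) * S))
  if (tail_adjust) {
    sd_at <- function(k) ifelse(L == 0, M * exp(S * k), M * (1 + L * S * k)^(1 / L))
    hi <- is.finite(z) & z > 3
    if (any(hi)) {
      sd3 <- sd_at(3); sd2 <- sd_at(2)
      z[hi] <- 3 + (measure[hi] - sd3[hi]) / (sd3[hi] - sd2[hi])
    }
    lo <- is.finite(z) & z < -3
    if (any(lo)) {
      sd3n <- sd_at(-3); sd2n <- sd_at(-2)
      z[lo] <- -3 + (measure[lo] - sd3n[lo]) / (sd2n[lo] - sd3n[lo])
    }
  }
  z
}

#' Invert the LMS transform
#'
#' Returns the measurement with z-score `z` at reference point `(L, M, S)`
#' (no tail adjustment).  Used by the synthetic generator to produce raw
#' anthropometry consistent with simulated z-scores.
#'
#' @inheritParams lms_zscore
#' @param z z-score vector.
#' @return measurement vector.
#' @export
lms_inverse <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  near0 <- abs(L) < 1e-5
  ifelse(near0, M * exp(S * z),
         M * (1 + ifelse(near0, 1, L) * S * z)^(1 / ifelse(near0, 1, L)))
}

#' Read an LMS reference table
#'
#' Expects CSV columns `indicator` (`wfh` weight-for-height or `hfa`
#' height-for-age), `sex` (`male`/`female`), `key` (height in cm for
#' `wfh`, age in months for `hfa`), `L`, `M`, `S`.  Keys must be strictly
#' increasing within each (indicator, sex) series.
#'
#' @param path CSV file path; default is the synthetic reference shipped
#'   with the package (a plausible but entirely artificial set of curves,
#'   for offline testing -- not the WHO 2006 standard).
#' @return data frame of class `lms_reference`.
#' @export
read_lms_reference <- function(path = system.file("extdata", "lms_synthetic.csv",
                                                  package = "conflictnutr")) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("indicator", "sex", "key", "L", "M", "S")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("LMS reference missing column(s): ", paste(miss, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0)) stop("LMS reference requires M > 0 and S > 0")
  for (grp in split(ref, list(ref$indicator, ref$sex), drop = TRUE))
    if (is.unsorted(grp$key, strictly = TRUE))
      stop("LMS keys must be strictly increasing within each (indicator, sex) series")
  class(ref) <- c("lms_reference", class(ref))
  ref
}

#' Interpolate LMS parameters at arbitrary keys
#'
#' Linear interpolation in the key (height or age) within one
#' (indicator, sex) series; keys outside the reference range are an error.
#'
#' @param ref an `lms_reference` from [read_lms_reference()].
#' @param indicator `"wfh"` or `"hfa"`.
#' @param sex `"male"` or `"female"` (vectorised).
#' @param key numeric keys (vectorised).
#' @return data frame with columns `L`, `M`, `S`.
#' @export
lms_lookup <- function(ref, indicator, sex, key) {
  n <- max(length(sex), length(key))
  sex <- rep_len(sex, n); key <- rep_len(key, n)
  out <- data.frame(L = numeric(n), M = numeric(n), S = numeric(n))
  for (sx in unique(sex)) {
    sel <- ref$indicator == indicator & ref$sex == sx
    if (!any(sel)) stop("no LMS series for indicator=", indicator, " sex=", sx)
    grp <- ref[sel, ]
    i <- sex == sx
    if (any(key[i] < min(grp$key) | key[i] > max(grp$key)))
      stop("key outside LMS reference range for ", indicator, "/", sx)
    out$L[i] <- stats::approx(grp$key, grp$L, xout = key[i])$y
    out$M[i] <- stats::approx(grp$key, grp$M, xout = key[i])$y
    out$S[i] <- stats::approx(grp$key, grp$S, xout = key[i])$y
  }
  out
}

#' Classify undernutrition from z-scores
#'
#' Outcome 1 iff `z < cutoff` (strictly below; the conventional case
#' definition is z-score below -2).  Missing z-scores yield missing
#' outcomes, to be dropped downstream with a logged count.
#'
#' @param z z-score vector.
#' @param cutoff default `-2`.
#' @return integer vector in `{0, 1, NA}`.
#' @export
classify_undernutrition <- function(z, cutoff = -2) {
  ifelse(is.na(z), NA_integer_, as.integer(z < cutoff))
}

#' Prevalence table by group
#'
#' Per-group child counts, case counts and percentages (2 decimals), plus
#' a totals row.  Empty groups report a count of 0 and a blank (NA)
#' percentage rather than 0.
#'
#' @param dataset data frame with an outcome column and a grouping column.
#' @param group name of the grouping column (e.g. `"region_id"`).
#' @param outcome name of the binary outcome column.
#' @return data frame with `group`, `n`, `cases`, `pct`.
#' @export
prevalence_table <- function(dataset, group, outcome) {
  stopifnot(group %in% names(dataset), outcome %in% names(dataset))
  g <- dataset[[group]]
  if (!is.factor(g)) g <- factor(g)   # keep caller-declared empty levels
  y <- dataset[[outcome]]
  keep <- !is.na(y)
  n <- tapply(keep, g, sum, default = 0L)
  cases <- tapply(ifelse(keep, y, 0L), g, sum, default = 0L)
  pct <- ifelse(n > 0, round(100 * cases / n, 2), NA_real_)
  out <- data.frame(group = names(n), n = as.integer(n),
                    cases = as.integer(cases), pct = as.numeric(pct),
                    stringsAsFactors = FALSE)
  tot <- data.frame(group = "Total", n = sum(out$n), cases = sum(out$cases),
                    pct = if (sum(out$n) > 0) round(100 * sum(out$cases) / sum(out$n), 2) else NA_real_)
  rbind(out, tot)
}

#' Totals of a pre-aggregated per-region summary table
#'
#' Sums already-aggregated per-region counts (children examined, clusters,
#' cases) into the totals row of a survey-summary table, for checking a
#' published table's arithmetic or summarising a run.
#'
#' @param region_table data frame with numeric columns to total; any
#'   non-numeric columns are ignored.
#' @return named numeric vector of column sums.
#' @export
summarize_region_counts <- function(region_table) {
  num <- vapply(region_table, is.numeric, logical(1))
  colSums(region_table[, num, drop = FALSE])
}
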