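# Model design: covariate assembly, standardisation, interaction columns
# and collinearity screening.

#' Pairwise collinearity screen
#'
#' Computes all pairwise Pearson correlations among numeric columns and
#' flags pairs at or above the threshold (default 0.6, the conventional
#' cut below which all predictors are retained).  Flagging warns; it does
#' not abort.  Constant columns have undefined correlations and are
#' reported separately.
#'
#' @param x numeric data frame or matrix of covariates.
#' @param threshold absolute-correlation flag threshold.
#' @return list: `cor` (matrix), `flagged` (data frame `var1`, `var2`,
#'   `r`), `constant` (column names with zero variance).
#' @export
screen_collinearity <- function(x, threshold = 0.6) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[, num, drop = FALSE]
  if (ncol(x) < 2) stop("need at least two numeric columns")
  sds <- vapply(x, stats::sd, numeric(1))
  constant <- names(x)[sds == 0 | is.na(sds)]
  keep <- setdiff(names(x), constant)
  cm <- stats::cor(x[, keep, drop = FALSE])
  pairs <- which(abs(cm) >= threshold & upper.tri(cm), arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(cm)[pairs[, 1]],
                        var2 = colnames(cm)[pairs[, 2]],
                        r = cm[pairs], stringsAsFactors = FALSE)
  if (nrow(flagged))
    warning(nrow(flagged), " covariate pair(s) with |r| >= ", threshold,
            "; fitting proceeds")
  list(cor = cm, flagged = flagged, constant = constant)
}

design_interaction_pairs <- function() {
  list(c("conflict_recent", "carbohydrate"),
       c("conflict_recent", "protein"),
       c("conflict_recent", "evi"),
       c("conflict_recent", "rainfall"),
       c("conflict_longer", "carbohydrate"),
       c("conflict_longer", "protein"),
       c("conflict_longer", "evi"),
       c("conflict_longer", "rainfall"),
       c("carbohydrate", "evi"),
       c("carbohydrate", "rainfall"),
       c("protein", "evi"),
       c("protein", "rainfall"),
       c("evi", "temperature"))
}

#' Build the regression design
#'
#' Assembles the covariate block from survey records, the exposure matrix
#' and per-cluster seasonal environmental covariates.  Indicator groups
#' use stated reference levels (livelihood: agro-pastoral; season: Deyr;
#' age: under 12 months).  Continuous covariates are standardised (mean
#' 0, sd 1) with the transform recorded for back-reporting.  Variant A
#' has no conflict columns; variant B adds the recent and longer-term
#' exposure indicators and the interaction set (products of mean-centred
#' parents).  Records with a missing model covariate or outcome are
#' dropped with a logged count; constant columns are dropped with a
#' warning.
#'
#' @param dataset validated survey data frame.
#' @param exposure exposure matrix from [build_exposure_matrix()].
#' @param geography cluster geography with seasonal covariate columns.
#' @param variant `"A"` (no conflict) or `"B"` (with conflict).
#' @param outcome name of the binary outcome column in `dataset` (e.g.
#'   `"wasted"`); optional, but required for fitting.
#' @param standardize standardise continuous covariates (default TRUE).
#' @param keep_constant keep structurally constant columns instead of
#'   dropping them (used by the synthetic generator so truth
#'   coefficients always find their column).
#' @return list of class `cn_design`: `y`, `X` (with intercept),
#'   `cluster`/`district`/`round` index vectors, id/date lookups, column
#'   `meta`data (kind, centring and scaling constants, interaction
#'   parents), `raw` parent values for counterfactuals, `n_dropped`.
#' @export
build_design <- function(dataset, exposure, geography,
                         variant = c("B", "A"), outcome = NULL,
                         standardize = TRUE, keep_constant = FALSE) {
  variant <- match.arg(variant)
  df <- dataset
  n0 <- nrow(df)

  # exposure join on (cluster_id, survey_date)
  key <- paste(df$cluster_id, as.Date(df$survey_date))
  ekey <- paste(exposure$cluster_id, as.Date(exposure$survey_date))
  ei <- match(key, ekey)
  if (anyNA(ei)) stop("record(s) with no exposure entry for their (cluster, survey date)")
  df$conflict_recent <- exposure$recent_any[ei]
  df$conflict_longer <- exposure$longer_any[ei]

  # seasonal environmental covariates joined from geography
  gi <- match(df$cluster_id, geography$cluster_id)
  if (anyNA(gi)) stop("record(s) with cluster_id absent from geography")
  seas <- season_of(df$survey_date)
  pick_seasonal <- function(var) {
    out <- numeric(nrow(df))
    for (s in unique(seas)) {
      col <- paste0(var, "_", s)
      if (!col %in% names(geography)) stop("geography lacks column ", col)
      out[seas == s] <- geography[[col]][gi[seas == s]]
    }
    out
  }
  df$evi <- pick_seasonal("evi")
  df$rainfall <- pick_seasonal("rainfall")
  df$temperature <- pick_seasonal("temperature")
  df$distance_to_water <- geography$distance_to_water[gi]
  df$urbanisation <- geography$urbanisation[gi]

  binary_cols <- c("vitamin_a", "measles_vax", "polio_vax", "diarrhoea",
                   "ari", "fever", "suspected_measles", "female_head",
                   "carbohydrate", "protein", "fats", "fruits_veg",
                   "urbanisation")
  cont_cols <- c("household_size", "n_under5", "mother_age", "mother_muac",
                 "distance_to_water", "evi", "rainfall", "temperature")

  df$sex_female <- as.integer(df$sex == "female")
  df$age_12_23 <- as.integer(df$age_months >= 12 & df$age_months < 24)
  df$age_24_59 <- as.integer(df$age_months >= 24)
  for (lv in setdiff(livelihood_levels(), "agro-pastoral"))
    df[[paste0("livelihood_", lv)]] <- as.integer(df$livelihood == lv)
  for (s in setdiff(season_levels(), "Deyr"))
    df[[paste0("season_", s)]] <- as.integer(seas == s)

  model_cols <- c("conflict_recent", "conflict_longer",
                  paste0("livelihood_", setdiff(livelihood_levels(), "agro-pastoral")),
                  binary_cols[1:7], "sex_female", "age_12_23", "age_24_59",
                  cont_cols[1:4], "female_head",
                  "carbohydrate", "protein", "fats", "fruits_veg",
                  paste0("season_", setdiff(season_levels(), "Deyr")),
                  "distance_to_water", "evi", "rainfall", "temperature",
                  "urbanisation")
  model_cols <- unique(model_cols)
  if (variant == "A")
    model_cols <- setdiff(model_cols, c("conflict_recent", "conflict_longer"))

  need <- c(model_cols, if (!is.null(outcome)) outcome)
  complete <- stats::complete.cases(df[, need, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped) message("build_design: dropping ", n_dropped,
                         " record(s) with missing covariates or outcome")
  df <- df[complete, , drop = FALSE]
  if (!nrow(df)) stop("no complete records left for the design")

  X <- cbind(intercept = rep(1, nrow(df)))
  meta <- list(intercept = list(kind = "intercept"))
  raw <- list()
  for (col in model_cols) {
    v <- as.numeric(df[[col]])
    raw[[col]] <- v
    if (standardize && col %in% cont_cols) {
      m <- mean(v); s <- stats::sd(v)
      if (s == 0 && !keep_constant) { meta[[col]] <- list(kind = "constant"); next }
      if (s == 0) s <- 1
      X <- cbind(X, (v - m) / s)
      meta[[col]] <- list(kind = "continuous", center = m, scale = s)
    } else {
      if (stats::sd(v) == 0 && !keep_constant) {
        meta[[col]] <- list(kind = "constant"); next
      }
      X <- cbind(X, v)
      meta[[col]] <- list(kind = if (col %in% c(binary_cols, "sex_female",
                                                "age_12_23", "age_24_59",
                                                "conflict_recent", "conflict_longer") ||
                                     grepl("^(livelihood|season)_", col))
                            "binary" else "continuous",
                          center = 0, scale = 1)
    }
    colnames(X)[ncol(X)] <- col
  }
  dropped_const <- names(meta)[vapply(meta, function(m) m$kind == "constant", logical(1))]
  if (length(dropped_const))
    message("build_design: dropping constant column(s): ",
            paste(dropped_const, collapse = ", "))

  if (variant == "B") {
    for (pr in design_interaction_pairs()) {
      if (!all(pr %in% colnames(X))) next   # parent dropped as constant
      nm <- paste(pr, collapse = ":")
      m1 <- mean(X[, pr[1]]); m2 <- mean(X[, pr[2]])
      X <- cbind(X, (X[, pr[1]] - m1) * (X[, pr[2]] - m2))
      colnames(X)[ncol(X)] <- nm
      meta[[nm]] <- list(kind = "interaction", parents = pr,
                         parent_means = c(m1, m2))
    }
  }

  cluster_ids <- geography$cluster_id
  district_ids <- sort(unique(geography$district_id))
  round_dates <- sort(unique(as.Date(df$survey_date)))
  structure(list(
    y = if (!is.null(outcome)) as.integer(df[[outcome]]) else NULL,
    X = X,
    cluster = match(df$cluster_id, cluster_ids),
    district = match(df$district_id, district_ids),
    round = match(as.Date(df$survey_date), round_dates),
    cluster_ids = cluster_ids, district_ids = district_ids,
    round_dates = round_dates,
    meta = meta[!vapply(meta, function(m) m$kind == "constant", logical(1))],
    raw = as.data.frame(raw),
    variant = variant, outcome = outcome, n_dropped = n_dropped,
    data = df[, c("child_id", "cluster_id", "district_id", "survey_date")]),
    class = "cn_design")
}
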