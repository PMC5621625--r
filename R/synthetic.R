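# Synthetic-data generator: geography with adjacency, seasonal conflict
# event streams, spatially smooth environmental fields, and child survey
# records whose outcomes are drawn from the hierarchical logistic model
# with known parameters.

#' Default truth parameters for the synthetic generator
#'
#' Fixed-effect coefficients on the log-odds scale for every design
#' column, plus random-effect precisions and conflict-process intensities.
#' Main-effect defaults are the published adjusted odds ratios for the
#' conflict-adjusted model (recent conflict OR 1.37 wasting / 1.21
#' stunting; longer-term 1.76 / 1.88; etc.); interaction coefficients
#' default to zero because the printed interaction ORs are on a raw
#' measurement scale the generator does not reproduce.  The intercept is
#' the logit of the observed national prevalence (21% wasting, 31%
#' stunting).
#'
#' @param outcome `"wasting"` or `"stunting"`.
#' @param overrides named numeric vector replacing or adding coefficients.
#' @return list of class `truth_params`: `outcome`, `beta` (named),
#'   `tau_u`, `tau_v`, `tau_d`, `tau_w`, `conflict_base_rate` (events per
#'   district-month), `season_multipliers`, `class_mix`.
#' @export
truth_params <- function(outcome = c("wasting", "stunting"), overrides = NULL) {
  outcome <- match.arg(outcome)
  or_w <- c(conflict_recent = 1.37, conflict_longer = 1.76,
            livelihood_pastoral = 0.93, livelihood_riverine = 1.17,
            livelihood_urban = 0.98, livelihood_idp = 1.62,
            vitamin_a = 0.89, measles_vax = 0.86, polio_vax = 0.96,
            diarrhoea = 1.37, ari = 1.27, fever = 1.28,
            suspected_measles = 1.13, sex_female = 0.72,
            age_12_23 = 0.57, age_24_59 = 0.69,
            household_size = 1.10, n_under5 = 1.03, female_head = 1.08,
            mother_age = 1.04, mother_muac = 0.89,
            carbohydrate = 0.89, protein = 0.87, fats = 0.96,
            fruits_veg = 0.94,
            season_Jilal = 1.33, season_Gu = 0.81, season_Hagaa = 1.11,
            distance_to_water = 1.00, evi = 0.39, rainfall = 0.83,
            temperature = 1.12, urbanisation = 0.82)
  or_s <- c(conflict_recent = 1.21, conflict_longer = 1.88,
            livelihood_pastoral = 0.60, livelihood_riverine = 1.50,
            livelihood_urban = 0.83, livelihood_idp = 2.23,
            vitamin_a = 0.90, measles_vax = 0.88, polio_vax = 0.95,
            diarrhoea = 1.42, ari = 1.13, fever = 1.16,
            suspected_measles = 1.02, sex_female = 0.75,
            age_12_23 = 3.36, age_24_59 = 2.34,
            household_size = 1.04, n_under5 = 1.03, female_head = 1.22,
            mother_age = 1.00, mother_muac = 0.97,
            carbohydrate = 0.95, protein = 0.94, fats = 0.95,
            fruits_veg = 0.98,
            season_Jilal = 1.10, season_Gu = 0.92, season_Hagaa = 1.09,
            distance_to_water = 1.00, evi = 0.40, rainfall = 0.86,
            temperature = 1.32, urbanisation = 0.91)
  ors <- if (outcome == "wasting") or_w else or_s
  beta <- c(intercept = stats::qlogis(if (outcome == "wasting") 0.21 else 0.31),
            log(ors))
  if (!is.null(overrides)) {
    stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
    beta[names(overrides)] <- overrides
  }
  structure(list(outcome = outcome, beta = beta,
                 tau_u = 4, tau_v = 16, tau_d = 16, tau_w = 100,
                 conflict_base_rate = 0.5, district_dispersion = 0.35,
                 season_multipliers = c(Jilal = 1.3, Gu = 0.7,
                                        Hagaa = 1.1, Deyr = 0.9),
                 class_mix = c(battle = 0.54, remote_violence = 0.08,
                               violence_against_civilians = 0.28,
                               other = 0.10)),
            class = "truth_params")
}

# smooth spatial field on points (lon, lat): low-rank random cosine basis
smooth_field <- function(lon, lat, n_basis = 12, length_scale = NULL) {
  if (is.null(length_scale))
    length_scale <- max(diff(range(lon)), diff(range(lat)), 1e-6) / 2
  w <- matrix(stats::rnorm(2 * n_basis, sd = 1 / length_scale), n_basis, 2)
  phi <- stats::runif(n_basis, 0, 2 * pi)
  amp <- stats::rnorm(n_basis)
  f <- numeric(length(lon))
  for (j in seq_len(n_basis))
    f <- f + amp[j] * cos(w[j, 1] * lon + w[j, 2] * lat + phi[j])
  as.vector(scale(f)) * 1  # unit-sd smooth field
}

#' Generate synthetic cluster geography with adjacency
#'
#' Lays districts on a grid, scatters jittered clusters within each,
#' links each cluster to its `k` nearest neighbours (symmetrised), and
#' draws per-season environmental covariates as spatially smooth fields.
#'
#' @param n_districts,clusters_per_district counts (>= 1).
#' @param seed integer RNG seed.
#' @param k_neighbors nearest-neighbour count for the adjacency rule.
#' @return list with `geography` (data frame) and `adjacency`.
#' @export
generate_geography <- function(n_districts, clusters_per_district, seed,
                               k_neighbors = 4) {
  stopifnot(n_districts >= 1, clusters_per_district >= 1)
  n <- n_districts * clusters_per_district
  if (n == 1L) stop("a single cluster has no adjacency; ICAR undefined on one node")
  set.seed(as.integer(seed))
  ncol_d <- ceiling(sqrt(n_districts))
  dx <- ((seq_len(n_districts) - 1) %% ncol_d)
  dy <- ((seq_len(n_districts) - 1) %/% ncol_d)
  cluster_id <- sprintf("c%04d", seq_len(n))
  district <- rep(seq_len(n_districts), each = clusters_per_district)
  lon <- 43 + dx[district] + stats::runif(n)      # degrees, Somalia-like box
  lat <- 2 + dy[district] + stats::runif(n)
  region <- (district - 1) %/% 2 + 1              # two districts per region

  # k-nearest-neighbour adjacency, symmetrised
  dmat <- as.matrix(stats::dist(cbind(lon, lat)))
  diag(dmat) <- Inf
  k <- min(k_neighbors, n - 1)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[seq_len(k)]
    from <- c(from, rep(i, k)); to <- c(to, nb)
  }
  adj <- make_adjacency(cluster_id[from], cluster_id[to], ids = cluster_id)

  geo <- data.frame(cluster_id = cluster_id,
                    district_id = sprintf("d%03d", district),
                    region_id = sprintf("r%03d", region),
                    lon = lon, lat = lat,
                    livelihood = sample(livelihood_levels(), n, replace = TRUE,
                                        prob = c(0.42, 0.27, 0.16, 0.04, 0.11)),
                    distance_to_water = abs(5 * smooth_field(lon, lat)) + 0.5,
                    urbanisation = stats::rbinom(n, 1, 0.15),
                    stringsAsFactors = FALSE)
  # seasonal fields: shared smooth base plus seasonal offsets
  rain_base <- smooth_field(lon, lat)
  evi_base <- smooth_field(lon, lat)
  temp_base <- smooth_field(lon, lat)
  rain_season <- c(Deyr = 60, Jilal = 10, Gu = 110, Hagaa = 25)   # mm/month
  temp_season <- c(Deyr = 27, Jilal = 30, Gu = 28, Hagaa = 29)    # deg C
  evi_season <- c(Deyr = 0.25, Jilal = 0.12, Gu = 0.35, Hagaa = 0.18)
  for (s in season_levels()) {
    geo[[paste0("rainfall_", s)]] <- pmax(0, rain_season[[s]] * (1 + 0.4 * rain_base))
    geo[[paste0("evi_", s)]] <- stats::plogis(stats::qlogis(evi_season[[s]]) + 0.8 * evi_base)
    geo[[paste0("temperature_", s)]] <- temp_season[[s]] + 2 * temp_base
  }
  list(geography = geo, adjacency = adj)
}

#' Simulate a seasonal conflict event stream
#'
#' District-month event counts are Poisson with rate
#' `base_rate * district_multiplier * season_multiplier`.  The district
#' multipliers are Gamma(`district_dispersion`, `district_dispersion`)
#' draws (mean 1): observed conflict-event tables are strongly
#' concentrated in hotspot districts, and this heterogeneity is what
#' leaves a realistic share of district-windows with zero events.  Each
#' event gets a uniform day within the month, a class from the stated
#' mixture (54% battle, 8% remote violence, 28% violence against
#' civilians, 10% other), a concrete ACLED label within the class, and
#' the location of a random cluster of the district (jittered).
#'
#' @param geography geography data frame from [generate_geography()].
#' @param truth `truth_params` (intensities and class mix).
#' @param start_date,end_date study window (`Date` or ISO strings).
#' @param seed integer RNG seed.
#' @return event data frame (same schema as [read_conflict_events()]).
#' @export
simulate_conflict_events <- function(geography, truth, start_date, end_date, seed) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("end_date before start_date")
  set.seed(as.integer(seed))
  months <- seq(as.Date(format(start_date, "%Y-%m-01")), end_date, by = "month")
  districts <- unique(geography$district_id)
  class_labels <- list(
    battle = c("battle - no change of territory",
               "battle - non-state actor overtakes territory",
               "battle - government regains territory"),
    remote_violence = "remote violence",
    violence_against_civilians = "violence against civilians",
    other = c("headquarters or base established", "strategic development",
              "riots or protests", "non-violent transfer of territory"))
  disp <- if (is.null(truth$district_dispersion)) Inf else truth$district_dispersion
  dist_mult <- if (is.finite(disp))
    stats::setNames(stats::rgamma(length(districts), disp, disp), districts)
  else stats::setNames(rep(1, length(districts)), districts)
  rows <- list()
  for (d in districts) {
    clus <- geography[geography$district_id == d, ]
    for (m in seq_along(months)) {
      m0 <- months[m]
      mdays <- as.integer(seq(m0, by = "month", length.out = 2)[2] - m0)
      lambda <- truth$conflict_base_rate * dist_mult[[d]] *
        truth$season_multipliers[[season_of(m0)]]
      nev <- stats::rpois(1, lambda)
      if (nev == 0) next
      day <- m0 + sample.int(mdays, nev, replace = TRUE) - 1L
      keep <- day >= start_date & day <= end_date
      if (!any(keep)) next
      day <- day[keep]; nev <- length(day)
      cls <- sample(names(truth$class_mix), nev, replace = TRUE,
                    prob = truth$class_mix)
      typ <- vapply(cls, function(cl) {
        labs <- class_labels[[cl]]
        labs[sample.int(length(labs), 1)]
      }, character(1))
      ci <- sample.int(nrow(clus), nev, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        event_date = day, district_id = d,
        region_id = clus$region_id[1],
        lon = clus$lon[ci] + stats::runif(nev, -0.05, 0.05),
        lat = clus$lat[ci] + stats::runif(nev, -0.05, 0.05),
        acled_type = unname(typ), fatalities = stats::rpois(nev, 1.5),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    ev <- data.frame(event_id = character(0), event_date = as.Date(character(0)),
                     district_id = character(0), region_id = character(0),
                     lon = numeric(0), lat = numeric(0),
                     acled_type = character(0), fatalities = integer(0))
    return(ev)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$event_date, ev$district_id), ]
  ev <- cbind(event_id = sprintf("e%05d", seq_len(nrow(ev))), ev)
  rownames(ev) <- NULL
  attr(ev, "district_multipliers") <- dist_mult
  ev
}

# draw z-scores consistent with a binary outcome at the -2 cutoff, from a
# truncated N(mu, sd) marginal, clipped for LMS invertibility
draw_consistent_z <- function(y, mu = -0.8, sd = 1.1, cutoff = -2) {
  p0 <- stats::pnorm(cutoff, mu, sd)
  u <- stats::runif(length(y))
  z <- ifelse(y == 1,
              stats::qnorm(u * p0, mu, sd),
              stats::qnorm(p0 + u * (1 - p0), mu, sd))
  pmin(pmax(z, -4.9), 4.9)
}

#' Simulate a child survey dataset from the hierarchical logistic model
#'
#' Children are allocated to clusters multinomially with equal cluster
#' probabilities and to survey rounds uniformly; child and household
#' covariates are drawn from fixed marginals; conflict exposure is
#' computed from `events` through [build_exposure_matrix()] (the same
#' code path the analysis uses); cluster effects are a BYM convolution
#' (ICAR `u` plus iid `v`), rounds follow a first-order random walk `w`,
#' districts are iid `d`; outcomes are Bernoulli with
#' `logit p = x'beta + u + v + w + d`.  Setting a precision to `Inf`
#' disables that random-effect block exactly, so with all precisions
#' infinite the generator reduces to a plain logistic model.
#'
#' @param geography,adjacency from [generate_geography()].
#' @param events conflict events (possibly empty) for exposure.
#' @param truth a `truth_params` object, or a named list of them (e.g.
#'   `list(wasting = ..., stunting = ...)`) sharing covariates and random
#'   effects draws per outcome.
#' @param n_children number of children.
#' @param survey_dates `Date` vector of survey rounds.
#' @param seed integer RNG seed.
#' @param lms optional `lms_reference` used to back-derive weight/height
#'   from simulated z-scores; defaults to the shipped synthetic reference.
#' @return list: `data` (survey data frame passing [validate_survey()]
#'   cleanly, with `wasted`/`whz` and/or `stunted`/`haz` columns),
#'   `exposure`, `latent` (per-outcome list of `u`, `v`, `d`, `w`,
#'   `linpred`, `prob`), `truth`.
#' @export
simulate_survey <- function(geography, adjacency, events, truth, n_children,
                            survey_dates, seed, lms = NULL) {
  set.seed(as.integer(seed))
  truths <- if (inherits(truth, "truth_params")) {
    stats::setNames(list(truth), truth$outcome)
  } else truth
  stopifnot(length(truths) >= 1, all(vapply(truths, inherits, logical(1), "truth_params")))
  survey_dates <- sort(as.Date(survey_dates))
  K <- nrow(geography); T <- length(survey_dates)
  D <- length(unique(geography$district_id))

  ci <- sample.int(K, n_children, replace = TRUE)   # equal-probability clusters
  ti <- sample.int(T, n_children, replace = TRUE)
  df <- data.frame(
    child_id = sprintf("k%06d", seq_len(n_children)),
    cluster_id = geography$cluster_id[ci],
    district_id = geography$district_id[ci],
    region_id = geography$region_id[ci],
    survey_date = survey_dates[ti],
    age_months = sample(6:59, n_children, replace = TRUE),
    sex = ifelse(stats::rbinom(n_children, 1, 0.47) == 1, "female", "male"),
    diarrhoea = stats::rbinom(n_children, 1, 0.15),
    ari = stats::rbinom(n_children, 1, 0.15),
    fever = stats::rbinom(n_children, 1, 0.15),
    suspected_measles = stats::rbinom(n_children, 1, 0.05),
    vitamin_a = stats::rbinom(n_children, 1, 0.6),
    measles_vax = stats::rbinom(n_children, 1, 0.6),
    polio_vax = stats::rbinom(n_children, 1, 0.7),
    household_size = 4L + stats::rpois(n_children, 2),
    n_under5 = 1L + stats::rbinom(n_children, 3, 0.3),
    female_head = stats::rbinom(n_children, 1, 0.3),
    mother_age = round(stats::runif(n_children, 16, 45)),
    mother_muac = round(pmax(18, stats::rnorm(n_children, 25, 2)), 1),
    carbohydrate = stats::rbinom(n_children, 1, 0.8),
    protein = stats::rbinom(n_children, 1, 0.5),
    fats = stats::rbinom(n_children, 1, 0.5),
    fruits_veg = stats::rbinom(n_children, 1, 0.4),
    livelihood = geography$livelihood[ci],
    stringsAsFactors = FALSE)

  survey_index <- expand.grid(cluster_id = geography$cluster_id,
                              survey_date = survey_dates,
                              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  exposure <- build_exposure_matrix(events, geography, survey_index)

  district_ids <- sort(unique(geography$district_id))
  latent <- list()
  for (nm in names(truths)) {
    tp <- truths[[nm]]
    u <- if (is.finite(tp$tau_u)) icar_sample(adjacency, tp$tau_u) else numeric(K)
    v <- if (is.finite(tp$tau_v)) stats::rnorm(K, 0, 1 / sqrt(tp$tau_v)) else numeric(K)
    d <- if (is.finite(tp$tau_d)) stats::rnorm(D, 0, 1 / sqrt(tp$tau_d)) else numeric(D)
    w <- if (is.finite(tp$tau_w) && T > 1) {
      w0 <- cumsum(c(0, stats::rnorm(T - 1, 0, 1 / sqrt(tp$tau_w))))
      w0 - mean(w0)
    } else numeric(T)

    design <- build_design(df, exposure, geography, variant = "B",
                           keep_constant = TRUE)
    beta <- numeric(ncol(design$X))
    names(beta) <- colnames(design$X)
    unknown <- setdiff(names(tp$beta), names(beta))
    if (length(unknown))
      stop("truth coefficient(s) with no matching design column: ",
           paste(unknown, collapse = ", "))
    beta[names(tp$beta)] <- tp$beta
    di <- match(df$district_id, district_ids)
    eta <- as.vector(design$X %*% beta) + u[ci] + v[ci] + w[ti] + d[di]
    p <- stats::plogis(eta)
    y <- stats::rbinom(n_children, 1, p)
    latent[[nm]] <- list(u = u, v = v, d = d, w = w, linpred = eta, prob = p, y = y)
  }

  if (is.null(lms)) lms <- read_lms_reference()
  if ("stunting" %in% names(latent)) {
    df$stunted <- latent$stunting$y
    df$haz <- round(draw_consistent_z(df$stunted), 3)
  }
  hfa <- lms_lookup(lms, "hfa", df$sex, df$age_months)
  haz_for_height <- if ("haz" %in% names(df)) df$haz else rep(0, n_children)
  df$height_cm <- round(lms_inverse(haz_for_height, hfa$L, hfa$M, hfa$S), 1)
  if ("wasting" %in% names(latent)) {
    df$wasted <- latent$wasting$y
    df$whz <- round(draw_consistent_z(df$wasted), 3)
    wfh <- lms_lookup(lms, "wfh", df$sex, df$height_cm)
    df$weight_kg <- round(lms_inverse(df$whz, wfh$L, wfh$M, wfh$S), 2)
  }
  list(data = df, exposure = exposure, latent = latent, truth = truths)
}

#' Moran's I spatial autocorrelation statistic
#'
#' Binary-weight Moran's I on an adjacency graph; used to check that
#' generated environmental fields are spatially smooth.
#'
#' @param x numeric vector over the graph's nodes.
#' @param adj adjacency object.
#' @return scalar Moran's I.
#' @export
moran_i <- function(x, adj) {
  z <- x - mean(x)
  num <- 2 * sum(z[adj$edges[, 1]] * z[adj$edges[, 2]])
  wsum <- 2 * nrow(adj$edges)
  (length(x) / wsum) * num / sum(z * z)
}
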