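# Conflict exposure construction: temporal windowing, spatial linkage and
# descriptive event tables.

#' Classify an event/survey date pair into an exposure window
#'
#' The day difference `delta = survey_date - event_date` determines the
#' window: `recent` for `delta` in `[0, 91)` (events within roughly three
#' months before the survey), `longer` for `[91, 366)` (three to twelve
#' months before), and `none` otherwise.  Months are operationalised as
#' day counts with half-open intervals so boundaries are unambiguous;
#' future events (`delta < 0`) are never exposure.
#'
#' @param event_date,survey_date `Date` vectors (recycled).
#' @param windows integer vector `c(recent_end, longer_end)` in days,
#'   default `c(91, 366)`.
#' @return character vector in `{"recent", "longer", "none"}`.
#' @export
window_exposure <- function(event_date, survey_date, windows = c(91L, 366L)) {
  stopifnot(length(windows) == 2L, windows[1] > 0, windows[2] > windows[1])
  delta <- as.numeric(as.Date(survey_date) - as.Date(event_date))
  out <- rep("none", length(delta))
  out[delta >= 0 & delta < windows[1]] <- "recent"
  out[delta >= windows[1] & delta < windows[2]] <- "longer"
  out
}

# great-circle distance in km between (lon1,lat1) and (lon2,lat2)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Build the per-(cluster, survey date) conflict exposure matrix
#'
#' Links each conflict event to clusters (same district by default, or all
#' clusters whose centroid lies within `buffer_km` of the event), windows
#' it against every survey date, and reduces to binary any-event
#' indicators plus event counts, overall and per conflict class.
#'
#' @param events data frame with `event_date`, `acled_type` and
#'   `district_id` and/or `lon`/`lat` columns (see
#'   [read_conflict_events()]).
#' @param geography cluster table with `cluster_id`, `district_id` and,
#'   for buffer linkage, `lon`/`lat` centroids.
#' @param survey_index data frame with `cluster_id` and `survey_date`
#'   giving the survey occasions to score; defaults to all clusters
#'   crossed with the unique survey dates found in `survey_dates`.
#' @param linkage `"district"` or `"buffer"`.
#' @param buffer_km radius in km for buffer linkage.
#' @param windows passed to [window_exposure()].
#' @param class_map passed to [classify_event_type()].
#' @return data frame with one row per (cluster_id, survey_date):
#'   `recent_any`, `longer_any` indicators, `recent_n`, `longer_n`
#'   counts, and per-class indicator columns `recent_<class>`,
#'   `longer_<class>`.
#' @export
build_exposure_matrix <- function(events, geography, survey_index,
                                  linkage = c("district", "buffer"),
                                  buffer_km = 25,
                                  windows = c(91L, 366L),
                                  class_map = default_class_map()) {
  linkage <- match.arg(linkage)
  stopifnot(all(c("cluster_id", "survey_date") %in% names(survey_index)))
  si <- unique(survey_index[, c("cluster_id", "survey_date")])
  si$survey_date <- as.Date(si$survey_date)
  classes <- conflict_classes()

  out <- si
  out$recent_any <- 0L; out$longer_any <- 0L
  out$recent_n <- 0L; out$longer_n <- 0L
  for (cl in classes) {
    out[[paste0("recent_", cl)]] <- 0L
    out[[paste0("longer_", cl)]] <- 0L
  }
  if (is.null(events) || nrow(events) == 0L) return(out)

  ev <- events
  ev$event_date <- as.Date(ev$event_date)
  ev$class <- classify_event_type(ev$acled_type, class_map)

  geo <- geography
  if (linkage == "district") {
    if (!all(c("cluster_id", "district_id") %in% names(geo)))
      stop("district linkage needs cluster_id and district_id in geography")
    if (!"district_id" %in% names(ev) || anyNA(ev$district_id))
      stop("district linkage needs a district_id on every event")
  } else {
    if (!all(c("lon", "lat") %in% names(geo)) || anyNA(geo$lon) || anyNA(geo$lat)) {
      bad <- if ("cluster_id" %in% names(geo))
        geo$cluster_id[!stats::complete.cases(geo[, intersect(c("lon", "lat"), names(geo))])]
      else "<all>"
      stop("buffer linkage needs centroids; missing for cluster(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (!all(c("lon", "lat") %in% names(ev)))
      stop("buffer linkage needs event coordinates")
  }

  geo_idx <- match(out$cluster_id, geo$cluster_id)
  if (anyNA(geo_idx)) stop("survey_index contains cluster_id absent from geography")

  for (e in seq_len(nrow(ev))) {
    linked <- if (linkage == "district")
      geo$district_id[geo_idx] == ev$district_id[e]
    else
      haversine_km(geo$lon[geo_idx], geo$lat[geo_idx],
                   ev$lon[e], ev$lat[e]) <= buffer_km
    if (!any(linked)) next
    win <- window_exposure(ev$event_date[e], out$survey_date, windows)
    for (w in c("recent", "longer")) {
      hit <- linked & win == w
      if (!any(hit)) next
      out[[paste0(w, "_any")]][hit] <- 1L
      out[[paste0(w, "_n")]][hit] <- out[[paste0(w, "_n")]][hit] + 1L
      col <- paste0(w, "_", ev$class[e])
      out[[col]][hit] <- 1L
    }
  }
  out
}

#' Expand a per-region class-count table into pseudo-events
#'
#' Turns a table with `region_id` (or `region`) and one count column per
#' conflict class into one pseudo-event row per counted event, using a
#' representative ACLED label per class, so re-entered published summary
#' counts can flow through [summarize_events()].
#'
#' @param counts data frame with a region column and columns named after
#'   [conflict_classes()].
#' @return event data frame with `region_id` and `acled_type`.
#' @export
expand_class_counts <- function(counts) {
  region_col <- intersect(c("region_id", "region"), names(counts))[1]
  if (is.na(region_col)) stop("counts need a region/region_id column")
  rep_label <- c(battle = "battle - no change of territory",
                 remote_violence = "remote violence",
                 violence_against_civilians = "violence against civilians",
                 other = "strategic development")
  rows <- list()
  for (cl in conflict_classes()) {
    if (!cl %in% names(counts)) stop("counts lack class column ", cl)
    n <- as.integer(counts[[cl]])
    rows[[cl]] <- data.frame(
      region_id = rep(as.character(counts[[region_col]]), n),
      acled_type = rep_label[[cl]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive conflict-event table by region and class
#'
#' Classifies events and tabulates counts per region and class with class
#' totals, a grand total, and integer-rounded class percentages.
#'
#' @param events event table with `acled_type` and either a `region_id`
#'   column or a `district_id` resolvable through `geography`.
#' @param geography optional cluster/district table with `district_id` and
#'   `region_id`, used to resolve regions when events carry only districts.
#' @param class_map passed to [classify_event_type()].
#' @return list with `by_region` (data frame region x class counts +
#'   `total`), `class_totals` (named vector), `class_pct` (named vector,
#'   rounded to nearest integer) and `grand_total`.
#' @export
summarize_events <- function(events, geography = NULL,
                             class_map = default_class_map()) {
  ev <- events
  ev$class <- classify_event_type(ev$acled_type, class_map)
  if (!"region_id" %in% names(ev)) {
    if (is.null(geography) || !all(c("district_id", "region_id") %in% names(geography)))
      stop("events lack region_id and geography cannot resolve it")
    lut <- unique(geography[, c("district_id", "region_id")])
    ev$region_id <- lut$region_id[match(ev$district_id, lut$district_id)]
  }
  classes <- conflict_classes()
  tab <- table(factor(ev$region_id), factor(ev$class, levels = classes))
  by_region <- as.data.frame.matrix(tab)
  by_region <- cbind(region_id = rownames(by_region), by_region,
                     total = rowSums(by_region))
  rownames(by_region) <- NULL
  class_totals <- colSums(tab)
  grand <- sum(class_totals)
  list(by_region = by_region,
       class_totals = class_totals,
       class_pct = round(100 * class_totals / grand),
       grand_total = grand)
}
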