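# Tabular readers/writers for survey records, conflict events, cluster
# geography and adjacency.  Dialect: comma-separated UTF-8 with a header
# row and ISO-8601 dates.  Invalid rows are quarantined with reasons, not
# silently dropped and not fatal.

livelihood_levels <- function() c("agro-pastoral", "pastoral", "riverine", "urban", "idp")

survey_binary_cols <- function() {
  c("diarrhoea", "ari", "fever", "suspected_measles",
    "vitamin_a", "measles_vax", "polio_vax", "female_head",
    "carbohydrate", "protein", "fats", "fruits_veg")
}

survey_mandatory_cols <- function() {
  c("child_id", "cluster_id", "district_id", "survey_date",
    "age_months", "sex", "livelihood")
}

survey_all_cols <- function() {
  c(survey_mandatory_cols(), "region_id", survey_binary_cols(),
    "household_size", "n_under5", "mother_age", "mother_muac",
    "weight_kg", "height_cm", "whz", "haz", "wasted", "stunted")
}

#' Read a child survey table
#'
#' Reads a CSV of child-level survey records, validates row invariants
#' (age 6-59 months, binary flags in {0,1}, known sex and livelihood,
#' parseable ISO date, some anthropometry present) and quarantines failing
#' rows with row numbers and reasons.  Unknown columns are ignored with a
#' warning; a missing mandatory column or an empty file is an error.
#'
#' @param path CSV file path.
#' @param require_anthropometry if `TRUE` (default) a row must carry `whz`
#'   or `haz` or both of `weight_kg`/`height_cm`.
#' @return list with `data` (valid rows, `survey_date` as `Date`) and
#'   `quarantine` (data frame `row`, `child_id`, `reason`).
#' @export
read_survey_table <- function(path, require_anthropometry = TRUE) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("survey file is empty: ", path)
  miss <- setdiff(survey_mandatory_cols(), names(df))
  if (length(miss)) stop("survey file missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  unknown <- setdiff(names(df), survey_all_cols())
  if (length(unknown)) {
    warning("ignoring unknown survey column(s): ", paste(unknown, collapse = ", "))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  validate_survey(df, require_anthropometry = require_anthropometry)
}

#' Validate an in-memory survey data frame
#' @inheritParams read_survey_table
#' @param df survey data frame with the columns of [read_survey_table()].
#' @return same structure as [read_survey_table()].
#' @export
validate_survey <- function(df, require_anthropometry = TRUE) {
  n <- nrow(df)
  reasons <- vector("list", n)
  add <- function(idx, why) for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)

  dates <- as.Date(as.character(df$survey_date), format = "%Y-%m-%d")
  add(is.na(dates), "unparseable survey_date")
  age <- suppressWarnings(as.numeric(df$age_months))
  add(is.na(age) | age < 6 | age > 59 | age != round(age), "age out of range")
  add(!(tolower(as.character(df$sex)) %in% c("male", "female")), "unknown sex")
  add(!(tolower(as.character(df$livelihood)) %in% livelihood_levels()),
      "unknown livelihood")
  for (col in intersect(survey_binary_cols(), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & (is.na(v) | !(v %in% c(0, 1)))
    add(bad, paste0("non-binary ", col))
  }
  for (col in intersect(c("weight_kg", "height_cm", "mother_muac"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    add(!is.na(df[[col]]) & (is.na(v) | v <= 0), paste0("non-positive ", col))
  }
  if (require_anthropometry) {
    has_whz <- "whz" %in% names(df) & if ("whz" %in% names(df)) !is.na(df$whz) else FALSE
    has_haz <- if ("haz" %in% names(df)) !is.na(df$haz) else rep(FALSE, n)
    has_wh <- if (all(c("weight_kg", "height_cm") %in% names(df)))
      !is.na(df$weight_kg) & !is.na(df$height_cm) else rep(FALSE, n)
    add(!(has_whz | has_haz | has_wh), "no anthropometry")
  }

  bad <- !vapply(reasons, is.null, logical(1))
  quarantine <- data.frame(
    row = which(bad),
    child_id = if (n) as.character(df$child_id[bad]) else character(0),
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE)
  data <- df[!bad, , drop = FALSE]
  if (nrow(data)) {
    data$survey_date <- as.Date(as.character(data$survey_date))
    data$sex <- tolower(as.character(data$sex))
    data$livelihood <- tolower(as.character(data$livelihood))
    rownames(data) <- NULL
  }
  list(data = data, quarantine = quarantine)
}

#' Write a survey table to CSV
#' @param data survey data frame.
#' @param path output path.
#' @export
write_survey_table <- function(data, path) {
  out <- data
  if ("survey_date" %in% names(out)) out$survey_date <- format(as.Date(out$survey_date))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a conflict event table
#'
#' Reads a CSV with columns `event_id`, `event_date`, `acled_type` and
#' location (`district_id` and/or `lon`/`lat`; optional `region_id`,
#' `fatalities`).  Event-type labels are normalised to the canonical
#' nine-label ACLED vocabulary; rows with unknown labels or unparseable
#' dates are quarantined with reasons.
#'
#' @param path CSV file path.
#' @return list with `data` and `quarantine` as in [read_survey_table()].
#' @export
read_conflict_events <- function(path) {
  if (!file.exists(path)) stop("conflict event file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_date", "acled_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("conflict file missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  reasons <- vector("list", n)
  add <- function(idx, why) for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)

  dates <- as.Date(as.character(df$event_date), format = "%Y-%m-%d")
  add(is.na(dates), "unparseable event_date")
  canon <- normalize_event_type(df$acled_type)
  add(is.na(canon), "unknown event type")
  if (!"district_id" %in% names(df) && !all(c("lon", "lat") %in% names(df)))
    stop("conflict file needs district_id and/or lon/lat columns")

  bad <- !vapply(reasons, is.null, logical(1))
  quarantine <- data.frame(
    row = which(bad),
    event_id = if ("event_id" %in% names(df)) as.character(df$event_id[bad])
               else as.character(which(bad)),
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE)
  data <- df[!bad, , drop = FALSE]
  if (nrow(data)) {
    data$event_date <- as.Date(as.character(data$event_date))
    data$acled_type <- normalize_event_type(data$acled_type)
    rownames(data) <- NULL
  }
  list(data = data, quarantine = quarantine)
}

#' Write a conflict event table to CSV
#' @param data event data frame.
#' @param path output path.
#' @export
write_conflict_events <- function(data, path) {
  out <- data
  if ("event_date" %in% names(out)) out$event_date <- format(as.Date(out$event_date))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read cluster geography
#'
#' CSV with `cluster_id`, `district_id`, `region_id`, `lon`, `lat`,
#' `livelihood` and per-season environmental columns named
#' `<covariate>_<season>` (e.g. `rainfall_Gu`), plus season-invariant
#' `distance_to_water` and `urbanisation`.
#'
#' @param path CSV file path.
#' @return validated geography data frame.
#' @export
read_geography <- function(path) {
  geo <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "district_id")
  miss <- setdiff(need, names(geo))
  if (length(miss)) stop("geography missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(geo$cluster_id)) stop("duplicate cluster_id in geography")
  geo
}

#' Read an adjacency edge list
#'
#' CSV with columns `from`, `to` holding cluster ids.  Edges are
#' symmetrised; self-loops are an error.
#'
#' @param path CSV file path.
#' @param cluster_ids optional vector of node ids to validate against.
#' @return adjacency list (see [make_adjacency()]).
#' @export
read_adjacency <- function(path, cluster_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(df)))
  make_adjacency(df$from, df$to, cluster_ids)
}

#' Write an adjacency edge list to CSV
#' @param adj adjacency object from [make_adjacency()].
#' @param path output path.
#' @export
write_adjacency <- function(adj, path) {
  e <- adj$edges
  utils::write.csv(data.frame(from = adj$ids[e[, 1]], to = adj$ids[e[, 2]]),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
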