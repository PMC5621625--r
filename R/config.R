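# Run configuration: defaults, a flat YAML-style key/value reader, and
# validation.  Every source of randomness flows from `seed`.

#' Default run configuration
#'
#' @return named list of all pipeline settings: synthetic-data scale,
#'   exposure windows and linkage, MCMC settings, hyperpriors,
#'   attribution options and output paths.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "artifacts",
    # synthetic data scale
    n_districts = 6L, clusters_per_district = 5L, n_children = 600L,
    # one round per season so the seasonal block is estimable
    survey_dates = c("2009-01-15", "2009-05-15", "2009-08-15", "2009-11-15"),
    conflict_start = "2008-01-01", conflict_end = "2010-12-31",
    # exposure
    windows = c(91L, 366L), linkage = "district", buffer_km = 25,
    # outcomes and classification
    outcomes = c("wasting", "stunting"), cutoff = -2,
    # MCMC
    chains = 2L, iter = 1500L, burnin = 500L, thin = 2L,
    beta_precision = 1e-4, tau_shape = 1, tau_rate = 5e-4,
    # attribution
    af_factors = c("recent", "longer", "evi"), af_scaling = "none",
    evi_quantile = 0.9, max_draws = 400L,
    # external inputs (NULL means: use the simulate stage's outputs)
    survey_file = NULL, events_file = NULL, geography_file = NULL,
    adjacency_file = NULL)
}

coerce_value <- function(v) {
  v <- trimws(v)
  if (grepl(",", v)) return(unname(vapply(strsplit(v, ",")[[1]],
                                          function(x) coerce_value(x), v)))
  if (tolower(v) %in% c("true", "yes")) return(TRUE)
  if (tolower(v) %in% c("false", "no")) return(FALSE)
  if (tolower(v) %in% c("null", "~", "")) return(NA)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num) && !grepl("^\\d{4}-\\d{2}-\\d{2}$", v)) return(num)
  gsub('^["\']|["\']$', "", v)
}

#' Read a run configuration file
#'
#' Flat YAML-style `key: value` text; `#` comments and blank lines are
#' ignored; comma-separated values become vectors; unknown keys warn.
#' Values merge over [default_config()].
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return validated config list.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      if (!grepl(":", ln)) stop("malformed config line: ", ln)
      key <- trimws(sub(":.*$", "", ln))
      val <- sub("^[^:]*:", "", ln)
      if (!key %in% names(cfg)) {
        warning("unknown config key ignored: ", key)
        next
      }
      cfg[[key]] <- coerce_value(val)
    }
  }
  if (!is.null(overrides)) for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  validate_config(cfg)
}

#' Validate a configuration list
#' @param cfg config list.
#' @return the config, invisibly amended (integer coercions applied).
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed must be explicit")
  cfg$seed <- as.integer(cfg$seed)
  w <- as.numeric(cfg$windows)
  if (length(w) != 2 || w[1] <= 0 || w[2] <= w[1])
    stop("windows must be two increasing positive day counts")
  if (as.numeric(cfg$iter) <= as.numeric(cfg$burnin))
    stop("iterations must exceed burn-in")
  for (k in c("n_districts", "clusters_per_district", "n_children",
              "chains", "iter", "burnin", "thin", "max_draws"))
    cfg[[k]] <- as.integer(cfg[[k]])
  if (!cfg$linkage %in% c("district", "buffer"))
    stop("linkage must be 'district' or 'buffer'")
  if (!all(cfg$outcomes %in% c("wasting", "stunting")))
    stop("outcomes must be wasting and/or stunting")
  cfg
}
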