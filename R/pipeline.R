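# End-to-end pipeline: simulate -> exposure -> fit -> af -> waic ->
# report.  Every artefact is plain text (CSV/JSON); a failing stage
# aborts with the stage name, keeping completed artefacts on disk.

outcome_col <- function(outcome) if (outcome == "wasting") "wasted" else "stunted"

#' Run the analysis pipeline
#'
#' Executes the requested stages in order against the configured inputs
#' (synthetic by default), writing all artefacts under `config$out_dir`:
#' simulated inputs plus `truth.json`, `exposure.csv`, per-outcome
#' odds-ratio tables and posterior draws, the attributable-fraction
#' report, the WAIC comparison, the observed-versus-fitted table and a
#' machine-readable `run_log.json` holding the seed and resolved
#' configuration.  Identical config and seed give byte-identical
#' numerical artefacts (no timestamps are written).
#'
#' @param config configuration list (see [read_run_config()]).
#' @param stages subset of
#'   `c("simulate", "exposure", "fit", "af", "waic", "report")`.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "exposure", "fit", "af",
                                    "waic", "report")) {
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  state <- list(cfg = cfg)
  run_stage <- function(name, fn) {
    if (!name %in% stages) return()
    state <<- tryCatch(fn(state),
                       error = function(e) stop("stage '", name, "' failed: ",
                                                conditionMessage(e), call. = FALSE))
  }
  run_stage("simulate", stage_simulate)
  run_stage("exposure", stage_exposure)
  run_stage("fit", stage_fit)
  run_stage("af", stage_af)
  run_stage("waic", stage_waic)
  run_stage("report", stage_report)
  jsonlite::write_json(list(seed = cfg$seed,
                            stages = stages,
                            config = cfg[!vapply(cfg, is.null, logical(1))]),
                       file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(state)
}

stage_simulate <- function(state) {
  cfg <- state$cfg; out <- cfg$out_dir
  gg <- generate_geography(cfg$n_districts, cfg$clusters_per_district,
                           seed = cfg$seed)
  truths <- list()
  for (oc in cfg$outcomes) truths[[oc]] <- truth_params(oc)
  events <- simulate_conflict_events(gg$geography, truths[[1]],
                                     cfg$conflict_start, cfg$conflict_end,
                                     seed = cfg$seed + 1L)
  sim <- simulate_survey(gg$geography, gg$adjacency, events, truths,
                         cfg$n_children, as.Date(cfg$survey_dates),
                         seed = cfg$seed + 2L)
  utils::write.csv(gg$geography, file.path(out, "geography.csv"), row.names = FALSE)
  write_adjacency(gg$adjacency, file.path(out, "adjacency.csv"))
  write_conflict_events(events, file.path(out, "events.csv"))
  write_survey_table(sim$data, file.path(out, "survey.csv"))
  jsonlite::write_json(
    lapply(truths, function(tp) list(outcome = tp$outcome,
                                     beta = as.list(tp$beta),
                                     tau_u = tp$tau_u, tau_v = tp$tau_v,
                                     tau_d = tp$tau_d, tau_w = tp$tau_w)),
    file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$geography <- gg$geography; state$adjacency <- gg$adjacency
  state$events <- events; state$survey <- sim$data
  state
}

load_inputs <- function(state) {
  cfg <- state$cfg; out <- cfg$out_dir
  pick <- function(slot, file, reader) {
    if (!is.null(state[[slot]])) return(state[[slot]])
    path <- if (!is.null(cfg[[file]]) && !is.na(cfg[[file]])) cfg[[file]]
            else file.path(out, sub("_file$", ".csv", file))
    reader(path)
  }
  state$geography <- pick("geography", "geography_file", read_geography)
  state$adjacency <- if (!is.null(state$adjacency)) state$adjacency else
    read_adjacency(if (!is.null(cfg$adjacency_file) && !is.na(cfg$adjacency_file))
                     cfg$adjacency_file else file.path(out, "adjacency.csv"),
                   state$geography$cluster_id)
  state$events <- pick("events", "events_file",
                       function(p) read_conflict_events(p)$data)
  state$survey <- pick("survey", "survey_file",
                       function(p) read_survey_table(p)$data)
  state
}

stage_exposure <- function(state) {
  state <- load_inputs(state)
  cfg <- state$cfg
  si <- unique(state$survey[, c("cluster_id", "survey_date")])
  # all clusters of every surveyed date, so designs never miss an entry
  si <- expand.grid(cluster_id = state$geography$cluster_id,
                    survey_date = unique(as.Date(si$survey_date)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  exp_m <- build_exposure_matrix(state$events, state$geography, si,
                                 linkage = cfg$linkage,
                                 buffer_km = as.numeric(cfg$buffer_km),
                                 windows = as.integer(cfg$windows))
  exp_out <- exp_m; exp_out$survey_date <- format(exp_out$survey_date)
  utils::write.csv(exp_out, file.path(cfg$out_dir, "exposure.csv"),
                   row.names = FALSE)
  state$exposure <- exp_m
  state
}

stage_fit <- function(state) {
  state <- load_inputs(state)
  cfg <- state$cfg
  if (is.null(state$exposure)) state <- stage_exposure(state)
  priors <- prior_spec(cfg$beta_precision, cfg$tau_shape, cfg$tau_rate)
  mc <- mcmc_control(cfg$chains, cfg$iter, cfg$burnin, cfg$thin)
  state$fits <- list()
  for (oc in cfg$outcomes) {
    ycol <- outcome_col(oc)
    if (!ycol %in% names(state$survey)) {
      zcol <- if (oc == "wasting") "whz" else "haz"
      state$survey[[ycol]] <- classify_undernutrition(state$survey[[zcol]],
                                                      as.numeric(cfg$cutoff))
    }
    for (variant in c("A", "B")) {
      design <- build_design(state$survey, state$exposure, state$geography,
                             variant = variant, outcome = ycol)
      fit <- fit_model(design, state$adjacency, priors, mc,
                       seed = cfg$seed + 10L)
      key <- paste0(oc, "_", variant)
      state$fits[[key]] <- list(design = design, posterior = fit)
      write_posterior(fit, file.path(cfg$out_dir, paste0("posterior_", key)))
      utils::write.csv(summarize_effects(fit),
                       file.path(cfg$out_dir, paste0("or_table_", key, ".csv")),
                       row.names = FALSE)
    }
  }
  state
}

stage_af <- function(state) {
  cfg <- state$cfg
  if (is.null(state$fits)) stop("fit stage has not run")
  afs <- list()
  for (oc in cfg$outcomes) {
    f <- state$fits[[paste0(oc, "_B")]]
    factors <- af_factors(f$design, evi_quantile = as.numeric(cfg$evi_quantile))
    rep <- sequential_af(f$posterior, f$design,
                         factor_names = intersect(cfg$af_factors, names(factors)),
                         factors = factors, scaling = cfg$af_scaling,
                         max_draws = cfg$max_draws)
    utils::write.csv(af_table(rep),
                     file.path(cfg$out_dir, paste0("af_report_", oc, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(observed = rep$observed,
                              expected = as.list(rep$expected),
                              averaged = as.list(rep$averaged),
                              combined = as.list(rep$combined),
                              per_permutation = rep$per_permutation,
                              scaling = rep$scaling),
                         file.path(cfg$out_dir, paste0("af_permutations_", oc, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    afs[[oc]] <- rep
  }
  state$af <- afs
  state
}

stage_waic <- function(state) {
  cfg <- state$cfg
  if (is.null(state$fits)) stop("fit stage has not run")
  res <- list()
  for (oc in cfg$outcomes) {
    wa <- waic(pointwise_loglik(state$fits[[paste0(oc, "_A")]]$posterior,
                                state$fits[[paste0(oc, "_A")]]$design,
                                max_draws = cfg$max_draws))
    wb <- waic(pointwise_loglik(state$fits[[paste0(oc, "_B")]]$posterior,
                                state$fits[[paste0(oc, "_B")]]$design,
                                max_draws = cfg$max_draws))
    res[[oc]] <- c(compare_waic(wa, wb),
                   list(lppd_a = wa$lppd, p_waic_a = wa$p_waic,
                        lppd_b = wb$lppd, p_waic_b = wb$p_waic))
  }
  jsonlite::write_json(res, file.path(cfg$out_dir, "waic.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$waic <- res
  state
}

stage_report <- function(state) {
  cfg <- state$cfg
  if (is.null(state$fits)) stop("fit stage has not run")
  for (oc in cfg$outcomes) {
    f <- state$fits[[paste0(oc, "_B")]]
    ovf <- observed_vs_fitted(f$posterior, f$design, max_draws = cfg$max_draws)
    utils::write.csv(ovf$table,
                     file.path(cfg$out_dir, paste0("observed_fitted_", oc, ".csv")),
                     row.names = FALSE)
  }
  state
}
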