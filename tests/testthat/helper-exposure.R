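# toy exposure instances shared by the unit and acceptance suites

toy_exposure_instance <- function(seed, n_events = 50, n_clusters = 20) {
  set.seed(seed)
  geo <- data.frame(cluster_id = sprintf("c%02d", 1:n_clusters),
                    district_id = sprintf("d%d", rep(1:4, each = n_clusters / 4)),
                    lon = runif(n_clusters, 44, 46),
                    lat = runif(n_clusters, 2, 4),
                    stringsAsFactors = FALSE)
  ev <- data.frame(event_id = sprintf("e%02d", 1:n_events),
                   event_date = as.Date("2009-06-01") +
                     sample(-500:100, n_events, replace = TRUE),
                   district_id = sample(geo$district_id, n_events, replace = TRUE),
                   acled_type = sample(acled_event_types(), n_events, replace = TRUE),
                   stringsAsFactors = FALSE)
  si <- expand.grid(cluster_id = geo$cluster_id,
                    survey_date = as.Date(c("2009-05-15", "2009-11-15")),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  list(geo = geo, ev = ev, si = si)
}

# independent brute-force oracle: triple loop over (occasion, event)
brute_exposure <- function(ev, geo, si) {
  out <- si
  out$recent_any <- 0L; out$longer_any <- 0L
  for (r in seq_len(nrow(si))) {
    cl <- si$cluster_id[r]
    dd <- geo$district_id[geo$cluster_id == cl]
    for (e in seq_len(nrow(ev))) {
      if (ev$district_id[e] != dd) next
      delta <- as.numeric(si$survey_date[r] - ev$event_date[e])
      if (delta >= 0 && delta < 91) out$recent_any[r] <- 1L
      if (delta >= 91 && delta < 366) out$longer_any[r] <- 1L
    }
  }
  out
}

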