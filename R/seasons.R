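# Somalia's four-season calendar.

#' Season of a calendar date
#'
#' Maps a date to one of Somalia's four seasons: `Jilal` (the harsh dry
#' season, December-March), `Gu` (the main rains, April-June), `Hagaa`
#' (the second dry season, July-September) and `Deyr` (the short rains,
#' October-December).  December belongs to both ranges as commonly quoted;
#' here it resolves to `Jilal` by default (`december = "Jilal"` switches it).
#'
#' @param date a `Date` vector (or something `as.Date()` accepts).
#' @param december season that December resolves to, `"Jilal"` or `"Deyr"`.
#' @return character vector of season names.
#' @export
season_of <- function(date, december = c("Jilal", "Deyr")) {
  december <- match.arg(december)
  m <- as.integer(format(as.Date(date), "%m"))
  out <- character(length(m))
  out[m %in% c(1L, 2L, 3L)] <- "Jilal"
  out[m %in% 4:6] <- "Gu"
  out[m %in% 7:9] <- "Hagaa"
  out[m %in% c(10L, 11L)] <- "Deyr"
  out[m == 12L] <- december
  out
}

#' The four season levels, reference level last
#' @return character vector `c("Deyr", "Jilal", "Gu", "Hagaa")`; `Deyr`
#'   is the reference level in model designs.
#' @export
season_levels <- function() c("Deyr", "Jilal", "Gu", "Hagaa")
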