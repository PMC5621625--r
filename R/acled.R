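# ACLED event-type vocabulary and the nine-to-four class mapping.

#' The nine ACLED conflict event-type labels
#'
#' Canonical spellings of the nine event types recorded by the Armed
#' Conflict Location and Event Data project (ACLED).  Input labels are
#' matched case-insensitively after punctuation/whitespace normalisation,
#' so e.g. `"Riots/Protests"` normalises to `"riots or protests"`.
#'
#' @return character vector of the nine canonical labels.
#' @export
acled_event_types <- function() {
  c("battle - no change of territory",
    "battle - non-state actor overtakes territory",
    "battle - government regains territory",
    "headquarters or base established",
    "strategic development",
    "riots or protests",
    "violence against civilians",
    "non-violent transfer of territory",
    "remote violence")
}

#' The four analysis classes of conflict events
#' @return character vector: battle, remote_violence,
#'   violence_against_civilians, other.
#' @export
conflict_classes <- function() {
  c("battle", "remote_violence", "violence_against_civilians", "other")
}

# lower-case, collapse punctuation and separators to single spaces
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[/_,]+", " ", x)
  x <- gsub("\\s*-\\s*", " - ", x)
  x <- gsub("\\s+", " ", x)
  # "riots protests" / "riots or protests" both map to the canonical form
  x <- sub("^riots( or)? protests$", "riots or protests", x)
  x
}

#' Normalise an event-type label to the canonical nine-label vocabulary
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical labels, `NA` where no match.
#' @export
normalize_event_type <- function(x) {
  canon <- acled_event_types()
  key <- normalize_label(canon)
  idx <- match(normalize_label(as.character(x)), key)
  canon[idx]
}

# default nine -> four mapping; the detailed mapping used upstream is not
# public, so this partition (the only one consistent with the four class
# names) is the default and can be overridden per run.
default_class_map <- function() {
  c("battle - no change of territory"              = "battle",
    "battle - non-state actor overtakes territory" = "battle",
    "battle - government regains territory"        = "battle",
    "remote violence"                              = "remote_violence",
    "violence against civilians"                   = "violence_against_civilians",
    "headquarters or base established"             = "other",
    "strategic development"                        = "other",
    "riots or protests"                            = "other",
    "non-violent transfer of territory"            = "other")
}

#' Map an ACLED event type to its analysis class
#'
#' Battles (all three subtypes) map to `battle`; remote violence and
#' violence against civilians map to their own classes; the remaining four
#' event types map to `other`.  The mapping is total on the nine-label
#' vocabulary and configurable through `class_map`.
#'
#' @param acled_type character vector of event-type labels (canonical or
#'   any spelling that [normalize_event_type()] accepts).
#' @param class_map named character vector overriding the default mapping.
#' @return character vector of classes (see [conflict_classes()]).
#' @export
classify_event_type <- function(acled_type, class_map = default_class_map()) {
  canon <- normalize_event_type(acled_type)
  if (anyNA(canon)) {
    bad <- unique(acled_type[is.na(canon)])
    stop("unknown ACLED event type label(s): ", paste(bad, collapse = ", "))
  }
  cls <- unname(class_map[canon])
  if (anyNA(cls) || !all(cls %in% conflict_classes()))
    stop("class_map does not cover the nine-label vocabulary or uses an unknown class")
  cls
}
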