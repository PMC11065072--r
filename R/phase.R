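#' Clinical trial phase groups
#'
#' Canonical phase groups used throughout the package. Trials are grouped as
#' Phase I (Phase I and Early Phase I), Phase II (Phase II and Phase I/II),
#' Phase III (Phase III and Phase II/III); Phase IV trials are post-approval
#' and count as indications. Anything unmatched falls into `UNKNOWN`.
#'
#' `UNKNOWN` carries no position in the advancement order; among the ordered
#' groups `PHASE_I < PHASE_II < PHASE_III < INDICATED`.
#'
#' @format Character vector of the five group labels.
#' @export
PHASE_LEVELS <- c("UNKNOWN", "PHASE_I", "PHASE_II", "PHASE_III", "INDICATED")

#' The six complex disease categories
#' @format Character vector of category labels.
#' @export
DISEASE_CATEGORIES <- c("cardiovascular", "hormonal", "immune",
                        "neoplasms", "neurological", "ophthalmological")

normalize_phase_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- ""
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub(" ?/ ?", "/", x)
  # roman -> arabic, longest token first so "iv" is not eaten by "i"
  x <- gsub("\\biv\\b", "4", x)
  x <- gsub("\\biii\\b", "3", x)
  x <- gsub("\\bii\\b", "2", x)
  x <- gsub("\\bi\\b", "1", x)
  x <- gsub("phase([0-9])", "phase \\1", x)
  x
}

.phase_lookup <- c(
  "early phase 1"   = "PHASE_I",
  "phase 1"         = "PHASE_I",
  "phase 2"         = "PHASE_II",
  "phase 1/phase 2" = "PHASE_II",
  "phase 1/2"       = "PHASE_II",
  "phase 3"         = "PHASE_III",
  "phase 2/phase 3" = "PHASE_III",
  "phase 2/3"       = "PHASE_III",
  "phase 4"         = "INDICATED"
)

#' Group a raw clinical trial phase label
#'
#' Maps free-text registry phase labels onto the five canonical groups.
#' Matching is case-insensitive and accepts both arabic ("Phase 2") and roman
#' ("Phase II") numerals as well as combined labels ("Phase 2/Phase 3", which
#' groups with the later phase). Unrecognized labels, empty strings and `NA`
#' map to `"UNKNOWN"`; the function is total and never errors.
#'
#' @param raw_phase character vector of raw phase labels.
#' @return character vector of the same length with values in [PHASE_LEVELS].
#' @examples
#' group_phase(c("Early Phase 1", "Phase II", "Phase 2/Phase 3", "Phase 4", ""))
#' @export
group_phase <- function(raw_phase) {
  norm <- normalize_phase_label(raw_phase)
  # canonical group labels pass through unchanged (idempotence)
  out <- ifelse(toupper(trimws(as.character(raw_phase))) %in% PHASE_LEVELS,
                toupper(trimws(as.character(raw_phase))),
                unname(.phase_lookup[norm]))
  out[is.na(out)] <- "UNKNOWN"
  out
}

#' Advancement rank of a phase group
#'
#' `UNKNOWN` ranks lowest (0) so that any informative phase dominates it when
#' duplicate trial records for one (drug, disease) pair are collapsed to the
#' most advanced evidence.
#'
#' @param phase character vector of values in [PHASE_LEVELS].
#' @return integer ranks, 0 (UNKNOWN) to 4 (INDICATED).
#' @export
phase_rank <- function(phase) {
  r <- match(phase, PHASE_LEVELS) - 1L
  if (anyNA(r)) stop("unknown phase group label(s): ",
                     paste(unique(phase[is.na(r)]), collapse = ", "))
  r
}
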