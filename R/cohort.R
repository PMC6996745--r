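#' Cohort dataset: one trait questionnaire plus an EMA event log
#'
#' Bundles the two tables of a trait/state eating-motive study: a trait
#' table with one row per participant (the one-shot dispositional
#' questionnaire) and an event table with one row per logged eating
#' occasion (the in-the-moment EMA ratings). Construction validates both
#' tables against the motive catalog and rating scale; every violation is
#' reported with the offending row and field.
#'
#' @param traits Data frame with column `participant_id` followed by one
#'   column per catalog motive.
#' @param events Data frame with columns `participant_id`, `day_index`,
#'   `meal_type`, followed by one column per catalog motive. May have zero
#'   rows.
#' @param catalog A [motive_catalog()].
#' @param scale A [likert_scale()].
#' @param provenance Free-text origin tag, e.g. `"observed"` or
#'   `"simulated seed=1"`.
#' @param strict If `TRUE` (the default, appropriate for raw data), ratings
#'   must be whole numbers on the Likert scale; derived or averaged profiles
#'   may use `strict = FALSE`.
#' @return A list with elements `catalog`, `scale`, `traits`, `events`,
#'   `provenance`, of class `cohort_dataset`.
#' @seealso [read_cohort()], [simulate_cohort()]
#' @examples
#' tr <- data.frame(participant_id = "p1",
#'                  t(stats::setNames(rep(2, 15), tems_motives())))
#' ev <- tr
#' ev$day_index <- 1L
#' ev$meal_type <- "lunch"
#' d <- cohort_dataset(tr, ev)
#' d
#' @export
cohort_dataset <- function(traits, events,
                           catalog = motive_catalog(),
                           scale = likert_scale(),
                           provenance = "observed",
                           strict = TRUE) {
  traits <- tibble::as_tibble(traits)
  events <- tibble::as_tibble(events)
  validate_trait_table(traits, catalog, scale, strict = strict)
  validate_event_table(events, catalog, scale,
                       known_ids = as.character(traits$participant_id),
                       strict = strict)
  traits$participant_id <- as.character(traits$participant_id)
  if (nrow(events)) {
    events$participant_id <- as.character(events$participant_id)
    events$day_index <- as.integer(events$day_index)
  }
  structure(
    list(catalog = catalog, scale = scale,
         traits = traits[, c("participant_id", as.character(catalog))],
         events = events[, c("participant_id", "day_index", "meal_type",
                             as.character(catalog)), drop = FALSE],
         provenance = as.character(provenance)[1]),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset: %d participants, %d eating events, %d motives (%s)>\n",
    nrow(x$traits), nrow(x$events), length(x$catalog), x$provenance))
  invisible(x)
}

#' Number of participants / events in a cohort
#'
#' @param dataset A [cohort_dataset()].
#' @return Integer count.
#' @export
n_participants <- function(dataset) nrow(dataset$traits)

#' @rdname n_participants
#' @export
n_events <- function(dataset) nrow(dataset$events)

schema_stop <- function(table, row, field, msg) {
  stop(structure(
    class = c("motiveprofiles_schema_error", "error", "condition"),
    list(message = sprintf("%s row %s, field '%s': %s", table,
                           as.character(row), field, msg),
         call = NULL)))
}

check_ratings <- function(df, table, catalog, scale, strict) {
  for (m in as.character(catalog)) {
    v <- df[[m]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      schema_stop(table, if (is.na(bad)) "?" else bad, m,
                  "rating is not numeric")
    }
    bad <- which(!is.finite(v))[1]
    if (!is.na(bad)) schema_stop(table, bad, m, "rating is missing")
    bad <- which(v < scale$min_value | v > scale$max_value)[1]
    if (!is.na(bad)) {
      schema_stop(table, bad, m,
                  sprintf("rating %g outside scale [%g, %g]",
                          v[bad], scale$min_value, scale$max_value))
    }
    if (strict) {
      bad <- which(abs(v - round(v)) > 1e-8)[1]
      if (!is.na(bad)) {
        schema_stop(table, bad, m,
                    sprintf("rating %g is not a whole-number Likert response",
                            v[bad]))
      }
    }
  }
  invisible(TRUE)
}

validate_trait_table <- function(traits, catalog, scale, strict = TRUE) {
  need <- c("participant_id", as.character(catalog))
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    schema_stop("traits", "header", miss[1], "required column missing")
  }
  if (nrow(traits) == 0) {
    schema_stop("traits", 0, "participant_id", "no participants")
  }
  dup <- which(duplicated(traits$participant_id))[1]
  if (!is.na(dup)) {
    schema_stop("traits", dup, "participant_id",
                sprintf("duplicate participant id '%s'",
                        traits$participant_id[dup]))
  }
  check_ratings(traits, "traits", catalog, scale, strict)
}

validate_event_table <- function(events, catalog, scale, known_ids,
                                 strict = TRUE) {
  need <- c("participant_id", "day_index", "meal_type",
            as.character(catalog))
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    schema_stop("events", "header", miss[1], "required column missing")
  }
  if (nrow(events) == 0) return(invisible(TRUE))
  bad <- which(!as.character(events$participant_id) %in% known_ids)[1]
  if (!is.na(bad)) {
    schema_stop("events", bad, "participant_id",
                sprintf("unknown participant '%s' (no trait profile)",
                        events$participant_id[bad]))
  }
  di <- events$day_index
  bad <- which(!is.finite(as.numeric(di)) | as.numeric(di) < 1 |
                 abs(as.numeric(di) - round(as.numeric(di))) > 1e-8)[1]
  if (!is.na(bad)) {
    schema_stop("events", bad, "day_index", "day index must be an integer >= 1")
  }
  bad <- which(!as.character(events$meal_type) %in% meal_types())[1]
  if (!is.na(bad)) {
    schema_stop("events", bad, "meal_type",
                sprintf("unknown meal type '%s' (expected one of %s)",
                        events$meal_type[bad],
                        paste(meal_types(), collapse = ", ")))
  }
  check_ratings(events, "events", catalog, scale, strict)
}
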