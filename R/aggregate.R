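#' Person-level state profiles from event-level ratings
#'
#' Collapses each participant's repeatedly assessed state motives to one
#' profile by averaging, unweighted, across all of their logged eating
#' occasions, and records the within-person fluctuation of each motive as
#' the sample (n - 1) variance across events. Variances are `NA` for
#' participants with a single event. Participants logging fewer than
#' `min_events` occasions are excluded from the result and listed in the
#' `"excluded"` attribute rather than silently dropped.
#'
#' @param dataset A [cohort_dataset()].
#' @param min_events Minimum number of logged occasions for a participant
#'   to be summarized (default 1: no exclusions, matching a protocol with
#'   no dropout).
#' @return A tibble with one row per retained participant: `participant_id`,
#'   `n_events`, then `mean_<motive>` and `var_<motive>` columns in catalog
#'   order. Attributes: `excluded` (character vector of participant ids
#'   below the threshold), `catalog`.
#' @examples
#' d <- simulate_cohort(simulation_config(n_participants = 3, seed = 2))
#' s <- summarize_states(d)
#' s[, 1:4]
#' @export
summarize_states <- function(dataset, min_events = 1) {
  stopifnot(inherits(dataset, "cohort_dataset"), min_events >= 1)
  motives <- as.character(dataset$catalog)
  ids <- dataset$traits$participant_id
  ev <- dataset$events
  if (nrow(ev) == 0) {
    warning("dataset has no events; returning an empty state summary",
            call. = FALSE)
    out <- tibble::as_tibble(c(
      list(participant_id = character(), n_events = integer()),
      stats::setNames(rep(list(numeric()), length(motives)),
                      paste0("mean_", motives)),
      stats::setNames(rep(list(numeric()), length(motives)),
                      paste0("var_", motives))))
    attr(out, "excluded") <- ids
    attr(out, "catalog") <- dataset$catalog
    return(out)
  }
  counts <- table(factor(ev$participant_id, levels = ids))
  rows <- lapply(ids, function(id) {
    n <- as.integer(counts[[id]])
    if (n < min_events) return(NULL)
    m <- as.matrix(ev[ev$participant_id == id, motives])
    mn <- colMeans(m)
    vr <- if (n >= 2) apply(m, 2, stats::var) else rep(NA_real_, length(motives))
    tibble::as_tibble(c(list(participant_id = id, n_events = n),
                        stats::setNames(as.list(mn), paste0("mean_", motives)),
                        stats::setNames(as.list(vr), paste0("var_", motives))))
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  attr(out, "excluded") <- ids[!keep]
  attr(out, "catalog") <- dataset$catalog
  out
}

#' Share computation for occasion counts
#'
#' Percentages of total, rounded to one decimal place.
#'
#' @param counts Named integer vector of per-category counts.
#' @return Named numeric vector of percentages (or `NA` if total is 0).
#' @examples
#' occasion_shares(c(breakfast = 231, lunch = 194, afternoon_tea = 25,
#'                   snack = 209, dinner = 229))
#' @export
occasion_shares <- function(counts) {
  total <- sum(counts)
  if (total == 0) {
    return(stats::setNames(rep(NA_real_, length(counts)), names(counts)))
  }
  round(100 * counts / total, 1)
}

#' Meal-type composition of the event log
#'
#' Counts and percentage shares of logged eating occasions per
#' participant-identified meal type.
#'
#' @param dataset A [cohort_dataset()].
#' @return A list of class `occasion_summary`: `counts` (named integer
#'   vector over [meal_types()]), `total`, and `shares` (percentages
#'   rounded to one decimal, `NA` when there are no events).
#' @export
summarize_occasions <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  counts <- table(factor(dataset$events$meal_type, levels = meal_types()))
  counts <- stats::setNames(as.integer(counts), meal_types())
  structure(list(counts = counts, total = sum(counts),
                 shares = occasion_shares(counts)),
            class = "occasion_summary")
}

#' @export
print.occasion_summary <- function(x, ...) {
  cat(sprintf("<occasion_summary: %d eating occasions>\n", x$total))
  for (m in names(x$counts)) {
    cat(sprintf("  %-14s %4d  (%s%%)\n", m, x$counts[[m]],
                ifelse(is.na(x$shares[[m]]), "-",
                       format(x$shares[[m]], nsmall = 1))))
  }
  invisible(x)
}

# state means / variances of a summary as participant x motive matrices
state_mean_matrix <- function(summaries, motives) {
  m <- as.matrix(summaries[, paste0("mean_", motives)])
  dimnames(m) <- list(summaries$participant_id, motives)
  m
}

state_var_matrix <- function(summaries, motives) {
  m <- as.matrix(summaries[, paste0("var_", motives)])
  dimnames(m) <- list(summaries$participant_id, motives)
  m
}

trait_matrix <- function(traits, motives) {
  m <- as.matrix(traits[, motives])
  dimnames(m) <- list(traits$participant_id, motives)
  m
}
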