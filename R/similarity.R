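#' Double-entry intraclass correlation between two profiles
#'
#' The omnibus index of profile similarity: sensitive simultaneously to
#' differences in shape, scatter and elevation. With m the grand mean of
#' all 2k values,
#' \deqn{ICC_{de} = \frac{\sum_i (x_i - m)(y_i - m)}
#'   {[\sum_i (x_i - m)^2 + \sum_i (y_i - m)^2] / 2}.}
#' This closed form equals the Pearson correlation computed over the
#' "double-entry" pairing \{(x_i, y_i)\} together with \{(y_i, x_i)\}.
#' Two identical constant profiles have no variation to correlate; the
#' result is then `NA` rather than an error.
#'
#' @param x,y Numeric profile vectors of equal length k >= 2 (trait and
#'   state, in catalog order).
#' @return A scalar in `[-1, 1]`, or `NA` when the denominator is zero.
#' @examples
#' icc_double_entry(c(1, 2, 3), c(1, 2, 3))   #  1
#' icc_double_entry(c(1, 2, 3), c(3, 2, 1))   # -1
#' icc_double_entry(1:4, 2:5)                 #  2/3
#' @export
icc_double_entry <- function(x, y) {
  check_pair(x, y, k_min = 2)
  m <- mean(c(x, y))
  den <- (sum((x - m)^2) + sum((y - m)^2)) / 2
  if (den <= 0) return(NA_real_)
  sum((x - m) * (y - m)) / den
}

#' Shape similarity of two profiles
#'
#' The Pearson product-moment correlation between the two profile vectors:
#' agreement of the rank order / relative patterning of the motives,
#' insensitive to elevation and scatter differences.
#'
#' @inheritParams icc_double_entry
#' @return Pearson r, or `NA` when either profile is constant.
#' @export
shape_similarity <- function(x, y) {
  check_pair(x, y, k_min = 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Scatter similarity of two profiles
#'
#' Raw difference between profile variances, trait minus state, using the
#' sample (n - 1) variance over the k motive values. Zero indicates equal
#' spread; the sign says which profile is more dispersed.
#'
#' @inheritParams icc_double_entry
#' @return Signed variance difference `var(x) - var(y)`.
#' @export
scatter_similarity <- function(x, y) {
  check_pair(x, y, k_min = 2)
  stats::var(x) - stats::var(y)
}

#' Elevation similarity of two profiles
#'
#' Raw difference between profile means, trait minus state. A positive
#' value means the trait profile sits higher on the rating scale overall.
#'
#' @inheritParams icc_double_entry
#' @return Signed mean difference `mean(x) - mean(y)`.
#' @export
elevation_similarity <- function(x, y) {
  check_pair(x, y, k_min = 1)
  mean(x) - mean(y)
}

check_pair <- function(x, y, k_min) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("profiles must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(x) < k_min) {
    stop(sprintf("profiles must have at least %d elements", k_min),
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("profiles must not contain missing values", call. = FALSE)
  }
  invisible(TRUE)
}

#' All four similarity indices for one trait/state profile pair
#'
#' Bundles overall similarity (`icc_de`), shape (`shape_r`), scatter
#' (`scatter_var_d`), elevation (`elevation_m_d`) and the derived
#' percentage of state-profile variance explained by the trait profile,
#' `variance_explained_pct = icc_de^2 * 100`. Degenerate components are
#' `NA` independently; one flat profile never aborts a batch analysis.
#'
#' @inheritParams icc_double_entry
#' @param label Level tag carried through to tabular output (e.g. `"group"`
#'   or a participant id).
#' @return A one-row tibble: `label`, `icc_de`, `shape_r`, `scatter_var_d`,
#'   `elevation_m_d`, `variance_explained_pct`.
#' @examples
#' similarity_profile(c(4, 3, 2, 1), c(3.5, 3, 1.5, 1), label = "p01")
#' @export
similarity_profile <- function(x, y, label = NA_character_) {
  icc <- icc_double_entry(x, y)
  tibble::tibble(
    label = as.character(label),
    icc_de = icc,
    shape_r = shape_similarity(x, y),
    scatter_var_d = scatter_similarity(x, y),
    elevation_m_d = elevation_similarity(x, y),
    variance_explained_pct = icc^2 * 100)
}

#' Group-level (between-person) profile pair
#'
#' The average trait profile versus the average state profile: per motive,
#' the mean of trait ratings across participants and the mean of the
#' participants' state means. Each participant contributes equally to the
#' state profile regardless of how many occasions they logged (person
#' means are averaged, events are not pooled).
#'
#' @param traits Trait table of a [cohort_dataset()] (or the dataset's
#'   `$traits`).
#' @param summaries Output of [summarize_states()].
#' @param catalog A [motive_catalog()].
#' @return A list with numeric vectors `trait` and `state` (named by
#'   motive) and `label = "group"`.
#' @export
between_person_pair <- function(traits, summaries,
                                catalog = motive_catalog()) {
  motives <- as.character(catalog)
  common <- intersect(traits$participant_id, summaries$participant_id)
  if (length(common) == 0) {
    stop("no participant appears in both the trait table and the state ",
         "summaries", call. = FALSE)
  }
  tm <- trait_matrix(traits[traits$participant_id %in% common, ], motives)
  sm <- state_mean_matrix(
    summaries[summaries$participant_id %in% common, ], motives)
  list(trait = colMeans(tm), state = colMeans(sm), label = "group")
}

#' Within-person profile pairs
#'
#' One trait/state pair per participant: the participant's own trait
#' vector against their own vector of state means. Participants missing
#' from `summaries` (below the event threshold) are omitted and reported
#' in the `"excluded"` attribute. Ordering follows the trait table.
#'
#' @inheritParams between_person_pair
#' @return A named list (by participant id) of lists with elements
#'   `trait`, `state`, `label`; attribute `excluded`.
#' @export
within_person_pairs <- function(traits, summaries,
                                catalog = motive_catalog()) {
  motives <- as.character(catalog)
  present <- traits$participant_id %in% summaries$participant_id
  tm <- trait_matrix(traits[present, , drop = FALSE], motives)
  sm <- state_mean_matrix(summaries, motives)
  ids <- traits$participant_id[present]
  pairs <- lapply(ids, function(id) {
    list(trait = tm[id, ], state = sm[id, ], label = id)
  })
  names(pairs) <- ids
  attr(pairs, "excluded") <- traits$participant_id[!present]
  pairs
}

#' Similarity indices at every level of analysis
#'
#' Convenience wrapper assembling the exportable similarity table: the
#' group-level row first, then one row per participant, each with the four
#' indices and the variance-explained percentage.
#'
#' @param dataset A [cohort_dataset()].
#' @param min_events Passed to [summarize_states()].
#' @return A tibble with columns `level` (`"group"` / `"participant"`),
#'   `label`, `icc_de`, `shape_r`, `scatter_var_d`, `elevation_m_d`,
#'   `variance_explained_pct`.
#' @examples
#' d <- simulate_cohort(simulation_config(n_participants = 4, seed = 3))
#' similarity_table(d)
#' @export
similarity_table <- function(dataset, min_events = 1) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  summaries <- summarize_states(dataset, min_events = min_events)
  gp <- between_person_pair(dataset$traits, summaries, dataset$catalog)
  rows <- list(cbind(tibble::tibble(level = "group"),
                     similarity_profile(gp$trait, gp$state, gp$label)))
  wp <- within_person_pairs(dataset$traits, summaries, dataset$catalog)
  for (p in wp) {
    rows[[length(rows) + 1L]] <-
      cbind(tibble::tibble(level = "participant"),
            similarity_profile(p$trait, p$state, p$label))
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "excluded") <- attr(wp, "excluded")
  out
}
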