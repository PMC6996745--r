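# Build tiny cohorts in code; no stored fixtures.

motives <- tems_motives()

# trait table for given participant ids; ratings a function(id) -> vector
make_traits <- function(ids, ratings) {
  rows <- lapply(ids, function(id) {
    tibble::as_tibble(c(list(participant_id = id),
                        stats::setNames(as.list(ratings(id)), motives)))
  })
  do.call(rbind, rows)
}

# event rows for one participant: each row of `mat` is one occasion
make_events <- function(id, mat, meal = "lunch", day = 1L) {
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    tibble::as_tibble(c(list(participant_id = id, day_index = day,
                             meal_type = meal),
                        stats::setNames(as.list(mat[i, ]), motives)))
  })
  do.call(rbind, rows)
}

# 2-participant, 4-event hand fixture used across files
tiny_cohort <- function() {
  tr <- make_traits(c("a", "b"), function(id) {
    if (id == "a") rep(c(1, 2, 3), 5) else rep(c(4, 3, 2), 5)
  })
  ev <- rbind(
    make_events("a", matrix(2, 2, 15), meal = "breakfast"),
    make_events("b", rbind(rep(2, 15), rep(4, 15)), meal = "dinner"))
  cohort_dataset(tr, ev)
}

# minimal trait/summary tables for compare_motive on a single motive "m":
# per-person trait values tv and state means sv
paired_tables <- function(tv, sv, motive = "liking") {
  ids <- sprintf("p%d", seq_along(tv))
  traits <- tibble::tibble(participant_id = ids)
  traits[[motive]] <- tv
  summ <- tibble::tibble(participant_id = ids, n_events = 5L)
  summ[[paste0("mean_", motive)]] <- sv
  summ[[paste0("var_", motive)]] <- 0.5
  list(traits = traits, summaries = summ)
}

# independent paired-t oracle: mean(d) / (sd(d)/sqrt(n)), two-sided p
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# independent ICC_de oracle: Pearson over the doubled pairing
icc_doubled_oracle <- function(x, y) stats::cor(c(x, y), c(y, x))
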