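#' Paired trait-state comparison for one motive
#'
#' Across participants, compares the dispositional rating of a motive with
#' the person-level mean of its momentary ratings: a paired two-sided t
#' test on the per-person (trait, state-mean) pairs, Cohen's d, and the
#' between-person trait-state Pearson correlation.
#'
#' Cohen's d uses the averaged-SD convention by default,
#' \deqn{d_{av} = \bar{D} / [(SD_{trait} + SD_{state}) / 2],}
#' with the SDs taken between persons; `d_method = "z"` gives the
#' change-score standardization \eqn{d_z = \bar{D} / SD_D} instead.
#'
#' When the paired differences are all identical the t statistic is not
#' defined; `t_stat` and `p_value` are then `NA` while `mean_diff` is
#' still reported. Likewise `trait_state_r` is `NA` when either member
#' has zero between-person variance, and all inferential fields are `NA`
#' with fewer than 3 matched participants (means are still reported, so
#' batch analyses of tiny cohorts do not abort).
#'
#' @param motive Motive identifier (a catalog entry).
#' @param traits Trait table of a [cohort_dataset()].
#' @param summaries Output of [summarize_states()].
#' @param d_method `"av"` (default) or `"z"`.
#' @return A one-row tibble with fields `motive`, `n`, `trait_mean`,
#'   `state_mean`, `mean_diff`, `trait_var`, `state_var`, `t_stat`, `df`,
#'   `p_value`, `cohen_d`, `trait_state_r`, `effect_band`, `r_band`.
#' @seealso [compare_all_motives()] for the full per-motive table.
#' @export
compare_motive <- function(motive, traits, summaries,
                           d_method = c("av", "z")) {
  d_method <- match.arg(d_method)
  common <- intersect(traits$participant_id, summaries$participant_id)
  if (length(common) < 1) {
    stop("no matched participants for paired comparison", call. = FALSE)
  }
  tv <- trait_matrix(traits[match(common, traits$participant_id), ],
                     motive)[, 1]
  sv <- state_mean_matrix(
    summaries[match(common, summaries$participant_id), ], motive)[, 1]
  if (anyNA(sv)) {
    stop("state means undefined for motive '", motive, "'", call. = FALSE)
  }
  n <- length(common)
  diffs <- tv - sv
  sd_t <- stats::sd(tv); sd_s <- stats::sd(sv); sd_d <- stats::sd(diffs)
  if (n < 3) sd_t <- sd_s <- sd_d <- NA_real_  # too few pairs for inference

  if (!is.na(sd_d) && sd_d > 0) {
    tt <- stats::t.test(tv, sv, paired = TRUE)
    t_stat <- unname(tt$statistic); p_value <- tt$p.value
  } else {
    t_stat <- NA_real_; p_value <- NA_real_
  }
  cohen_d <- if (d_method == "av") {
    if (!is.na(sd_t) && sd_t + sd_s > 0) {
      mean(diffs) / ((sd_t + sd_s) / 2)
    } else NA_real_
  } else {
    if (!is.na(sd_d) && sd_d > 0) mean(diffs) / sd_d else NA_real_
  }
  r <- if (!is.na(sd_t) && sd_t > 0 && sd_s > 0) {
    stats::cor(tv, sv)
  } else NA_real_

  tibble::tibble(
    motive = motive, n = n,
    trait_mean = mean(tv), state_mean = mean(sv),
    mean_diff = mean(diffs),
    trait_var = stats::var(tv), state_var = stats::var(sv),
    t_stat = t_stat, df = n - 1L, p_value = p_value,
    cohen_d = cohen_d, trait_state_r = r,
    effect_band = band_effect(cohen_d), r_band = band_correlation(r))
}

#' Descriptive band for a Cohen's d effect size
#'
#' `|d| > 0.8` is `"large"`, `|d| > 0.5` `"moderate"`, `|d| > 0.3`
#' `"small"` (all strict inequalities), anything else `"negligible"`.
#'
#' @param d Standardized mean difference (vectorized).
#' @return Character vector of bands; `NA` for undefined d.
#' @examples
#' band_effect(c(1.97, 0.55, 0.30, NA))
#' @export
band_effect <- function(d) {
  ifelse(is.na(d), NA_character_,
         ifelse(abs(d) > 0.8, "large",
                ifelse(abs(d) > 0.5, "moderate",
                       ifelse(abs(d) > 0.3, "small", "negligible"))))
}

#' Descriptive band for a trait-state correlation
#'
#' `r >= 0.50` is `"high"` (inclusive), `0.30 < r < 0.50` `"medium"`,
#' anything else `"low"`.
#'
#' @param r Pearson correlation (vectorized).
#' @return Character vector of bands; `NA` for undefined r.
#' @export
band_correlation <- function(r) {
  ifelse(is.na(r), NA_character_,
         ifelse(r >= 0.50, "high",
                ifelse(r > 0.30, "medium", "low")))
}

#' Per-motive paired comparisons across the whole catalog
#'
#' Runs [compare_motive()] for every catalog motive and flags motives
#' rated significantly higher as traits than as states (two-sided
#' `p_value < alpha` and `mean_diff > 0`). A Holm-adjusted p-value column
#' is emitted alongside the raw p-values; flagging uses the raw p-values.
#'
#' @inheritParams compare_motive
#' @param alpha Two-sided significance level (default 0.05).
#' @param catalog A [motive_catalog()].
#' @return A tibble with one row per catalog motive (all
#'   [compare_motive()] fields plus `p_holm` and logical `flagged`);
#'   attribute `counts` is a list with `n_flagged` and `alpha`.
#' @examples
#' d <- simulate_cohort(study_config(seed = 1))
#' s <- summarize_states(d)
#' cmp <- compare_all_motives(d$traits, s)
#' sum(cmp$flagged)
#' @export
compare_all_motives <- function(traits, summaries, alpha = 0.05,
                                d_method = c("av", "z"),
                                catalog = motive_catalog()) {
  d_method <- match.arg(d_method)
  rows <- lapply(as.character(catalog), compare_motive,
                 traits = traits, summaries = summaries,
                 d_method = d_method)
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$flagged <- !is.na(out$p_value) & out$p_value < alpha &
    out$mean_diff > 0
  attr(out, "counts") <- list(n_flagged = sum(out$flagged), alpha = alpha)
  out
}
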