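#' Run the full trait-state analysis on a cohort
#'
#' Convenience wrapper executing every analysis stage on one dataset:
#' person-level state summaries, occasion composition, the similarity
#' table at group and participant level, and the per-motive paired
#' comparisons.
#'
#' @param dataset A [cohort_dataset()].
#' @param min_events Minimum events per participant (see
#'   [summarize_states()]).
#' @param alpha Significance level for the per-motive tests.
#' @return A list of class `motive_analysis` with elements `states`,
#'   `occasions`, `similarity`, `motives`, and `meta` (row counts,
#'   provenance, parameters).
#' @export
analyze_cohort <- function(dataset, min_events = 1, alpha = 0.05) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  states <- summarize_states(dataset, min_events = min_events)
  res <- list(
    states = states,
    occasions = summarize_occasions(dataset),
    similarity = similarity_table(dataset, min_events = min_events),
    motives = compare_all_motives(dataset$traits, states, alpha = alpha,
                                  catalog = dataset$catalog),
    meta = list(n_participants = n_participants(dataset),
                n_events = n_events(dataset),
                provenance = dataset$provenance,
                min_events = min_events, alpha = alpha))
  class(res) <- "motive_analysis"
  res
}

#' @export
print.motive_analysis <- function(x, ...) {
  g <- x$similarity[x$similarity$level == "group", ]
  cat(sprintf(
    "<motive_analysis: %d participants, %d events>\n",
    x$meta$n_participants, x$meta$n_events))
  cat(sprintf(
    "  group similarity: ICC_de = %.2f, shape r = %.2f, Var_D = %.2f, M_D = %.2f\n",
    g$icc_de, g$shape_r, g$scatter_var_d, g$elevation_m_d))
  cat(sprintf("  motives rated higher as trait than state: %d of %d (alpha = %g)\n",
              attr(x$motives, "counts")$n_flagged, nrow(x$motives),
              x$meta$alpha))
  invisible(x)
}

#' Plain-text report of an analysis, mirroring the three levels
#'
#' Formats the between-person, between-motive and within-person results of
#' [analyze_cohort()] as a human-readable report.
#'
#' @param analysis A `motive_analysis`.
#' @return A character vector of report lines.
#' @export
pipeline_report <- function(analysis) {
  stopifnot(inherits(analysis, "motive_analysis"))
  g <- analysis$similarity[analysis$similarity$level == "group", ]
  p <- analysis$similarity[analysis$similarity$level == "participant", ]
  mv <- analysis$motives
  occ <- analysis$occasions
  fmt <- function(x) formatC(x, digits = 2, format = "f")
  lines <- c(
    "Trait-state eating-motive profile analysis",
    "==========================================",
    sprintf("Cohort: %d participants, %d eating occasions (%s)",
            analysis$meta$n_participants, analysis$meta$n_events,
            analysis$meta$provenance),
    "",
    "Eating occasions",
    paste(sprintf("  %s %d (%.1f%%)", names(occ$counts), occ$counts,
                  occ$shares), collapse = ","),
    "",
    "Between-person level (average profiles)",
    sprintf("  ICC_de = %s (variance explained %.0f%%), shape r = %s, M_D = %s, Var_D = %s",
            fmt(g$icc_de), g$variance_explained_pct, fmt(g$shape_r),
            fmt(g$elevation_m_d), fmt(g$scatter_var_d)),
    "",
    "Between-motive level (paired trait vs state-mean comparisons)",
    sprintf("  %d of %d motives rated significantly higher as trait (alpha = %g)",
            attr(mv, "counts")$n_flagged, nrow(mv), analysis$meta$alpha),
    sprintf("  %-20s diff %+.2f  t(%d) = %s  p = %s  d = %s (%s)  r = %s (%s)",
            mv$motive, mv$mean_diff, mv$df,
            ifelse(is.na(mv$t_stat), "NA", fmt(mv$t_stat)),
            ifelse(is.na(mv$p_value), "NA",
                   formatC(mv$p_value, digits = 3, format = "g")),
            ifelse(is.na(mv$cohen_d), "NA", fmt(mv$cohen_d)),
            ifelse(is.na(mv$effect_band), "NA", mv$effect_band),
            ifelse(is.na(mv$trait_state_r), "NA", fmt(mv$trait_state_r)),
            ifelse(is.na(mv$r_band), "NA", mv$r_band)),
    "",
    "Within-person level (per-participant profile similarity)",
    sprintf("  median ICC_de = %s; %d/%d participants with ICC_de >= 0.80; %d with ICC_de >= 0.50",
            fmt(stats::median(p$icc_de, na.rm = TRUE)),
            sum(p$icc_de >= 0.80, na.rm = TRUE), nrow(p),
            sum(p$icc_de >= 0.50, na.rm = TRUE)),
    sprintf("  %s: ICC_de = %s, r = %s, M_D = %s, Var_D = %s",
            p$label, fmt(p$icc_de), fmt(p$shape_r), fmt(p$elevation_m_d),
            fmt(p$scatter_var_d)))
  lines
}

#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `trait_path`/`event_path` (observed data) or
#' `sim_config` (synthetic data) must be supplied.
#'
#' @param trait_path,event_path CSV inputs for an observed cohort.
#' @param sim_config A [simulation_config()] for a synthetic cohort.
#' @param out_dir Output directory (created if needed).
#' @param min_events,alpha Analysis parameters.
#' @param order_by Row-ordering key for the rendered matrix.
#' @return A list of class `run_config`.
#' @export
run_config <- function(trait_path = NULL, event_path = NULL,
                       sim_config = NULL, out_dir = "motiveprofiles-out",
                       min_events = 1, alpha = 0.05,
                       order_by = "overall") {
  have_files <- !is.null(trait_path) || !is.null(event_path)
  if (have_files == !is.null(sim_config)) {
    stop("supply either trait_path+event_path or sim_config, not both",
         call. = FALSE)
  }
  if (have_files && (is.null(trait_path) || is.null(event_path))) {
    stop("both trait_path and event_path are required for observed data",
         call. = FALSE)
  }
  structure(list(trait_path = trait_path, event_path = event_path,
                 sim_config = sim_config, out_dir = out_dir,
                 min_events = min_events, alpha = alpha,
                 order_by = order_by),
            class = "run_config")
}

#' Execute the pipeline and write the result bundle
#'
#' Loads or simulates the cohort, runs [analyze_cohort()], renders the
#' person x motive matrix, and writes all artifacts to `out_dir`:
#' `traits.csv` / `events.csv` (for simulated cohorts), `state_summaries.csv`,
#' `occasion_summary.csv`, `similarity_indices.csv`,
#' `motive_comparisons.csv`, `matrix.svg`, `report.txt` and `run_log.json`
#' (package version, provenance/seed, row counts, parameters).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the dataset, the `motive_analysis`, and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$sim_config)) {
    dataset <- simulate_cohort(config$sim_config)
    write_cohort(dataset, path("traits.csv"), path("events.csv"))
  } else {
    dataset <- read_cohort(config$trait_path, config$event_path)
  }
  analysis <- analyze_cohort(dataset, min_events = config$min_events,
                             alpha = config$alpha)

  readr::write_csv(analysis$states, path("state_summaries.csv"),
                   progress = FALSE)
  occ <- analysis$occasions
  readr::write_csv(tibble::tibble(meal_type = names(occ$counts),
                                  count = occ$counts,
                                  share_pct = occ$shares),
                   path("occasion_summary.csv"), progress = FALSE)
  readr::write_csv(analysis$similarity, path("similarity_indices.csv"),
                   progress = FALSE)
  readr::write_csv(analysis$motives, path("motive_comparisons.csv"),
                   progress = FALSE)
  render_matrix(dataset, min_events = config$min_events,
                order_by = config$order_by, file = path("matrix.svg"))
  writeLines(pipeline_report(analysis), path("report.txt"))
  jsonlite::write_json(
    list(package = "motiveprofiles",
         version = as.character(utils::packageVersion("motiveprofiles")),
         provenance = dataset$provenance,
         seed = if (!is.null(config$sim_config)) config$sim_config$seed,
         n_participants = n_participants(dataset),
         n_events = n_events(dataset),
         min_events = config$min_events, alpha = config$alpha,
         order_by = config$order_by),
    path("run_log.json"), auto_unbox = TRUE, null = "null")
  invisible(list(dataset = dataset, analysis = analysis,
                 out_dir = config$out_dir))
}
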