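#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model used by [simulate_cohort()]. For each
#' participant p and motive m the generator draws a latent dispositional
#' level lambda_pm ~ Normal(mu_m, trait_sd_between^2), then a latent state
#' level eta_pm whose population mean sits `elevation_bias[m]` below the
#' trait mean and whose correlation with lambda_pm equals
#' `trait_state_coupling`. The reported trait rating is lambda_pm rounded
#' (half up) and clamped to the scale; each logged event adds
#' Normal(0, state_sd_within^2) momentary noise to eta_pm before the same
#' rounding. Events per day are Poisson(events_per_day_mean) truncated at
#' >= 1 (the protocol assumes at least one meal is logged per day) and meal
#' types are drawn from `meal_type_probs`.
#'
#' @param n_participants Number of participants.
#' @param n_days Number of EMA days per participant.
#' @param events_per_day_mean Mean of the (truncated) Poisson number of
#'   logged eating occasions per participant-day.
#' @param motive_means Per-motive grand means of the latent trait, in
#'   catalog order. The default declines linearly from 3.5 to 1.3,
#'   mimicking the typical descending TEMS profile.
#' @param elevation_bias Per-motive trait-minus-state bias on the rating
#'   scale (scalar recycled, or a vector in catalog order).
#' @param trait_sd_between Between-person SD of the latent trait.
#' @param state_sd_within Event-to-event SD of momentary noise; a scalar
#'   global value.
#' @param state_sd_within_per_motive Optional named numeric vector
#'   overriding `state_sd_within` for specific motives.
#' @param trait_state_coupling Correlation in `[0, 1]` between a
#'   participant's latent trait and latent state level for each motive.
#' @param meal_type_probs Named probabilities over [meal_types()]; must sum
#'   to 1.
#' @param seed Integer seed; all randomness flows from it.
#' @param catalog,scale Profile axis and rating scale.
#' @return A list of class `simulation_config`.
#' @seealso [study_config()] for defaults that emulate a 35-participant,
#'   8-day EMA protocol.
#' @export
simulation_config <- function(n_participants = 35,
                              n_days = 8,
                              events_per_day_mean = 3.2,
                              motive_means = NULL,
                              elevation_bias = 0,
                              trait_sd_between = 0.6,
                              state_sd_within = 0.7,
                              state_sd_within_per_motive = NULL,
                              trait_state_coupling = 0.5,
                              meal_type_probs = NULL,
                              seed = 1L,
                              catalog = motive_catalog(),
                              scale = likert_scale()) {
  k <- length(catalog)
  if (is.null(motive_means)) {
    motive_means <- seq(3.5, 1.3, length.out = k)
  }
  motive_means <- stats::setNames(rep_len(as.numeric(motive_means), k),
                                  as.character(catalog))
  elevation_bias <- stats::setNames(rep_len(as.numeric(elevation_bias), k),
                                    as.character(catalog))
  if (is.null(meal_type_probs)) {
    # occasion mix typical of free-living adult meal logs: breakfast, lunch
    # and dinner each ~1/4, snacks ~1/4, afternoon tea rare
    meal_type_probs <- c(breakfast = 231, lunch = 194, afternoon_tea = 25,
                         snack = 209, dinner = 229) / 888
  }
  sw <- stats::setNames(rep_len(as.numeric(state_sd_within), k),
                        as.character(catalog))
  if (!is.null(state_sd_within_per_motive)) {
    nm <- names(state_sd_within_per_motive)
    if (is.null(nm) || !all(nm %in% as.character(catalog))) {
      stop("state_sd_within_per_motive must be named by catalog motives",
           call. = FALSE)
    }
    sw[nm] <- as.numeric(state_sd_within_per_motive)
  }
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    events_per_day_mean = as.numeric(events_per_day_mean),
    motive_means = motive_means,
    elevation_bias = elevation_bias,
    trait_sd_between = as.numeric(trait_sd_between),
    state_sd_within = sw,
    trait_state_coupling = as.numeric(trait_state_coupling),
    meal_type_probs = meal_type_probs,
    seed = as.integer(seed),
    catalog = catalog,
    scale = scale), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 1 || n_days < 1 || events_per_day_mean <= 0) {
      stop("counts must be >= 1 and events_per_day_mean > 0", call. = FALSE)
    }
    if (trait_sd_between < 0 || any(state_sd_within < 0)) {
      stop("standard deviations must be >= 0", call. = FALSE)
    }
    if (trait_state_coupling < 0 || trait_state_coupling > 1) {
      stop("trait_state_coupling must lie in [0, 1]", call. = FALSE)
    }
    if (!setequal(names(meal_type_probs), meal_types())) {
      stop("meal_type_probs must be named by the five meal types",
           call. = FALSE)
    }
    if (any(meal_type_probs < 0) ||
        abs(sum(meal_type_probs) - 1) > 1e-9) {
      stop("meal_type_probs must be non-negative and sum to 1", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Study-design defaults for the synthetic generator
#'
#' A [simulation_config()] emulating the design and empirical structure of
#' a 35-participant, 8-day event-contingent EMA study of the 15 TEMS
#' motives (~888 logged occasions in total): a trait-over-state elevation
#' bias of 0.53 scale points on 12 of the 15 motives, with `convenience`,
#' `visual_appeal` and `social_image` unbiased; moderate trait-state
#' coupling (0.5); and motive-specific within-person fluctuation
#' (low-fluctuation motives `traditional_eating`, `sociability`,
#' `weight_control`, `affect_regulation`; high-fluctuation motives
#' `health`, `convenience`, `pleasure`, `natural_concerns`,
#' `visual_appeal`).
#'
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @examples
#' cfg <- study_config()
#' cfg$n_participants
#' @export
study_config <- function(seed = 1L) {
  bias <- stats::setNames(rep(0.53, 15), tems_motives())
  bias[c("convenience", "visual_appeal", "social_image")] <- 0
  simulation_config(
    n_participants = 35,
    n_days = 8,
    events_per_day_mean = 3.2,
    elevation_bias = bias,
    trait_sd_between = 0.6,
    state_sd_within = 0.7,
    state_sd_within_per_motive = c(
      traditional_eating = 0.45, sociability = 0.45,
      weight_control = 0.45, affect_regulation = 0.45,
      health = 0.85, convenience = 0.85, pleasure = 0.85,
      natural_concerns = 0.85, visual_appeal = 0.85),
    trait_state_coupling = 0.5,
    seed = seed)
}

round_half_up <- function(x) floor(x + 0.5)

clamp_likert <- function(x, scale) {
  pmin(pmax(x, scale$min_value), scale$max_value)
}

#' Simulate a cohort
#'
#' Draws a full synthetic cohort (trait questionnaire plus EMA event log)
#' under the generative model described in [simulation_config()]. The
#' latent state level is constructed as a bias-shifted convex mixture of
#' the latent trait and an independent normal draw, calibrated so the
#' population trait-state correlation equals `trait_state_coupling`.
#' Identical config and seed give an identical dataset.
#'
#' @param config A [simulation_config()].
#' @return A [cohort_dataset()] with provenance `"simulated seed=<seed>"`.
#' @examples
#' d <- simulate_cohort(simulation_config(n_participants = 4, seed = 7))
#' d
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  k <- length(cfg$catalog)
  motives <- as.character(cfg$catalog)
  np <- cfg$n_participants
  mu <- cfg$motive_means
  c_ts <- cfg$trait_state_coupling

  ids <- sprintf("p%02d", seq_len(np))
  lambda <- matrix(stats::rnorm(np * k, mean = rep(mu, each = np),
                                sd = cfg$trait_sd_between), np, k)
  # eta = (mu - bias) + c*(lambda - mu) + sqrt(1-c^2)*sd_b*Z:
  # preserves Var(eta) = Var(lambda) and corr(lambda, eta) = c
  eta <- sweep(c_ts * sweep(lambda, 2, mu), 2, mu - cfg$elevation_bias, "+") +
    sqrt(1 - c_ts^2) *
    matrix(stats::rnorm(np * k, 0, cfg$trait_sd_between), np, k)

  trait_obs <- clamp_likert(round_half_up(lambda), cfg$scale)
  traits <- tibble::as_tibble(
    c(list(participant_id = ids),
      stats::setNames(lapply(seq_len(k), function(j) trait_obs[, j]),
                      motives)))

  lam_pois <- cfg$events_per_day_mean
  p0 <- stats::ppois(0, lam_pois)
  ev_list <- vector("list", np)
  for (p in seq_len(np)) {
    # zero-truncated Poisson events per day via inverse-cdf on (P(0), 1]
    n_by_day <- stats::qpois(stats::runif(cfg$n_days, p0, 1), lam_pois)
    ne <- sum(n_by_day)
    day <- rep(seq_len(cfg$n_days), n_by_day)
    meal <- sample(names(cfg$meal_type_probs), ne, replace = TRUE,
                   prob = cfg$meal_type_probs)
    noise <- matrix(stats::rnorm(ne * k, 0,
                                 rep(cfg$state_sd_within, each = ne)), ne, k)
    st <- clamp_likert(round_half_up(
      matrix(eta[p, ], ne, k, byrow = TRUE) + noise), cfg$scale)
    ev_list[[p]] <- tibble::as_tibble(
      c(list(participant_id = rep(ids[p], ne),
             day_index = as.integer(day), meal_type = meal),
        stats::setNames(lapply(seq_len(k), function(j) st[, j]), motives)))
  }
  events <- do.call(rbind, ev_list)
  cohort_dataset(traits, events, catalog = cfg$catalog, scale = cfg$scale,
                 provenance = sprintf("simulated seed=%d", cfg$seed),
                 strict = TRUE)
}
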