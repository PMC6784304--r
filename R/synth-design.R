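#' Condition factor names and levels
#'
#' The five binary factors that define an experimental condition: presence of
#' the platform rack, beaker size, kind of hand-over (signalled by the border
#' colour of the can), beaker content, and the side of the giver. Their full
#' factorial spans the 32 experimental conditions.
#'
#' @return Named list of length-2 character vectors (first level is the
#'   reference level).
#' @export
condition_levels <- function() {
  list(
    platform      = c("absent", "present"),
    beaker_size   = c("small", "big"),
    handover_kind = c("direct", "indirect"),
    content       = c("empty", "full"),
    giver_side    = c("left", "right")
  )
}

#' Generate the trial design for one giver/receiver pair
#'
#' Enumerates the full factorial over the five binary condition factors
#' (32 conditions), replicates each condition `replicates` times, and returns
#' the trials in seeded-random presentation order.
#'
#' @param replicates Number of trials per condition (the study used 3, for a
#'   total of 96 trials per pair).
#' @param seed Integer seed controlling the trial order.
#' @return A tibble with one row per trial: `trial_index`, the five condition
#'   columns, `condition_id` (1--32), and `replicate`.
#' @export
#' @examples
#' d <- generate_design(replicates = 3, seed = 1)
#' nrow(d)                      # 96
#' dplyr::n_distinct(d$condition_id)  # 32
generate_design <- function(replicates = 3, seed = 1) {
  if (!is.numeric(replicates) || length(replicates) != 1 ||
      is.na(replicates) || replicates < 1) {
    abort("`replicates` must be a single integer >= 1.",
          class = "handovr_invalid_argument")
  }
  replicates <- as.integer(replicates)
  lv <- condition_levels()
  full <- tidyr::expand_grid(
    platform      = lv$platform,
    beaker_size   = lv$beaker_size,
    handover_kind = lv$handover_kind,
    content       = lv$content,
    giver_side    = lv$giver_side
  ) |>
    dplyr::mutate(condition_id = dplyr::row_number())
  design <- tidyr::expand_grid(full, replicate = seq_len(replicates))
  ord <- with_seed(substream_seed(seed, "design-order"),
                   sample.int(nrow(design)))
  design |>
    dplyr::slice(ord) |>
    dplyr::mutate(trial_index = dplyr::row_number(), .before = 1)
}

# Reference distributions used both to draw plausible profile fields and to
# standardize them when injecting trait effects (so a single profile can be
# z-scored without seeing the rest of the cohort).
profile_field_reference <- function() {
  tibble::tribble(
    ~field,              ~mean, ~sd,
    "age",                40,    18,
    "body_size",          1.72,  0.07,
    "weight",             68,    7,
    "sportiness",         3.4,   2.1,
    "satiety",            2.5,   1.3,
    "familiarity",        2,     1.8,
    "openness",           50,    28,
    "conscientiousness",  59,    21,
    "extraversion",       42,    15,
    "agreeableness",      54,    28,
    "neuroticism",        24,    8
  )
}

#' Generate synthetic participant profiles
#'
#' Draws `n` participant profiles with physical, cultural and Big Five
#' personality fields from plausible ranges. Participants are analysed in
#' giver/receiver pairs, so `n` must be even; consecutive profiles
#' (1,2), (3,4), ... form the pairs.
#'
#' @param n Number of participants (even, >= 2).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A tibble with one row per participant: `identity`, `gender`, `age`
#'   (years), `body_size` (m), `weight` (kg), `profession`, `sportiness`
#'   (hours/week), `satiety` (hours since last meal), `familiarity` (1--5),
#'   `health` ("yes" = problems with arm/shoulder/hand), and the five Big Five
#'   scores in \[0, 100\].
#' @export
generate_participants <- function(n = 8, seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 2 || n %% 2 != 0) {
    abort("`n` must be a single even integer >= 2 (participants are paired).",
          class = "handovr_invalid_argument")
  }
  n <- as.integer(n)
  ref <- profile_field_reference()
  with_seed(substream_seed(seed, "participants"), {
    draw <- function(field, lo, hi, digits = 1) {
      r <- ref[ref$field == field, ]
      pmin(hi, pmax(lo, round(rnorm(n, r$mean, r$sd), digits)))
    }
    fam <- sample(1:5, n / 2, replace = TRUE, prob = c(.5, .15, .1, .1, .15))
    tibble::tibble(
      identity   = paste0("P", seq_len(n)),
      gender     = sample(c("male", "female"), n, replace = TRUE),
      age        = draw("age", 18, 90, 0),
      body_size  = draw("body_size", 1.50, 2.00, 2),
      weight     = draw("weight", 45, 110, 1),
      profession = sample(c("student", "staff", "pensioner", "housekeeper"),
                          n, replace = TRUE, prob = c(.55, .2, .15, .1)),
      sportiness = draw("sportiness", 0, 15, 1),
      satiety    = draw("satiety", 0, 12, 1),
      familiarity = rep(fam, each = 2),  # shared within a pair
      health     = sample(c("no", "yes"), n, replace = TRUE, prob = c(.75, .25)),
      openness          = draw("openness", 0, 100, 0),
      conscientiousness = draw("conscientiousness", 0, 100, 0),
      extraversion      = draw("extraversion", 0, 100, 0),
      agreeableness     = draw("agreeableness", 0, 100, 0),
      neuroticism       = draw("neuroticism", 0, 100, 0)
    )
  })
}

#' Generator configuration
#'
#' Bundles the knobs of the synthetic trajectory generator. The effect-scale
#' hierarchy `sigma_identity > sigma_condition > sigma_trait` encodes the
#' hypothesis that who moves dominates what is moved, which in turn dominates
#' stable personal traits. All scales are in radians.
#'
#' @param n_pairs Number of giver/receiver pairs (default 4, i.e. 8 valid
#'   participants).
#' @param replicates Trials per condition per pair (default 3, i.e. 96 trials).
#' @param sigma_identity Scale of the per-participant motion signature.
#' @param sigma_condition Scale of the additive per-factor condition effects.
#' @param sigma_trait Scale of the trait-linked components (linear in the
#'   standardized profile fields).
#' @param sigma_noise Scale of i.i.d. measurement noise per sample.
#' @param warp_jitter Amplitude of the smooth monotone time warp, as a
#'   fraction of the trajectory duration.
#' @param failure_rate Per-trial probability of a tracking failure
#'   (hand-swap); scalar, or one value per participant.
#' @param t_range Integer range from which the number of time steps of each
#'   trial is sampled.
#' @param dt Seconds per sample.
#' @param seed Integer master seed, fanned out to all substreams.
#' @return A list of class `handovr_generator_config`.
#' @export
generator_config <- function(n_pairs = 4, replicates = 3,
                             sigma_identity = 0.6, sigma_condition = 0.25,
                             sigma_trait = 0.08, sigma_noise = 0.05,
                             warp_jitter = 0.1, failure_rate = 0,
                             t_range = c(80L, 120L), dt = 0.01, seed = 1) {
  cfg <- list(
    n_pairs = as.integer(n_pairs), replicates = as.integer(replicates),
    sigma_identity = sigma_identity, sigma_condition = sigma_condition,
    sigma_trait = sigma_trait, sigma_noise = sigma_noise,
    warp_jitter = warp_jitter, failure_rate = failure_rate,
    t_range = as.integer(t_range), dt = dt, seed = as.integer(seed)
  )
  scales <- c(cfg$sigma_identity, cfg$sigma_condition, cfg$sigma_trait,
              cfg$sigma_noise, cfg$warp_jitter)
  if (any(!is.finite(scales)) || any(scales < 0)) {
    abort("all effect scales and `warp_jitter` must be finite and >= 0.",
          class = "handovr_invalid_argument")
  }
  if (any(cfg$failure_rate < 0 | cfg$failure_rate > 1)) {
    abort("`failure_rate` must lie in [0, 1].",
          class = "handovr_invalid_argument")
  }
  if (cfg$replicates < 1 || cfg$n_pairs < 1) {
    abort("`n_pairs` and `replicates` must be >= 1.",
          class = "handovr_invalid_argument")
  }
  if (length(cfg$t_range) != 2 || any(cfg$t_range < 2) ||
      cfg$t_range[1] > cfg$t_range[2]) {
    abort("`t_range` must be an increasing pair of integers >= 2.",
          class = "handovr_invalid_argument")
  }
  structure(cfg, class = "handovr_generator_config")
}
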