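#' @rdname generate_trajectory
#' @export
N_ANGLE_CHANNELS <- 20L

# Smooth reach-grasp-release base profile per channel, evaluated at
# normalized time s in [0, 1]. Channel constants are fixed so the template is
# identical across runs; 4 degrees of freedom per digit, 5 digits.
base_template <- function(s, n_channels = N_ANGLE_CHANNELS) {
  ch <- seq_len(n_channels)
  center <- 0.35 + 0.3 * (ch - 1) / (n_channels - 1)
  amp <- 0.8 + 0.3 * sin(ch)
  offset <- 0.2 + 0.02 * ch
  out <- matrix(0, length(s), n_channels)
  for (c in ch) {
    reach <- exp(-(s - center[c])^2 / (2 * 0.18^2))
    release <- 0.35 * exp(-(s - 0.85)^2 / (2 * 0.1^2))
    out[, c] <- offset[c] + amp[c] * reach - amp[c] * release
  }
  out
}

# Per-participant signature: channel offsets plus a random-centered bell per
# channel, drawn once from the participant's substream; scale sigma_identity.
identity_signature <- function(s, identity, cfg) {
  with_seed(substream_seed(cfg$seed, "identity", identity), {
    off <- rnorm(N_ANGLE_CHANNELS, 0, 1)
    amp <- rnorm(N_ANGLE_CHANNELS, 0, 1)
    ctr <- runif(N_ANGLE_CHANNELS, 0.2, 0.8)
    sig <- matrix(0, length(s), N_ANGLE_CHANNELS)
    for (c in seq_len(N_ANGLE_CHANNELS)) {
      sig[, c] <- off[c] + amp[c] * exp(-(s - ctr[c])^2 / (2 * 0.2^2))
    }
    cfg$sigma_identity * sig
  })
}

# Additive smooth shape component for one condition factor; the factor level
# flips its sign. giver_side is excluded here: it acts by inverting the
# temporal profile (role flip), not additively.
condition_component <- function(s, factor_name, cfg) {
  with_seed(substream_seed(cfg$seed, "condition", factor_name), {
    a1 <- rnorm(N_ANGLE_CHANNELS, 0, 1)
    a2 <- rnorm(N_ANGLE_CHANNELS, 0, 1)
    comp <- matrix(0, length(s), N_ANGLE_CHANNELS)
    for (c in seq_len(N_ANGLE_CHANNELS)) {
      comp[, c] <- a1[c] * sin(pi * s) + a2[c] * sin(2 * pi * s)
    }
    cfg$sigma_condition * comp
  })
}

trait_fields <- function() profile_field_reference()$field

# Trait effect: linear in the standardized profile fields, each field with
# its own fixed channel loading and temporal shape.
trait_component <- function(s, profile, cfg) {
  if (cfg$sigma_trait == 0) return(matrix(0, length(s), N_ANGLE_CHANNELS))
  ref <- profile_field_reference()
  comp <- matrix(0, length(s), N_ANGLE_CHANNELS)
  for (i in seq_len(nrow(ref))) {
    f <- ref$field[i]
    z <- (as.numeric(profile[[f]]) - ref$mean[i]) / ref$sd[i]
    load <- with_seed(substream_seed(cfg$seed, "trait", f), {
      list(l = rnorm(N_ANGLE_CHANNELS, 0, 1), ph = runif(1, 0, pi))
    })
    shape <- sin(pi * s + load$ph)
    comp <- comp + z * outer(shape, load$l)
  }
  cfg$sigma_trait * comp / sqrt(nrow(ref))
}

# Smooth monotone warp of normalized time with amplitude `jitter`;
# fixed endpoints u(0)=0, u(1)=1.
monotone_warp <- function(s, jitter, a1, a2) {
  u <- s + jitter * (a1 * sin(pi * s) + a2 * sin(2 * pi * s)) / 2
  u <- cummax(u)                       # enforce monotonicity for large jitter
  (u - u[1]) / (u[length(u)] - u[1])
}

#' Generate one synthetic joint-angle trajectory
#'
#' Builds the time course of the 20 hand joint angles for one participant's
#' hand in one trial: a smooth reach--grasp--release template plus a
#' participant signature (fixed across that participant's trials), additive
#' condition effects, trait-linked components, and i.i.d. noise, evaluated on
#' a smoothly time-warped grid. A receiver's trajectory uses the time-inverted
#' template, so flipping the side of the giver inverts the temporal profile.
#'
#' @param trial One row of a design tibble (see [generate_design()]), with the
#'   five condition columns and `trial_index`.
#' @param profile One row of a participant tibble (see
#'   [generate_participants()]).
#' @param role `"giver"` or `"receiver"`.
#' @param cfg A [generator_config()].
#' @return A `joint_trajectory`: list with `values` (T x 20 matrix, radians),
#'   `dt`, `trial_index`, `owner_id`, `role`.
#' @export
generate_trajectory <- function(trial, profile, role = c("giver", "receiver"),
                                cfg = generator_config()) {
  role <- match.arg(role)
  stopifnot(inherits(cfg, "handovr_generator_config"))
  tr_seed <- substream_seed(cfg$seed, "trial", trial$trial_index, role,
                            profile$identity)
  n_t <- with_seed(substream_seed(tr_seed, "length"), {
    if (cfg$t_range[1] == cfg$t_range[2]) cfg$t_range[1]
    else sample(seq(cfg$t_range[1], cfg$t_range[2]), 1)
  })
  s <- seq(0, 1, length.out = n_t)
  u <- if (cfg$warp_jitter > 0) {
    ab <- with_seed(substream_seed(tr_seed, "warp"), runif(2, -1, 1))
    monotone_warp(s, cfg$warp_jitter, ab[1], ab[2])
  } else s
  s_eval <- if (role == "receiver") 1 - u else u

  vals <- base_template(s_eval) +
    identity_signature(s_eval, profile$identity, cfg) +
    trait_component(s_eval, profile, cfg)
  for (f in setdiff(names(condition_levels()), "giver_side")) {
    lev <- condition_levels()[[f]]
    sign <- if (as.character(trial[[f]]) == lev[1]) -1 else 1
    vals <- vals + sign * condition_component(s_eval, f, cfg)
  }
  if (cfg$sigma_noise > 0) {
    vals <- vals + with_seed(substream_seed(tr_seed, "noise"),
                             matrix(rnorm(n_t * N_ANGLE_CHANNELS, 0, cfg$sigma_noise),
                                    n_t, N_ANGLE_CHANNELS))
  }
  colnames(vals) <- sprintf("a%02d", seq_len(N_ANGLE_CHANNELS))
  structure(
    list(values = vals, dt = cfg$dt, trial_index = trial$trial_index,
         owner_id = profile$identity, role = role),
    class = "joint_trajectory"
  )
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf("<joint_trajectory> %s (%s), trial %d: %d steps x %d channels, dt = %g s\n",
              x$owner_id, x$role, x$trial_index, nrow(x$values),
              ncol(x$values), x$dt))
  invisible(x)
}

#' Generate a complete synthetic hand-over dataset
#'
#' Draws participant profiles, builds a randomized full-factorial design per
#' pair, generates giver and receiver hand trajectories for every trial, and
#' flags tracking failures. Consecutive participants (1,2), (3,4), ... form
#' the giver/receiver pairs; within a pair the first (left-seated) participant
#' is the giver whenever `giver_side == "left"`.
#'
#' @param cfg A [generator_config()].
#' @return A `handover_dataset`: list with tibbles `participants`, `trials`
#'   (one row per trial: `trial_id`, `pair_id`, condition columns, `giver_id`,
#'   `receiver_id`, `replicate`, `valid`), `trajectories` (one row per
#'   trial-and-hand with the T x 20 matrix in the `angles` list-column), and
#'   the `config`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_pairs = 1, replicates = 1, seed = 7))
#' nrow(ds$trials)        # 32
#' nrow(ds$trajectories)  # 64: giver and receiver hand per trial
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "handovr_generator_config"))
  n_part <- 2L * cfg$n_pairs
  participants <- generate_participants(n_part, substream_seed(cfg$seed, "profiles"))
  fr <- rep_len(cfg$failure_rate, n_part)

  trials_l <- list()
  trajs_l <- list()
  for (p in seq_len(cfg$n_pairs)) {
    left <- participants[2L * p - 1L, ]
    right <- participants[2L * p, ]
    design <- generate_design(cfg$replicates,
                              seed = substream_seed(cfg$seed, "pair-design", p))
    pair_fail <- max(fr[2L * p - 1L], fr[2L * p])
    valid <- with_seed(substream_seed(cfg$seed, "failures", p),
                       runif(nrow(design)) >= pair_fail)
    trials <- design |>
      dplyr::mutate(
        pair_id = paste0("pair", p),
        trial_id = sprintf("%s_t%03d", .data$pair_id, .data$trial_index),
        giver_id = ifelse(.data$giver_side == "left", left$identity, right$identity),
        receiver_id = ifelse(.data$giver_side == "left", right$identity, left$identity),
        valid = valid
      )
    trials_l[[p]] <- trials
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      for (role in c("giver", "receiver")) {
        owner <- if (role == "giver") tr$giver_id else tr$receiver_id
        prof <- participants[participants$identity == owner, ]
        traj <- generate_trajectory(tr, prof, role, cfg)
        trajs_l[[length(trajs_l) + 1L]] <- tibble::tibble(
          traj_id = paste0(tr$trial_id, "_", role),
          trial_id = tr$trial_id, pair_id = tr$pair_id,
          owner_id = owner, role = role,
          n_steps = nrow(traj$values), angles = list(traj$values)
        )
      }
    }
  }
  structure(
    list(participants = participants,
         trials = dplyr::bind_rows(trials_l),
         trajectories = dplyr::bind_rows(trajs_l),
         config = cfg),
    class = "handover_dataset"
  )
}

#' @export
print.handover_dataset <- function(x, ...) {
  cat(sprintf(
    "<handover_dataset> %d participants, %d trials (%d valid), %d trajectories\n",
    nrow(x$participants), nrow(x$trials), sum(x$trials$valid),
    nrow(x$trajectories)))
  invisible(x)
}

#' Apply the study's validity filter
#'
#' Drops every trial of any participant whose fraction of tracking-failed
#' trials exceeds `threshold` (a hand-swap failure corrupts both hands, so
#' both members of a failing pair are excluded together, as happened to the
#' study's subjects 7 and 8), then drops any remaining individually flagged
#' trials.
#'
#' @param dataset A `handover_dataset`.
#' @param threshold Maximum tolerated failure fraction per participant.
#' @return The filtered `handover_dataset`, with an `exclusions` tibble
#'   logging excluded participants and dropped trial counts.
#' @export
filter_valid <- function(dataset, threshold = 0.5) {
  stopifnot(inherits(dataset, "handover_dataset"))
  tr <- dataset$trials
  if (!"valid" %in% names(tr)) {
    abort("trials carry no `valid` flag.", class = "handovr_invalid_argument")
  }
  frac <- tr |>
    tidyr::pivot_longer(c("giver_id", "receiver_id"), values_to = "participant") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(failure_fraction = mean(!.data$valid), .groups = "drop")
  excluded <- frac$participant[frac$failure_fraction > threshold]
  keep <- tr |>
    dplyr::filter(!.data$giver_id %in% excluded,
                  !.data$receiver_id %in% excluded,
                  .data$valid)
  if (nrow(keep) == 0) {
    abort("no valid trials remain after filtering.", class = "handovr_empty_data")
  }
  out <- dataset
  out$trials <- keep
  out$trajectories <- dataset$trajectories |>
    dplyr::filter(.data$trial_id %in% keep$trial_id)
  out$participants <- dataset$participants |>
    dplyr::filter(!.data$identity %in% excluded)
  out$exclusions <- frac |>
    dplyr::mutate(excluded = .data$participant %in% excluded)
  out
}
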