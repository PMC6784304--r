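test_that("the design enumerates the full factorial with equal replicates", {
  for (r in c(1L, 3L)) {
    d <- generate_design(replicates = r, seed = 11)
    expect_equal(nrow(d), 32L * r)
    counts <- dplyr::count(d, condition_id)
    expect_equal(nrow(counts), 32L)
    expect_true(all(counts$n == r))
    # balance: every factor carries each level on exactly half the trials
    for (f in names(condition_levels())) {
      expect_equal(as.integer(table(d[[f]])), rep(16L * r, 2L))
    }
  }
  expect_error(generate_design(replicates = 0), class = "handovr_invalid_argument")
})

test_that("the design order is seeded and reproducible", {
  expect_identical(generate_design(3, seed = 5), generate_design(3, seed = 5))
  expect_false(identical(generate_design(3, seed = 5)$condition_id,
                         generate_design(3, seed = 6)$condition_id))
})

test_that("participant profiles satisfy their invariants and determinism", {
  p <- generate_participants(8, seed = 1)
  expect_equal(nrow(p), 8L)
  big5 <- c("openness", "conscientiousness", "extraversion", "agreeableness",
            "neuroticism")
  for (b in big5) expect_true(all(p[[b]] >= 0 & p[[b]] <= 100))
  expect_true(all(p$familiarity %in% 1:5))
  for (f in c("age", "body_size", "weight", "sportiness", "satiety")) {
    expect_true(all(p[[f]] >= 0))
  }
  expect_identical(p, generate_participants(8, seed = 1))
  expect_error(generate_participants(3), class = "handovr_invalid_argument")
  expect_error(generate_participants(0), class = "handovr_invalid_argument")
})

test_that("trajectories have 20 finite channels and a deterministic signature", {
  cfg <- generator_config(n_pairs = 1, replicates = 1, seed = 2)
  ds <- generate_dataset(cfg)
  expect_true(all(ds$trajectories$n_steps >= 2))
  for (m in ds$trajectories$angles[1:4]) {
    expect_equal(ncol(m), 20L)
    expect_true(all(is.finite(m)))
  }
  # regenerating the same dataset is bit-identical
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$trajectories$angles, ds2$trajectories$angles)
})

test_that("with all effects and warping off, same-role trajectories coincide", {
  cfg <- generator_config(n_pairs = 1, replicates = 1,
                          sigma_identity = 0, sigma_condition = 0,
                          sigma_trait = 0, sigma_noise = 0, warp_jitter = 0,
                          t_range = c(100L, 100L), seed = 4)
  ds <- generate_dataset(cfg)
  givers <- ds$trajectories$angles[ds$trajectories$role == "giver"]
  expect_gt(length(givers), 1)
  for (m in givers[-1]) expect_equal(m, givers[[1]])
  receivers <- ds$trajectories$angles[ds$trajectories$role == "receiver"]
  for (m in receivers[-1]) expect_equal(m, receivers[[1]])
  # the receiver profile is the time inversion of the giver profile
  expect_equal(receivers[[1]], givers[[1]][100:1, ], ignore_attr = TRUE)
})

test_that("a participant's signature is fixed across trials", {
  cfg <- generator_config(n_pairs = 1, replicates = 2,
                          sigma_condition = 0, sigma_trait = 0,
                          sigma_noise = 0, warp_jitter = 0,
                          t_range = c(90L, 90L), seed = 9)
  ds <- generate_dataset(cfg)
  one <- dplyr::filter(ds$trajectories, owner_id == "P1", role == "giver")
  for (m in one$angles[-1]) expect_equal(m, one$angles[[1]])
})

test_that("identity dominates within/between DTW distances when sigma_identity >> noise", {
  ds <- hierarchy_dataset(seed = 21)
  idx <- which(ds$trajectories$role == "giver")[1:40]
  D <- distance_matrix(ds$trajectories[idx, ])
  owners <- ds$trajectories$owner_id[idx]
  within <- between <- c()
  for (i in seq_along(idx)) {
    for (j in seq_len(i - 1)) {
      d <- D[i, j]
      if (owners[i] == owners[j]) within <- c(within, d) else between <- c(between, d)
    }
  }
  expect_lt(mean(within), mean(between))
})

test_that("the between/within distance ratio follows the effect hierarchy", {
  cfg <- generator_config(n_pairs = 2, replicates = 1,
                          sigma_identity = 0.6, sigma_condition = 0.25,
                          sigma_trait = 0.05, sigma_noise = 0.05,
                          warp_jitter = 0.1, t_range = c(60L, 80L), seed = 31)
  ds <- generate_dataset(cfg)
  D <- distance_matrix(ds$trajectories)
  labels <- handovr:::factor_label_table(ds)
  r_identity <- group_distance_ratio(D, labels$identity)
  r_condition <- group_distance_ratio(D, labels$content, labels$owner_id,
                                      "same_owner")
  # trait grouping: median split of a trait-linked field, on cross-subject
  # pairs so the identity signature cancels
  r_trait <- group_distance_ratio(D, labels$openness > median(labels$openness),
                                  labels$owner_id, "diff_owner")
  expect_gt(r_identity, r_condition)
  expect_gt(r_condition, r_trait)
})

test_that("the validity filter excludes failing participants pairwise", {
  cfg <- generator_config(n_pairs = 5, replicates = 1,
                          t_range = c(10L, 12L), sigma_noise = 0.01,
                          failure_rate = c(rep(0, 8), 1, 1), seed = 3)
  ds <- generate_dataset(cfg)
  filtered <- filter_valid(ds, threshold = 0.5)
  expect_equal(nrow(filtered$participants), 8L)
  expect_setdiff <- setdiff(ds$participants$identity,
                            filtered$participants$identity)
  expect_equal(sort(expect_setdiff), c("P10", "P9"))
  expect_true(all(filtered$trials$valid))
  expect_equal(sum(filtered$exclusions$excluded), 2L)

  # no failures: the filter is the identity mapping
  cfg0 <- generator_config(n_pairs = 1, replicates = 1, t_range = c(10L, 12L),
                           seed = 3)
  ds0 <- generate_dataset(cfg0)
  expect_identical(filter_valid(ds0)$trials, ds0$trials)

  # everyone failing: empty-data error
  cfg_all <- generator_config(n_pairs = 1, replicates = 1,
                              t_range = c(10L, 12L), failure_rate = 1, seed = 3)
  expect_error(filter_valid(generate_dataset(cfg_all)),
               class = "handovr_empty_data")
})
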