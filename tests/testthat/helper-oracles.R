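# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the DTW oracle enumerates warping paths
# explicitly, the isotonic oracle is base R's isoreg.

# Exhaustive enumeration of all monotone warping paths from (1,1) to (n,m)
# with unit steps; returns the minimal accumulated Euclidean cost.
dtw_enumerate <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + cost(i, j)
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# Random short multivariate trajectory for oracle comparisons.
random_traj <- function(t_len, k, sd = 1) {
  matrix(rnorm(t_len * k, sd = sd), t_len, k)
}

# Small synthetic dataset with a configurable effect hierarchy, used by the
# classification / MANOVA hierarchy checks.
hierarchy_dataset <- function(seed, n_pairs = 2, replicates = 1,
                              sigma_trait = 0) {
  cfg <- generator_config(
    n_pairs = n_pairs, replicates = replicates,
    sigma_identity = 0.6, sigma_condition = 0.25, sigma_trait = sigma_trait,
    sigma_noise = 0.05, warp_jitter = 0.1, t_range = c(60L, 80L), seed = seed
  )
  filter_valid(generate_dataset(cfg))
}

# Mean between-group over mean within-group DTW distance for a grouping
# vector. `pair_filter` restricts which trajectory pairs enter: grouping by a
# within-subject factor is isolated on same-owner pairs, grouping by a
# subject-level trait on different-owner pairs (otherwise the identity
# signature leaks into the ratio).
group_distance_ratio <- function(D, groups, owners = NULL,
                                 pair_filter = c("all", "same_owner",
                                                 "diff_owner")) {
  pair_filter <- match.arg(pair_filter)
  D <- unclass(D)
  use <- upper.tri(D)
  if (pair_filter != "all") {
    same_owner <- outer(owners, owners, "==")
    use <- use & (if (pair_filter == "same_owner") same_owner else !same_owner)
  }
  same_group <- outer(groups, groups, "==")
  within <- mean(D[use & same_group])
  between <- mean(D[use & !same_group])
  between / within
}
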