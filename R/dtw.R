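#' Dynamic time warping distance between two joint-angle trajectories
#'
#' Minimal accumulated cost over monotone warping paths from the first to the
#' last sample pair, with unit steps (diagonal, horizontal, vertical). The
#' local cost is the unsquared Euclidean norm of the 20-dimensional angle
#' difference, so the distance keeps the units of the angles (radians).
#'
#' @param a,b Joint trajectories: `joint_trajectory` objects or plain
#'   T x k numeric matrices with matching channel counts.
#' @param band Optional Sakoe--Chiba band half-width (samples) around the
#'   stretched diagonal; `NULL` (default) imposes no constraint.
#' @param normalize If `TRUE`, divide the accumulated cost by the length of
#'   the optimal warping path. Off by default: the downstream nonmetric
#'   embedding only uses distance ranks, and with roughly equal trajectory
#'   lengths normalization acts monotonically.
#' @param standardize If `TRUE`, z-score each channel (pooled over both
#'   trajectories) before computing costs. Off by default: channels are
#'   commensurable (all radians).
#' @return A single non-negative number.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' dtw_distance(x, x)  # 0
dtw_distance <- function(a, b, band = NULL, normalize = FALSE,
                         standardize = FALSE) {
  ma <- traj_matrix(a)
  mb <- traj_matrix(b)
  if (ncol(ma) != ncol(mb)) {
    abort(sprintf("channel count mismatch: %d vs %d.", ncol(ma), ncol(mb)),
          class = "handovr_invalid_argument")
  }
  if (standardize) {
    st <- channel_standardizer(list(ma, mb))
    ma <- st(ma); mb <- st(mb)
  }
  .dtw_pair_cpp(ma, mb, band %||% -1L, normalize)
}

traj_matrix <- function(x) {
  m <- if (inherits(x, "joint_trajectory")) x$values else x
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) < 1) {
    abort("a trajectory must be a numeric matrix with at least one row.",
          class = "handovr_invalid_argument")
  }
  if (any(!is.finite(m))) {
    abort("trajectory contains non-finite values.",
          class = "handovr_invalid_argument")
  }
  m
}

channel_standardizer <- function(mats) {
  pooled <- do.call(rbind, mats)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, sd)
  sdv[sdv == 0] <- 1
  function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
}

#' Pairwise DTW distance matrix of a trajectory set
#'
#' Computes [dtw_distance()] for every pair; the upper triangle is computed
#' once and mirrored, so the result is exactly symmetric with a zero
#' diagonal. The full-study-scale problem (hundreds of trajectories of ~100
#' samples) runs in well under a minute through the compiled core.
#'
#' @param trajs Either the `trajectories` tibble of a [generate_dataset()]
#'   result (matrices in an `angles` list-column, labels in `traj_id`) or a
#'   plain list of T x k matrices.
#' @param labels Optional character labels (defaults to `traj_id` or names).
#' @inheritParams dtw_distance
#' @return A `trajectory_dist`: a symmetric numeric matrix with the labels as
#'   dimnames.
#' @export
distance_matrix <- function(trajs, labels = NULL, band = NULL,
                            normalize = FALSE, standardize = FALSE) {
  if (is.data.frame(trajs)) {
    labels <- labels %||% trajs$traj_id
    trajs <- trajs$angles
  }
  if (!is.list(trajs) || length(trajs) < 2) {
    abort("need at least two trajectories.", class = "handovr_invalid_argument")
  }
  mats <- lapply(trajs, traj_matrix)
  k <- vapply(mats, ncol, 1L)
  if (length(unique(k)) != 1) {
    abort("all trajectories must share the channel count.",
          class = "handovr_invalid_argument")
  }
  if (standardize) {
    st <- channel_standardizer(mats)
    mats <- lapply(mats, st)
  }
  D <- .dtw_pairwise_cpp(mats, band %||% -1L, normalize)
  labels <- labels %||% names(trajs) %||% paste0("traj", seq_along(mats))
  dimnames(D) <- list(labels, labels)
  structure(D, class = c("trajectory_dist", "matrix", "array"))
}

#' @export
print.trajectory_dist <- function(x, ...) {
  cat(sprintf("<trajectory_dist> %d x %d DTW dissimilarities (radians)\n",
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))])
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Write / read a distance matrix as delimited text
#'
#' Square comma-separated layout with the trajectory labels as header row and
#' first column.
#'
#' @param D A `trajectory_dist` (or symmetric matrix with dimnames).
#' @param path File path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns a `trajectory_dist`.
#' @export
write_distance_matrix <- function(D, path) {
  df <- tibble::as_tibble(unclass(D), .name_repair = "minimal") |>
    dplyr::mutate(label = rownames(D), .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$label
  colnames(m) <- names(df)[-1]
  storage.mode(m) <- "double"
  structure(m, class = c("trajectory_dist", "matrix", "array"))
}
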