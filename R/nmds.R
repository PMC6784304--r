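#' Classical (Torgerson) scaling initialization
#'
#' Double-centers the squared dissimilarities and takes the top-`dim`
#' spectral coordinates; contributions of negative eigenvalues are truncated
#' to zero. Used as the default starting configuration of [nmds_embed()].
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param dim Target dimensionality (must be <= n - 1).
#' @return An n x `dim` coordinate matrix.
#' @export
classical_scaling_init <- function(D, dim) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (dim > n - 1 || dim < 1) {
    abort("`dim` must lie in [1, n - 1].", class = "handovr_invalid_argument")
  }
  # cmdscale warns when fewer than `dim` positive eigenvalues exist (e.g. a
  # degenerate all-zero D); the truncation below handles that case
  X <- suppressWarnings(cmdscale(D, k = dim))
  # cmdscale drops all-zero trailing axes (e.g. an all-zero D); pad them back
  if (ncol(X) < dim) {
    X <- cbind(X, matrix(0, n, dim - ncol(X)))
  }
  unname(X)
}

#' Kruskal's normalized stress-1
#'
#' `sqrt( sum_(i<j) (d_ij - dhat_ij)^2 / sum_(i<j) d_ij^2 )`, where `d` are
#' the configuration (Euclidean) distances and `dhat` the disparities: the
#' stress normalized by the sum of squares of the inter-point distances.
#'
#' @param coords n x d configuration.
#' @param disparities Symmetric matrix (or `dist`) of target disparities.
#' @return A single number >= 0.
#' @export
stress1 <- function(coords, disparities) {
  d <- as.vector(dist(coords))
  dh <- if (inherits(disparities, "dist")) as.vector(disparities)
        else as.vector(as.dist(as.matrix(disparities)))
  denom <- sum(d^2)
  if (denom == 0) {
    abort("all-zero configuration: stress-1 normalization undefined.",
          class = "handovr_undefined_normalization")
  }
  sqrt(sum((d - dh)^2) / denom)
}

#' Least-squares monotone (isotonic) regression
#'
#' Pool-adjacent-violators fit of the configuration distances as a
#' non-decreasing function of the dissimilarity rank, yielding the
#' disparities of nonmetric MDS. Ties in the dissimilarities follow
#' Kruskal's primary approach: tied values are mutually unconstrained
#' (within a tie block the distances are pre-sorted, so the block can be
#' fitted exactly).
#'
#' @param dissims Numeric vector of dissimilarities (defines the order).
#' @param distances Numeric vector of configuration distances (the values to
#'   be fitted), same length.
#' @return Numeric vector of disparities in the original element order.
#' @export
monotone_regression <- function(dissims, distances) {
  stopifnot(length(dissims) == length(distances))
  ord <- order(dissims, distances)
  fit <- .pava_cpp(distances[ord])
  out <- numeric(length(distances))
  out[ord] <- fit
  out
}

#' NMDS configuration
#'
#' @param dim Embedding dimensionality.
#' @param max_iter Iteration cap (default 200).
#' @param tol_fun Stop when the stress decrease falls below this (default 1e-4).
#' @param tol_x Stop when the maximum coordinate change falls below this
#'   (default 1e-4). Either tolerance terminates.
#' @param replicates Number of restarts; the best (lowest-stress) solution is
#'   kept (default 1).
#' @param init `"cmdscale"` (classical scaling start) or `"random"`.
#' @param seed Seed for random restarts.
#' @return List of class `handovr_nmds_config`.
#' @export
nmds_config <- function(dim = 3, max_iter = 200, tol_fun = 1e-4, tol_x = 1e-4,
                        replicates = 1, init = c("cmdscale", "random"),
                        seed = 1) {
  init <- match.arg(init)
  if (tol_fun <= 0 || tol_x <= 0 || max_iter < 1 || replicates < 1 || dim < 1) {
    abort("invalid NMDS configuration.", class = "handovr_invalid_argument")
  }
  structure(list(dim = as.integer(dim), max_iter = as.integer(max_iter),
                 tol_fun = tol_fun, tol_x = tol_x,
                 replicates = as.integer(replicates), init = init,
                 seed = as.integer(seed)),
            class = "handovr_nmds_config")
}

#' Nonmetric multidimensional scaling under stress-1
#'
#' Alternates Kruskal's monotone regression (disparities) with a
#' SMACOF-style majorization update of the configuration (Guttman transform
#' toward the disparities), starting from classical scaling or a random
#' configuration. An iteration is accepted only if it does not increase
#' stress-1, so the reported stress sequence is non-increasing; iteration
#' stops when the stress change drops below `tol_fun`, the maximum
#' coordinate change drops below `tol_x`, or `max_iter` is reached.
#'
#' @param D Dissimilarity matrix (`trajectory_dist` or symmetric matrix).
#' @param cfg An [nmds_config()]; or pass `dim` etc. via `...`.
#' @param ... Shorthand: arguments forwarded to [nmds_config()] when `cfg`
#'   is missing.
#' @return A `handover_nmds` object: `coords` (n x d, labelled rows),
#'   `stress`, `dim`, `n_iter`, `converged`, `stress_trace`.
#' @export
#' @examples
#' pts <- matrix(rnorm(20), 10, 2)
#' emb <- nmds_embed(as.matrix(dist(pts)), dim = 2)
#' emb$stress   # ~0: exactly Euclidean input
nmds_embed <- function(D, cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- nmds_config(...)
  stopifnot(inherits(cfg, "handovr_nmds_config"))
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  if (n < 2 || !isTRUE(all.equal(Dm, t(Dm))) || any(diag(Dm) != 0)) {
    abort("`D` must be a symmetric dissimilarity matrix with zero diagonal.",
          class = "handovr_invalid_argument")
  }
  labels <- rownames(Dm) %||% paste0("obs", seq_len(n))
  delta <- as.vector(as.dist(Dm))
  ord <- order(delta)          # fixed across iterations

  run_once <- function(X) {
    stress_trace <- numeric(0)
    d <- as.vector(dist(X))
    dh <- monotone_regression(delta, d)
    stress <- stress1_vec(d, dh)
    stress_trace <- stress
    converged <- FALSE
    iter <- 0L
    while (iter < cfg$max_iter) {
      iter <- iter + 1L
      X_new <- guttman_update(X, dh, n)
      d_new <- as.vector(dist(X_new))
      dh_new <- monotone_regression(delta, d_new)
      stress_new <- stress1_vec(d_new, dh_new)
      if (!is.finite(stress_new) || stress_new > stress + 1e-12) {
        converged <- TRUE      # majorization stalled; keep the last accepted
        break
      }
      dx <- max(abs(X_new - X))
      improved <- stress - stress_new
      X <- X_new; d <- d_new; dh <- dh_new; stress <- stress_new
      stress_trace <- c(stress_trace, stress)
      if (improved < cfg$tol_fun || dx < cfg$tol_x) {
        converged <- TRUE
        break
      }
    }
    list(X = X, stress = stress, n_iter = iter, converged = converged,
         trace = stress_trace)
  }

  best <- NULL
  for (r in seq_len(cfg$replicates)) {
    X0 <- if (r == 1 && cfg$init == "cmdscale") {
      classical_scaling_init(Dm, cfg$dim)
    } else {
      with_seed(substream_seed(cfg$seed, "nmds-restart", r),
                matrix(rnorm(n * cfg$dim), n, cfg$dim))
    }
    if (sum(dist(X0)^2) == 0) {       # degenerate start (e.g. all-zero D)
      X0 <- X0 + with_seed(substream_seed(cfg$seed, "nmds-degenerate", r),
                           matrix(rnorm(n * cfg$dim, 0, 1e-8), n, cfg$dim))
    }
    res <- run_once(X0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  coords <- best$X
  rownames(coords) <- labels
  colnames(coords) <- paste0("x", seq_len(cfg$dim))
  structure(
    list(coords = coords, stress = best$stress, dim = cfg$dim,
         n_iter = best$n_iter, converged = best$converged,
         stress_trace = best$trace, config = cfg),
    class = "handover_nmds"
  )
}

stress1_vec <- function(d, dh) {
  denom <- sum(d^2)
  if (denom == 0) return(Inf)
  sqrt(sum((d - dh)^2) / denom)
}

# Guttman transform: X_new = B(X) X / n with B built from disparities/distances.
guttman_update <- function(X, dh_vec, n) {
  d <- dist(X)
  dm <- as.matrix(d)
  dhm <- matrix(0, n, n)
  dhm[lower.tri(dhm)] <- dh_vec
  dhm <- dhm + t(dhm)
  ratio <- matrix(0, n, n)
  nz <- dm > 0
  ratio[nz] <- dhm[nz] / dm[nz]
  B <- -ratio
  diag(B) <- rowSums(ratio)
  (B %*% X) / n
}

#' @export
print.handover_nmds <- function(x, ...) {
  cat(sprintf("<handover_nmds> n = %d, dim = %d, stress-1 = %.5f (%s after %d iterations)\n",
              nrow(x$coords), x$dim, x$stress,
              if (x$converged) "converged" else "iteration cap", x$n_iter))
  invisible(x)
}

#' @export
tidy.handover_nmds <- function(x, ...) {
  tibble::as_tibble(x$coords) |>
    dplyr::mutate(label = rownames(x$coords), .before = 1)
}

#' @export
glance.handover_nmds <- function(x, ...) {
  tibble::tibble(dim = x$dim, stress = x$stress, n_iter = x$n_iter,
                 converged = x$converged, n = nrow(x$coords))
}

#' Scatter plot of an NMDS embedding
#'
#' First two embedding axes, optionally coloured by participant and shaped
#' by role (the layout used to inspect cluster separation by individual).
#'
#' @param object A `handover_nmds`.
#' @param metadata Optional tibble with columns `traj_id` (matching the
#'   embedding labels) and any of `owner_id`, `role`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.handover_nmds <- function(object, metadata = NULL, ...) {
  df <- tidy(object)
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = c(label = "traj_id"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x1,
                                        y = if (object$dim >= 2) .data$x2 else 0))
  if (!is.null(metadata) && all(c("owner_id", "role") %in% names(df))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$owner_id,
                                              shape = .data$role), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(
    x = "NMDS axis 1", y = if (object$dim >= 2) "NMDS axis 2" else NULL,
    subtitle = sprintf("stress-1 = %.4f", object$stress)
  ) + ggplot2::theme_minimal()
}

#' Write an NMDS embedding as delimited text
#'
#' One row per trajectory (`label, x1..xd`); the stress is recorded in a
#' `# stress1 = ...` footer comment.
#'
#' @param embedding A `handover_nmds`.
#' @param path File path.
#' @export
write_embedding <- function(embedding, path) {
  readr::write_csv(tidy(embedding), path)
  cat(sprintf("# stress1 = %.10g\n", embedding$stress),
      file = path, append = TRUE)
  invisible(path)
}
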