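#' Initialize the eight-axis self-organizing map
#'
#' The map has 8 lattice axes with 2 units per axis, i.e. 2^8 = 256 units
#' whose positions enumerate \{0,1\}^8; a unit's position is read as row,
#' column, plane, cube, tesseract, penteract, hexeract and hepteract. The
#' stated hexagonal layout is unrealizable with two units per axis in eight
#' dimensions, so neighbourhoods use the Hamming distance on the hypercube.
#' Weights start as small seeded perturbations of the data centroid (or of
#' the unit-hypercube midpoint when no data are given).
#'
#' @param input_dim Dimension d of the input vectors (embedded coordinates).
#' @param seed Integer seed.
#' @param X Optional n x d data matrix used for the centroid.
#' @return A `som_lattice`: `weights` (256 x d), `unit_coords` (256 x 8
#'   binary), `axes = 8`, `units_per_axis = 2`, `trained`.
#' @export
som_init <- function(input_dim, seed = 1, X = NULL) {
  stopifnot(input_dim >= 1)
  coords <- as.matrix(expand.grid(rep(list(0:1), 8)))[, 8:1, drop = FALSE]
  colnames(coords) <- c("row", "column", "plane", "cube", "tesseract",
                        "penteract", "hexeract", "hepteract")
  center <- if (!is.null(X)) colMeans(as.matrix(X)) else rep(0.5, input_dim)
  spread <- if (!is.null(X)) {
    s <- mean(apply(as.matrix(X), 2, sd)); if (!is.finite(s) || s == 0) 1 else s
  } else 1
  W <- with_seed(substream_seed(seed, "som-init"),
                 matrix(rnorm(256 * input_dim, 0, 0.05 * spread),
                        256, input_dim)) +
    matrix(center, 256, input_dim, byrow = TRUE)
  structure(list(weights = W, unit_coords = coords, axes = 8L,
                 units_per_axis = 2L, trained = FALSE),
            class = "som_lattice")
}

#' @export
print.som_lattice <- function(x, ...) {
  cat(sprintf("<som_lattice> 8 axes x 2 units = %d units, input dim %d, %s\n",
              nrow(x$weights), ncol(x$weights),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Pairwise Hamming distances between the 256 unit coordinate tuples.
unit_hamming <- function(coords) {
  as.matrix(dist(coords, method = "manhattan"))
}

#' Train the self-organizing map
#'
#' Classic online SOM: samples are presented in seeded shuffled order; the
#' best-matching unit (Euclidean) and its lattice neighbours (Gaussian
#' neighbourhood in Hamming distance) are pulled toward each sample. Learning
#' rate and neighbourhood radius decay linearly over the presentations.
#'
#' @param lattice A [som_init()] result.
#' @param X n x d data matrix.
#' @param epochs Passes over the data (default 20).
#' @param lr0 Initial learning rate (default 0.3).
#' @param radius0 Initial neighbourhood radius in Hamming units (default 2).
#' @param seed Seed for the presentation order.
#' @return The trained `som_lattice`.
#' @export
som_train <- function(lattice, X, epochs = 20, lr0 = 0.3, radius0 = 2,
                      seed = 1) {
  stopifnot(inherits(lattice, "som_lattice"))
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1, ncol(X) == ncol(lattice$weights))
  W <- lattice$weights
  H <- unit_hamming(lattice$unit_coords)
  n <- nrow(X)
  total <- epochs * n
  step <- 0L
  with_seed(substream_seed(seed, "som-order"), {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        step <- step + 1L
        frac <- (step - 1) / total
        lr <- lr0 * (1 - frac)
        radius <- max(radius0 * (1 - frac), 0.3)
        x <- X[i, ]
        dd <- rowSums(sweep(W, 2, x)^2)
        bmu <- which.min(dd)
        h <- exp(-H[bmu, ]^2 / (2 * radius^2))
        W <- W + (lr * h) * sweep(-W, 2, x, "+")
      }
    }
  })
  lattice$weights <- W
  lattice$trained <- TRUE
  lattice
}

#' Best-matching-unit codes
#'
#' For each sample, the 8 binary lattice coordinates (row, column, plane,
#' cube, tesseract, penteract, hexeract, hepteract) of the nearest unit;
#' exact ties go to the lexicographically smallest coordinate tuple.
#'
#' @param lattice A `som_lattice`.
#' @param X n x d data matrix.
#' @param labels Optional row labels.
#' @return A tibble: `label` plus the 8 binary coordinate columns.
#' @export
bmu_coordinates <- function(lattice, X, labels = NULL) {
  stopifnot(inherits(lattice, "som_lattice"))
  X <- as.matrix(X)
  stopifnot(ncol(X) == ncol(lattice$weights))
  # units are generated in lexicographic order of their tuples, so the first
  # index among tied minima is the lexicographically smallest tuple
  idx <- apply(X, 1, function(x) {
    which.min(rowSums(sweep(lattice$weights, 2, x)^2))
  })
  out <- tibble::as_tibble(lattice$unit_coords[idx, , drop = FALSE])
  labels <- labels %||% rownames(X) %||% paste0("s", seq_len(nrow(X)))
  dplyr::mutate(out, label = labels, .before = 1)
}

#' Cross-validated BMU coding
#'
#' For each fold of `cv`, a fresh map is trained on the complement and the
#' fold's trajectories are coded by that map, so no trajectory is coded by a
#' map that saw it; codes are assembled back in row order.
#'
#' @param X n x d embedded coordinates.
#' @param cv A [make_partitions()] result over the rows of `X`.
#' @param epochs,lr0,radius0,seed Passed to [som_train()].
#' @param labels Optional row labels.
#' @return A tibble of one 8-coordinate code per row of `X`, in row order,
#'   with a `fold` column recording the coding fold.
#' @export
cross_validated_codes <- function(X, cv, epochs = 20, lr0 = 0.3, radius0 = 2,
                                  seed = 1, labels = NULL) {
  X <- as.matrix(X)
  stopifnot(inherits(cv, "cv_partition"))
  labels <- labels %||% rownames(X) %||% paste0("s", seq_len(nrow(X)))
  pieces <- vector("list", length(cv$folds))
  for (f in seq_along(cv$folds)) {
    test_idx <- sort(cv$folds[[f]])
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    if (length(train_idx) == 0) train_idx <- test_idx  # single-fold resubstitution
    lat <- som_init(ncol(X), seed = substream_seed(seed, "som-fold", f),
                    X = X[train_idx, , drop = FALSE])
    lat <- som_train(lat, X[train_idx, , drop = FALSE], epochs, lr0, radius0,
                     seed = substream_seed(seed, "som-fold-train", f))
    codes <- bmu_coordinates(lat, X[test_idx, , drop = FALSE],
                             labels = labels[test_idx])
    codes$fold <- names(cv$folds)[f]
    codes$.orig_row <- test_idx
    pieces[[f]] <- codes
  }
  dplyr::bind_rows(pieces) |>
    dplyr::arrange(.data$.orig_row) |>
    dplyr::select(-".orig_row")
}

#' Write BMU codes as delimited text
#'
#' @param codes A [bmu_coordinates()] / [cross_validated_codes()] tibble.
#' @param path File path.
#' @export
write_bmu_codes <- function(codes, path) {
  readr::write_csv(codes, path)
  invisible(path)
}
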