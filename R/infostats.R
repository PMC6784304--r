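#' Choose a histogram descriptor for a sample
#'
#' First pass of the two-pass mutual-information protocol: the cell layout is
#' fixed from the data before any estimate is computed. Categorical inputs
#' (and numeric inputs with no more distinct values than the histogram rule
#' would allot) get one cell per category; continuous inputs get a
#' Sturges-style `ceiling(1 + log2(n))` equal-width cells over the sample
#' range. A constant sample yields a single cell (zero entropy), not an
#' error.
#'
#' @param x A sample (numeric, factor, character or logical).
#' @return A `descriptor`: list with `type`, `lower`, `upper`, `n_cells`,
#'   `levels`.
#' @export
choose_descriptor <- function(x) {
  n <- length(x)
  if (n < 1) abort("empty sample.", class = "handovr_invalid_argument")
  sturges <- max(1L, as.integer(ceiling(1 + log2(n))))
  if (!is.numeric(x)) {
    lev <- sort(unique(as.character(x)))
    return(structure(list(type = "categorical", lower = NA_real_,
                          upper = NA_real_, n_cells = length(lev),
                          levels = lev),
                     class = "descriptor"))
  }
  ux <- sort(unique(x))
  if (length(ux) == 1) {
    return(structure(list(type = "categorical", lower = ux, upper = ux,
                          n_cells = 1L, levels = as.character(ux)),
                     class = "descriptor"))
  }
  if (length(ux) <= sturges) {
    return(structure(list(type = "categorical", lower = min(ux),
                          upper = max(ux), n_cells = length(ux),
                          levels = as.character(ux)),
                     class = "descriptor"))
  }
  structure(list(type = "continuous", lower = min(x), upper = max(x),
                 n_cells = sturges, levels = NULL),
            class = "descriptor")
}

# Map a sample to integer cell indices 1..n_cells under a descriptor.
discretize <- function(x, desc) {
  stopifnot(inherits(desc, "descriptor"))
  if (desc$type == "categorical") {
    idx <- match(as.character(x), desc$levels)
    idx[is.na(idx)] <- desc$n_cells + 1L  # out-of-vocabulary overflow cell
    return(idx)
  }
  edges <- seq(desc$lower, desc$upper, length.out = desc$n_cells + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(idx, 1L), desc$n_cells)
}

#' Histogram mutual information (bits)
#'
#' Plug-in estimate `I = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` on the
#' joint histogram defined by the two descriptors, minus (when `correct`)
#' the first-order Miller--Madow bias term `(Rx - 1)(Ry - 1) / (2 N ln 2)`
#' with `Rx`, `Ry` the occupied cell counts — the "N-unbiased" reading of
#' the estimator. Descriptors default to [choose_descriptor()] on each
#' input, implementing the two-pass protocol.
#'
#' @param x,y Equal-length samples.
#' @param correct Apply the Miller--Madow correction (default `TRUE`).
#' @param descriptor_x,descriptor_y Optional pre-chosen descriptors.
#' @return Mutual information in bits (a single number; the corrected
#'   estimate can be slightly negative for independent variables).
#' @export
#' @examples
#' set.seed(1)
#' x <- sample(0:1, 1e4, replace = TRUE)
#' mutual_information(x, x)   # ~1 bit: the entropy of a fair coin
mutual_information <- function(x, y, correct = TRUE,
                               descriptor_x = NULL, descriptor_y = NULL) {
  if (length(x) != length(y)) {
    abort("`x` and `y` differ in length.", class = "handovr_invalid_argument")
  }
  dx <- descriptor_x %||% choose_descriptor(x)
  dy <- descriptor_y %||% choose_descriptor(y)
  ix <- discretize(x, dx)
  iy <- discretize(y, dy)
  n <- length(x)
  joint <- table(ix, iy) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  outer_p <- outer(px, py)
  mi <- sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
  if (correct) {
    rx <- sum(px > 0)
    ry <- sum(py > 0)
    mi <- mi - (rx - 1) * (ry - 1) / (2 * n * log(2))
  }
  mi
}

#' Plug-in entropy (bits)
#'
#' @param x A sample.
#' @param descriptor Optional pre-chosen descriptor.
#' @return Entropy in bits.
#' @export
plugin_entropy <- function(x, descriptor = NULL) {
  d <- descriptor %||% choose_descriptor(x)
  p <- table(discretize(x, d)) / length(x)
  -sum(p * log2(p))
}

#' Mutual-information matrix over factors and trajectory projections
#'
#' Pairwise mutual information over the participant properties, the
#' experimental condition factors, the participant identity, and the
#' components of the trajectory's NMDS projections at the requested
#' dimensionalities (each component treated as one factor: `tr` for the
#' 1-D projection, `t2x`/`t2y`, `t3x`..`t3z`, and `c01`..`c20` for the
#' 20-D case).
#'
#' @param dataset A `handover_dataset`.
#' @param embeddings Named list of `handover_nmds` objects keyed by their
#'   dimension (e.g. `list("1" = ..., "2" = ..., "3" = ..., "20" = ...)`),
#'   row-aligned with `dataset$trajectories`.
#' @param correct Miller--Madow correction (default `TRUE`; set `FALSE` for
#'   the uncorrected plug-in estimate, whose diagonal dominates each row).
#' @return An `mi_matrix`: symmetric numeric matrix (bits) with factor names
#'   as dimnames.
#' @export
mi_matrix <- function(dataset, embeddings, correct = TRUE) {
  labels <- factor_label_table(dataset)
  cols <- list(
    health = labels$health, gender = labels$gender,
    familiarity = labels$familiarity, profession = labels$profession,
    age = labels$age, agreeableness = labels$agreeableness,
    satiety = labels$satiety, openness = labels$openness,
    sportiness = labels$sportiness, extraversion = labels$extraversion,
    identity = labels$identity, conscientiousness = labels$conscientiousness,
    weight = labels$weight, neuroticism = labels$neuroticism,
    body_size = labels$body_size,
    giver_side = labels$giver_side, content = labels$content,
    platform = labels$platform, handover_kind = labels$handover_kind,
    beaker_size = labels$beaker_size
  )
  for (d in names(embeddings)) {
    emb <- embeddings[[d]]
    stopifnot(inherits(emb, "handover_nmds"))
    if (nrow(emb$coords) != nrow(labels)) {
      abort("embedding rows do not align with the trajectory table.",
            class = "handovr_invalid_argument")
    }
    dd <- emb$dim
    nm <- if (dd == 1) "tr"
          else if (dd <= 3) paste0("t", dd, c("x", "y", "z")[seq_len(dd)])
          else sprintf("c%02d", seq_len(dd))
    for (j in seq_len(dd)) cols[[nm[j]]] <- emb$coords[, j]
  }
  k <- length(cols)
  descs <- lapply(cols, choose_descriptor)
  M <- matrix(0, k, k, dimnames = list(names(cols), names(cols)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- mutual_information(cols[[i]], cols[[j]], correct = correct,
                              descriptor_x = descs[[i]],
                              descriptor_y = descs[[j]])
      M[i, j] <- v
      M[j, i] <- v
    }
  }
  structure(M, class = c("mi_matrix", "matrix", "array"), correct = correct)
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("<mi_matrix> %d factors, %s estimate (bits)\n", nrow(x),
              if (isTRUE(attr(x, "correct"))) "bias-corrected" else "plug-in"))
  invisible(x)
}

#' @export
tidy.mi_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(m, rownames = "factor_a") |>
    tidyr::pivot_longer(-"factor_a", names_to = "factor_b",
                        values_to = "mi_bits")
}

#' Heatmap of a mutual-information matrix
#'
#' Cells are coloured by the percentile rank of the MI value over all cells,
#' matching the percentile colour bar of the study's MI figure.
#'
#' @param object An `mi_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_matrix <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      percentile = 100 * (rank(.data$mi_bits) - 1) / (dplyr::n() - 1),
      factor_a = factor(.data$factor_a, levels = rownames(object)),
      factor_b = factor(.data$factor_b, levels = rownames(object))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$factor_a, .data$factor_b,
                                   fill = .data$percentile)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MI percentile") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Write an MI matrix as delimited text
#'
#' @param M An `mi_matrix`.
#' @param path File path.
#' @export
write_mi_matrix <- function(M, path) {
  tibble::as_tibble(unclass(M), rownames = "factor") |>
    readr::write_csv(path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# MANOVA over BMU codes

# A lattice coordinate that never varies across trials carries no information
# and makes the error matrix singular; the cross-validated wrappers drop such
# columns before fitting.
drop_constant_codes <- function(Y) {
  Y <- as.matrix(Y)
  keep <- apply(Y, 2, function(v) length(unique(v)) > 1)
  if (!any(keep)) {
    abort("all code columns are constant.", class = "handovr_rank_deficiency")
  }
  structure(Y[, keep, drop = FALSE], dropped = colnames(Y)[!keep])
}

# Fit, and on a singular error matrix retry without the offending response
# columns (collinear lattice coordinates code no independent information).
fit_manova_dropping <- function(Y, data, terms) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  Y <- drop_constant_codes(Y)
  repeat {
    res <- tryCatch(manova_codes(Y, data, terms),
                    handovr_rank_deficiency = function(e) e)
    if (!inherits(res, "condition")) return(res)
    msg <- conditionMessage(res)
    bad <- regmatches(msg, regexec("offending response columns: (.*)$", msg))[[1]][2]
    if (is.na(bad)) abort(msg, class = "handovr_rank_deficiency")
    bad <- strsplit(bad, ", ")[[1]]
    keep <- setdiff(colnames(Y), bad)
    if (length(keep) == 0) abort(msg, class = "handovr_rank_deficiency")
    Y <- Y[, keep, drop = FALSE]
  }
}

#' MANOVA with the four classical test statistics
#'
#' Fits the multivariate linear model of `Y` on the requested terms and, per
#' term, forms the hypothesis (H) and error (E) cross-product matrices with
#' Type II sums of squares (H of a term is the residual cross-product of the
#' model without that term minus that of the full model; with balanced
#' designs this coincides with the other types). The eigenvalues of
#' `solve(E) %*% H` yield Pillai's trace, Wilks' lambda, the
#' Hotelling--Lawley trace and Roy's largest root, each mapped to its
#' standard approximate F and p-value. Numerically they are computed through
#' the bounded eigenvalues of `solve(E + H) %*% H`, so a response direction
#' explained perfectly by the term (E singular there, as happens when the
#' map codes are a near-deterministic function of the design) yields the
#' natural limit: an infinite root and p = 0 for Wilks, Hotelling--Lawley
#' and Roy. A response that carries no variation at all for a term raises a
#' rank-deficiency error naming the offending columns.
#'
#' @param Y n x p numeric response matrix (e.g. the 8 binary BMU
#'   coordinates).
#' @param data Tibble holding the predictor columns.
#' @param terms Character vector of predictor column names (factors or
#'   numeric covariates; main effects only).
#' @return A `handovr_manova`: tibble `table` with columns `term`,
#'   `statistic`, `value`, `approx_f`, `df1`, `df2`, `p_value`, plus the
#'   eigenvalues per term.
#' @export
manova_codes <- function(Y, data, terms) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  p <- ncol(Y)
  stopifnot(nrow(data) == n, length(terms) >= 1)
  mm <- function(tms) {
    if (length(tms) == 0) return(matrix(1, n, 1))
    fml <- stats::as.formula(paste("~", paste(tms, collapse = " + ")))
    stats::model.matrix(fml, data = data)
  }
  X_full <- mm(terms)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    aliased <- colnames(X_full)[qr_full$pivot[(qr_full$rank + 1):ncol(X_full)]]
    abort(sprintf("rank-deficient design; aliased columns: %s",
                  paste(aliased, collapse = ", ")),
          class = "handovr_rank_deficiency")
  }
  df_res <- n - qr_full$rank
  if (df_res < p) {
    abort(sprintf("residual df (%d) below response dimension (%d): E singular.",
                  df_res, p),
          class = "handovr_rank_deficiency")
  }
  resid_cp <- function(qrX) {
    R <- qr.resid(qrX, Y)
    crossprod(R)
  }
  E <- resid_cp(qr_full)
  # a response with no variation at all leaves E singular with nothing to test
  total_var <- diag(resid_cp(qr(matrix(1, n, 1))))
  if (any(total_var <= 1e-10 * max(total_var, 1))) {
    bad <- (colnames(Y) %||% paste0("y", seq_len(p)))[total_var <= 1e-10 * max(total_var, 1)]
    abort(sprintf("singular error matrix; offending response columns: %s",
                  paste(bad, collapse = ", ")),
          class = "handovr_rank_deficiency")
  }
  rows <- list()
  eigs <- list()
  all_terms <- c("(intercept)", terms)
  for (tm in all_terms) {
    if (tm == "(intercept)") {
      # hypothesis: mean response zero, adjusted for nothing
      X_red <- mm(terms)
      X_red <- X_red[, colnames(X_red) != "(Intercept)", drop = FALSE]
      qr_red <- qr(X_red)
    } else {
      qr_red <- qr(mm(setdiff(terms, tm)))
    }
    Tm <- resid_cp(qr_red)       # E + H for this term
    H <- Tm - E
    q <- qr_full$rank - qr_red$rank
    if (q < 1) next
    # Work in the positive eigenspace of E + H: a null direction of E + H has
    # H v = E v = 0 (both p.s.d.), so it carries nothing about this term.
    et <- eigen(Tm, symmetric = TRUE)
    keep <- et$values > 1e-10 * max(et$values)
    V <- et$vectors[, keep, drop = FALSE]
    p_eff <- ncol(V)
    Tp <- crossprod(V, Tm %*% V)
    Hp <- crossprod(V, H %*% V)
    # eigenvalues theta of (E+H)^-1 H; lambda = theta/(1-theta) are the
    # eigenvalues of E^-1 H, with theta -> 1 (a direction explained
    # perfectly, E singular there) mapping to lambda = Inf and hence p -> 0
    # for Wilks/Hotelling/Roy
    theta <- Re(eigen(solve(Tp, Hp), only.values = TRUE)$values)
    theta <- pmin(pmax(theta, 0), 1)
    ev <- ifelse(theta >= 1, Inf, theta / (1 - theta))
    eigs[[tm]] <- ev
    rows[[tm]] <- dplyr::bind_rows(
      manova_stat_row(tm, "Pillai", ev, q, df_res, p_eff),
      manova_stat_row(tm, "Wilks", ev, q, df_res, p_eff),
      manova_stat_row(tm, "Hotelling", ev, q, df_res, p_eff),
      manova_stat_row(tm, "Roy", ev, q, df_res, p_eff)
    )
  }
  structure(list(table = dplyr::bind_rows(rows), eigenvalues = eigs,
                 df_residual = df_res, n = n, p = p, terms = terms),
            class = "handovr_manova")
}

manova_stat_row <- function(term, statistic, ev, q, df_res, p = length(ev)) {
  s <- min(p, q)
  m <- 0.5 * (abs(p - q) - 1)
  nn <- 0.5 * (df_res - p - 1)
  res <- switch(
    statistic,
    Pillai = {
      V <- sum(ifelse(is.infinite(ev), 1, ev / (1 + ev)))
      tmp1 <- 2 * m + s + 1
      tmp2 <- 2 * nn + s + 1
      c(V, (tmp2 / tmp1) * V / (s - V), s * tmp1, s * tmp2)
    },
    Wilks = {
      L <- prod(1 / (1 + ev))
      tmp1 <- df_res - 0.5 * (p - q + 1)
      tmp2 <- (p * q - 2) / 4
      p2q2 <- p^2 + q^2 - 5
      tmp3 <- if (p2q2 > 0) sqrt((p^2 * q^2 - 4) / p2q2) else 1
      c(L, ((L^(-1 / tmp3) - 1) * (tmp1 * tmp3 - 2 * tmp2)) / p / q,
        p * q, tmp1 * tmp3 - 2 * tmp2)
    },
    Hotelling = {
      U <- sum(ev)
      tmp1 <- 2 * m + s + 1
      tmp2 <- 2 * (s * nn + 1)
      c(U, (tmp2 * U) / s / s / tmp1, s * tmp1, tmp2)
    },
    Roy = {
      r <- max(p, q)
      tmp2 <- df_res - r + q
      c(max(ev), (tmp2 * max(ev)) / r, r, tmp2)
    }
  )
  tibble::tibble(term = term, statistic = statistic, value = res[1],
                 approx_f = res[2], df1 = res[3], df2 = res[4],
                 p_value = pf(res[2], res[3], res[4], lower.tail = FALSE))
}

#' @export
print.handovr_manova <- function(x, ...) {
  cat(sprintf("<handovr_manova> n = %d, %d responses, residual df = %d\n",
              x$n, x$p, x$df_residual))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @export
tidy.handovr_manova <- function(x, ...) x$table

#' @export
glance.handovr_manova <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, df_residual = x$df_residual,
                 n_terms = length(x$terms))
}

#' Cross-validated MANOVA over SOM codes
#'
#' For each fold of `cv`, a self-organizing map is trained on the fold's
#' complement, all trajectories are coded by that map (the held-out fold is
#' thus coded by a map that never saw it), and the MANOVA of the 8 binary
#' BMU coordinates on `terms` is computed (coordinates that never vary are
#' dropped from that fold's response set: a frozen lattice coordinate is
#' uninformative). Per-fold p-values and their means
#' form the reported table.
#'
#' @param X n x d embedded coordinates.
#' @param data Tibble with the predictor columns, row-aligned with `X`.
#' @param terms Predictor column names.
#' @param cv A [make_partitions()] result.
#' @param epochs,lr0,radius0,seed Passed to [som_train()].
#' @return A list: `per_fold` tibble (`fold`, `term`, `statistic`, `value`,
#'   `p_value`), `summary` tibble (`term`, `statistic`,
#'   `mean_asymptotic_significance`, `n_partitions`).
#' @export
manova_cv <- function(X, data, terms, cv, epochs = 20, lr0 = 0.3,
                      radius0 = 2, seed = 1) {
  X <- as.matrix(X)
  stopifnot(inherits(cv, "cv_partition"), nrow(data) == nrow(X))
  per_fold <- purrr::imap_dfr(cv$folds, function(test_idx, fold_name) {
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    if (length(train_idx) == 0) train_idx <- test_idx
    lat <- som_init(ncol(X), seed = substream_seed(seed, "mcv", fold_name),
                    X = X[train_idx, , drop = FALSE])
    lat <- som_train(lat, X[train_idx, , drop = FALSE], epochs, lr0, radius0,
                     seed = substream_seed(seed, "mcv-train", fold_name))
    codes <- bmu_coordinates(lat, X)
    fit <- fit_manova_dropping(as.matrix(codes[, -1]), data, terms)
    dplyr::mutate(fit$table, fold = fold_name, .before = 1)
  })
  summary <- per_fold |>
    dplyr::group_by(.data$term, .data$statistic) |>
    dplyr::summarise(
      mean_asymptotic_significance = mean(.data$p_value),
      n_partitions = dplyr::n(), .groups = "drop"
    )
  list(per_fold = per_fold, summary = summary)
}

#' Backward model reduction of a MANOVA
#'
#' Starting from the candidate factors, repeatedly drops the factor with the
#' largest Wilks p-value (the worst fold when several response sets / folds
#' are supplied) as long as that p-value is at or above `alpha`, until every
#' retained factor is significant in every fold or the set is empty. Ties
#' break deterministically toward the earlier column. Candidates whose model
#' columns are aliased with earlier ones are set aside up front and reported.
#'
#' @param Y_list A response matrix, or a list of response matrices (one per
#'   fold), all row-aligned with `data`.
#' @param data Tibble with the candidate predictor columns.
#' @param candidates Character vector of candidate column names.
#' @param alpha Significance level (default 0.05).
#' @return A list: `retained` (character), `dropped` (tibble with `factor`
#'   and `reason`), `fit` (the final per-fold [manova_codes()] tables, or
#'   `NULL` when nothing is retained).
#' @export
model_reduction <- function(Y_list, data, candidates, alpha = 0.05) {
  if (!is.list(Y_list)) Y_list <- list(Y_list)
  stopifnot(length(candidates) >= 1)
  dropped <- tibble::tibble(factor = character(), reason = character())

  # pre-screen aliased candidates (later columns lose)
  kept <- character(0)
  for (cand in candidates) {
    if (dplyr::n_distinct(data[[cand]]) < 2) {
      dropped <- dplyr::add_row(dropped, factor = cand, reason = "constant")
      next
    }
    tms <- c(kept, cand)
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(tms, collapse = " + "))), data = data)
    if (qr(X)$rank == ncol(X)) {
      kept <- tms
    } else {
      dropped <- dplyr::add_row(dropped, factor = cand, reason = "aliased")
    }
  }
  current <- kept
  fits <- NULL
  while (length(current) > 0) {
    fits <- lapply(Y_list, function(Y) fit_manova_dropping(Y, data, current))
    wilks <- purrr::map_dfr(fits, function(f) {
      dplyr::filter(f$table, .data$statistic == "Wilks",
                    .data$term != "(intercept)")
    }) |>
      dplyr::group_by(.data$term) |>
      dplyr::summarise(worst_p = max(.data$p_value), .groups = "drop") |>
      dplyr::mutate(ord = match(.data$term, current)) |>
      dplyr::arrange(.data$ord)
    if (all(wilks$worst_p < alpha)) break
    victim <- wilks$term[which.max(wilks$worst_p)]
    dropped <- dplyr::add_row(dropped, factor = victim,
                              reason = sprintf("Wilks p = %.4g >= %.3g",
                                               max(wilks$worst_p), alpha))
    current <- setdiff(current, victim)
    fits <- NULL
  }
  list(retained = current, dropped = dropped,
       fit = if (length(current) > 0) fits else NULL)
}

#' Write a MANOVA summary as delimited text
#'
#' @param summary The `summary` tibble of [manova_cv()] (or a
#'   [manova_codes()] table).
#' @param path File path.
#' @export
write_manova_table <- function(summary, path) {
  readr::write_csv(summary, path)
  invisible(path)
}
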