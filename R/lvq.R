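#' Cross-validation partitions over trials
#'
#' Two fold schemes are used throughout the pipeline. *Trialwise*: trials
#' from all participants are assigned to `k` folds at random, so the
#' classifier always sees training trials of the test participant.
#' *Participantwise*: one fold per participant, containing exactly that
#' participant's trials, testing generalization to unseen individuals.
#'
#' @param trials A tibble with one row per unit to be folded; needs an
#'   `owner_id` column for the participantwise mode.
#' @param mode `"trialwise"` or `"participantwise"`.
#' @param k Number of folds (trialwise only; ignored participantwise).
#' @param seed Seed for the trialwise assignment.
#' @return A `cv_partition`: list with `mode` and `folds` (named list of
#'   integer row indices into `trials`, disjoint, covering all rows).
#' @export
make_partitions <- function(trials, mode = c("trialwise", "participantwise"),
                            k = 4, seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(trials)
  if (mode == "trialwise") {
    if (k < 2 || k > n) {
      abort("`k` must lie in [2, n] for trialwise folds.",
            class = "handovr_invalid_argument")
    }
    idx <- with_seed(substream_seed(seed, "cv", mode, k), sample.int(n))
    folds <- split(idx, rep(seq_len(k), length.out = n))
    names(folds) <- paste0("fold", seq_len(k))
  } else {
    if (!"owner_id" %in% names(trials)) {
      abort("participantwise folds need an `owner_id` column.",
            class = "handovr_invalid_argument")
    }
    folds <- split(seq_len(n), trials$owner_id)
  }
  structure(list(mode = mode, folds = folds), class = "cv_partition")
}

#' @export
print.cv_partition <- function(x, ...) {
  cat(sprintf("<cv_partition> %s, %d folds (sizes: %s)\n", x$mode,
              length(x$folds),
              paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}

#' Train a learning vector quantization (LVQ1) classifier
#'
#' Prototypes are initialized at the class-conditional means plus a small
#' seeded jitter (default), or at seeded random class samples (`init =
#' "sample"`, useful when a class occupies several separate clusters, as a
#' condition-factor level does in the trajectory embedding); each training
#' sample attracts its winning (nearest) prototype when the labels match and
#' repels it otherwise, with a linearly decaying learning rate.
#'
#' @param X n x d numeric matrix of embedded coordinates.
#' @param y Class labels (one per row of `X`); at least two classes.
#' @param prototypes_per_class Prototypes per class (default 1).
#' @param lr0 Initial learning rate (default 0.3).
#' @param epochs Passes over the data (default 20).
#' @param seed Seed for jitter and presentation order.
#' @param init `"mean"` (class-conditional mean plus jitter) or `"sample"`
#'   (distinct random class samples).
#' @return An `lvq_model`: `prototypes` (m x d), `prototype_labels`, `trained`.
#' @export
lvq_train <- function(X, y, prototypes_per_class = 1, lr0 = 0.3, epochs = 20,
                      seed = 1, init = c("mean", "sample")) {
  init <- match.arg(init)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    abort("LVQ needs at least two classes.", class = "handovr_degenerate_labels")
  }
  d <- ncol(X)
  m <- length(classes) * prototypes_per_class
  proto <- matrix(0, m, d)
  plab <- character(m)
  with_seed(substream_seed(seed, "lvq-init"), {
    r <- 0L
    spread <- mean(apply(X, 2, sd))
    if (!is.finite(spread) || spread == 0) spread <- 1
    for (cl in classes) {
      members <- which(y == cl)
      mu <- colMeans(X[members, , drop = FALSE])
      picks <- if (init == "sample") {
        sample(members, prototypes_per_class,
               replace = length(members) < prototypes_per_class)
      } else NULL
      for (j in seq_len(prototypes_per_class)) {
        r <- r + 1L
        base <- if (is.null(picks)) mu else X[picks[j], ]
        proto[r, ] <- base + rnorm(d, 0, 0.01 * spread)
        plab[r] <- cl
      }
    }
  })
  n <- nrow(X)
  total <- epochs * n
  step <- 0L
  with_seed(substream_seed(seed, "lvq-order"), {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        step <- step + 1L
        lr <- lr0 * (1 - (step - 1) / total)
        dd <- rowSums(sweep(proto, 2, X[i, ])^2)
        w <- which.min(dd)
        dir <- if (plab[w] == y[i]) 1 else -1
        proto[w, ] <- proto[w, ] + dir * lr * (X[i, ] - proto[w, ])
      }
    }
  })
  structure(list(prototypes = proto, prototype_labels = plab, trained = TRUE,
                 classes = classes),
            class = "lvq_model")
}

#' @export
print.lvq_model <- function(x, ...) {
  cat(sprintf("<lvq_model> %d prototypes, %d classes, d = %d\n",
              nrow(x$prototypes), length(x$classes), ncol(x$prototypes)))
  invisible(x)
}

#' Classify with a trained LVQ model
#'
#' Nearest-prototype label under the Euclidean metric; exact distance ties go
#' to the prototype with the lowest index.
#'
#' @param model An [lvq_train()] result.
#' @param X Query matrix (n x d).
#' @return Character vector of predicted labels.
#' @export
lvq_predict <- function(model, X) {
  if (!inherits(model, "lvq_model") || !isTRUE(model$trained)) {
    abort("`model` is not a trained lvq_model.", class = "handovr_state_error")
  }
  X <- as.matrix(X)
  stopifnot(ncol(X) == ncol(model$prototypes))
  apply(X, 1, function(x) {
    dd <- rowSums(sweep(model$prototypes, 2, x)^2)
    model$prototype_labels[which.min(dd)]   # which.min takes the lowest index on ties
  })
}

#' Chi-square cross-tabulation of predictions against truth
#'
#' Contingency table of true versus predicted labels and the chi-square test
#' of independence (no continuity correction); its asymptotic p-value is the
#' "asymptotic significance" reported per partition. Degenerate tables with a
#' single row or column carry no evidence and return p = 1 with
#' `degenerate = TRUE`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @return A one-row tibble: `statistic`, `dof`, `p_value`, `degenerate`.
#' @export
crosstab_test <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    abort("label vectors differ in length.", class = "handovr_invalid_argument")
  }
  if (length(true_labels) < 1) {
    abort("need at least one observation.", class = "handovr_invalid_argument")
  }
  tab <- table(true = as.character(true_labels),
               pred = as.character(predicted_labels))
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(tibble::tibble(statistic = NA_real_, dof = NA_integer_,
                          p_value = 1, degenerate = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 dof = as.integer(unname(ct$parameter)),
                 p_value = unname(ct$p.value), degenerate = FALSE)
}

#' Cross-validated factor recognition from an embedding
#'
#' For each fold of `cv`: train an LVQ network on the complement, classify
#' the fold, record the error fraction and the cross-tabulation p-value;
#' report their means over folds together with the fold count. This is the
#' row format of the supervised-learning report (design, factor, error,
#' asymptotic significance, N).
#'
#' @param coords n x d embedded coordinates (or a `handover_nmds`).
#' @param factor_labels Label per embedded trajectory (the value of the
#'   factor being recognized).
#' @param cv A [make_partitions()] result over the same rows.
#' @param design `"between"` for participant properties, `"within"` for
#'   experimental conditions (bookkeeping only).
#' @param factor_name Name recorded in the report.
#' @param prototypes_per_class,lr0,epochs,seed,init Passed to [lvq_train()].
#' @return A one-row tibble: `design`, `factor`, `mean_error`,
#'   `mean_asymptotic_significance`, `n_partitions` (plus `n_skipped` folds
#'   whose training complement lacked a class).
#' @export
evaluate_factor <- function(coords, factor_labels, cv,
                            design = c("between", "within"),
                            factor_name = "factor",
                            prototypes_per_class = 1, lr0 = 0.3, epochs = 20,
                            seed = 1, init = "mean") {
  design <- match.arg(design)
  if (inherits(coords, "handover_nmds")) coords <- coords$coords
  X <- as.matrix(coords)
  y <- as.character(factor_labels)
  stopifnot(nrow(X) == length(y), inherits(cv, "cv_partition"))
  errs <- ps <- numeric(0)
  skipped <- 0L
  for (f in seq_along(cv$folds)) {
    test_idx <- cv$folds[[f]]
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    if (length(train_idx) == 0) train_idx <- test_idx  # single-fold resubstitution
    if (length(unique(y[train_idx])) < 2) {
      skipped <- skipped + 1L
      next
    }
    model <- lvq_train(X[train_idx, , drop = FALSE], y[train_idx],
                       prototypes_per_class, lr0, epochs,
                       seed = substream_seed(seed, "fold", f), init = init)
    pred <- lvq_predict(model, X[test_idx, , drop = FALSE])
    errs <- c(errs, mean(pred != y[test_idx]))
    ps <- c(ps, crosstab_test(y[test_idx], pred)$p_value)
  }
  if (length(errs) == 0) {
    abort(sprintf("every fold was skipped for factor '%s'.", factor_name),
          class = "handovr_degenerate_labels")
  }
  tibble::tibble(
    design = design, factor = factor_name,
    mean_error = mean(errs),
    mean_asymptotic_significance = mean(ps),
    n_partitions = length(errs), n_skipped = skipped
  )
}

#' Supervised-learning report over a set of factors
#'
#' Runs [evaluate_factor()] for every requested factor of a dataset and
#' stacks the rows into the classification report (columns `design`,
#' `factor`, `mean_error`, `mean_asymptotic_significance`, `n_partitions`).
#' Between-subject factors are the participant properties (including
#' identity) of the trajectory owner; within-subject factors are the five
#' condition factors of the trial.
#'
#' @param embedding A `handover_nmds` of the trajectory set.
#' @param dataset The `handover_dataset` the embedding came from.
#' @param factors Character vector of factor names: any of the condition
#'   factors, `"identity"`, or participant profile columns.
#' @param cv A [make_partitions()] result over the trajectory rows.
#' @param ... Passed on to [evaluate_factor()].
#' @return A tibble with one row per factor.
#' @export
evaluate_factors <- function(embedding, dataset, factors, cv, ...) {
  labels <- factor_label_table(dataset)
  stopifnot(all(labels$traj_id == rownames(embedding$coords)))
  purrr::map_dfr(factors, function(f) {
    if (!f %in% names(labels)) {
      abort(sprintf("unknown factor '%s'.", f),
            class = "handovr_invalid_argument")
    }
    design <- if (f %in% names(condition_levels())) "within" else "between"
    if (dplyr::n_distinct(labels[[f]]) < 2) {
      warn(sprintf("factor '%s' takes a single value in this dataset; skipped.", f))
      return(NULL)
    }
    evaluate_factor(embedding$coords, labels[[f]], cv,
                    design = design, factor_name = f, ...)
  })
}

# One row per trajectory: condition factors of its trial + profile fields of
# its owner + identity, aligned with dataset$trajectories.
factor_label_table <- function(dataset) {
  cond_cols <- c(names(condition_levels()), "condition_id")
  dataset$trajectories |>
    dplyr::select("traj_id", "trial_id", "owner_id", "role") |>
    dplyr::left_join(dplyr::select(dataset$trials, "trial_id",
                                   dplyr::all_of(cond_cols)),
                     by = "trial_id") |>
    dplyr::left_join(dataset$participants, by = c(owner_id = "identity")) |>
    dplyr::mutate(identity = .data$owner_id)
}

#' Write the classification report as delimited text
#'
#' @param report Result of [evaluate_factors()].
#' @param path File path.
#' @export
write_classification_report <- function(report, path) {
  report |>
    dplyr::mutate(design = ifelse(.data$design == "between", "b", "w")) |>
    dplyr::select(design, factor, error = "mean_error",
                  asympt_sign = "mean_asymptotic_significance",
                  n = "n_partitions") |>
    readr::write_csv(path)
  invisible(path)
}
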