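#' Pipeline configuration
#'
#' Bundles the per-stage configurations. The single global `seed` is fanned
#' out to every stage through a counter-based substream scheme, so stage
#' randomness is independent yet the whole run is bit-reproducible.
#'
#' @param generator A [generator_config()].
#' @param nmds_dims Projection dimensionalities to compute; the supervised
#'   network consumes `classify_dim`, the map consumes `som_dim`, and the MI
#'   matrix consumes all of them.
#' @param nmds Base [nmds_config()] (its `dim` is overridden per requested
#'   dimension).
#' @param classify_dim Embedding dimension fed to the LVQ network (default
#'   20: low-dimensional projections are dominated by the identity signature
#'   and lose the condition effects, which the full-rank projection keeps).
#' @param som_dim Embedding dimension fed to the SOM (default 20).
#' @param lvq List of LVQ settings (`prototypes_per_class`, `lr0`, `epochs`,
#'   `k_trialwise`). The pipeline default of 4 prototypes per class reflects
#'   that a factor level's point cloud in the embedding is a union of
#'   participant-and-role clusters, which a single prototype cannot cover.
#' @param som List of SOM settings (`epochs`, `lr0`, `radius0`).
#' @param stats List of statistics settings (`alpha`,
#'   `reduction_candidates`).
#' @param seed Global seed.
#' @return A list of class `handovr_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            nmds_dims = c(1, 2, 3, 20),
                            nmds = nmds_config(),
                            classify_dim = 20, som_dim = 20,
                            lvq = list(prototypes_per_class = 8, lr0 = 0.3,
                                       epochs = 20, k_trialwise = 8,
                                       init = "sample"),
                            som = list(epochs = 20, lr0 = 0.3, radius0 = 2),
                            stats = list(
                              alpha = 0.05,
                              reduction_candidates = c(
                                "gender", "weight", "sportiness", "satiety",
                                "openness", "conscientiousness", "extraversion")),
                            seed = 1) {
  stopifnot(inherits(generator, "handovr_generator_config"),
            inherits(nmds, "handovr_nmds_config"))
  if (!classify_dim %in% nmds_dims || !som_dim %in% nmds_dims) {
    abort("`classify_dim` and `som_dim` must be among `nmds_dims`.",
          class = "handovr_invalid_argument")
  }
  generator$seed <- substream_seed(seed, "generator")
  structure(list(generator = generator, nmds_dims = sort(unique(nmds_dims)),
                 nmds = nmds, classify_dim = classify_dim, som_dim = som_dim,
                 lvq = lvq, som = som, stats = stats,
                 seed = as.integer(seed)),
            class = "handovr_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generate (or take) a dataset, apply the validity filter, compute the DTW
#' distance matrix, embed it at every requested dimensionality, run the
#' supervised (LVQ) factor recognition under trialwise and participantwise
#' cross-validation, build the mutual-information matrix, code the
#' trajectories with the cross-validated SOM, and run the MANOVA over the
#' codes (condition + participant, then the participant-property model
#' reduction). All tabular outputs are written as delimited text with header
#' rows; re-running with the same configuration reproduces them
#' bit-for-bit.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param dataset Optional pre-built `handover_dataset` (e.g. from
#'   [load_external_trials()]); by default one is generated from
#'   `cfg$generator`.
#' @param write_trajectories Write the per-trial trajectory files (default
#'   `TRUE`).
#' @return Invisibly, a list with every in-memory result (`dataset`,
#'   `distances`, `embeddings`, `classification`, `mi`, `codes`, `manova`,
#'   `reduction`, `manifest`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("handovr_"),
                         dataset = NULL, write_trajectories = TRUE) {
  stopifnot(inherits(cfg, "handovr_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest <- list(seed = cfg$seed, failed_stage = name,
                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "handovr_stage_error", parent = e)
    })
  }

  dataset <- stage("generate", {
    ds <- dataset %||% generate_dataset(cfg$generator)
    filter_valid(ds)
  })
  readr::write_csv(dplyr::select(dataset$trials, -dplyr::any_of("angles")),
                   file.path(out_dir, "design.csv"))
  readr::write_csv(dataset$participants, file.path(out_dir, "participants.csv"))
  if (write_trajectories) {
    stage("write-trajectories", write_trial_files(dataset, file.path(out_dir, "trajectories")))
  }

  D <- stage("distances", distance_matrix(dataset$trajectories))
  write_distance_matrix(D, file.path(out_dir, "distances.csv"))

  embeddings <- stage("embed", {
    out <- list()
    for (d in cfg$nmds_dims) {
      ncfg <- cfg$nmds
      ncfg$dim <- as.integer(d)
      ncfg$seed <- substream_seed(cfg$seed, "nmds", d)
      out[[as.character(d)]] <- nmds_embed(D, ncfg)
      write_embedding(out[[as.character(d)]],
                      file.path(out_dir, sprintf("embedding_dim%02d.csv", d)))
    }
    out
  })

  labels <- factor_label_table(dataset)
  emb_cls <- embeddings[[as.character(cfg$classify_dim)]]

  classification <- stage("classify", {
    cv_trial <- make_partitions(dataset$trajectories, "trialwise",
                                k = min(cfg$lvq$k_trialwise,
                                        nrow(dataset$trajectories)),
                                seed = substream_seed(cfg$seed, "cv-trial"))
    between <- c("identity", "gender", "age", "body_size", "weight",
                 "profession", "sportiness", "satiety", "familiarity",
                 "health", "openness", "conscientiousness", "extraversion",
                 "agreeableness", "neuroticism")
    within <- names(condition_levels())
    evaluate_factors(emb_cls, dataset, c(within, between), cv_trial,
                     prototypes_per_class = cfg$lvq$prototypes_per_class,
                     lr0 = cfg$lvq$lr0, epochs = cfg$lvq$epochs,
                     seed = substream_seed(cfg$seed, "lvq"),
                     init = cfg$lvq$init %||% "mean")
  })
  write_classification_report(classification,
                              file.path(out_dir, "classification_report.csv"))

  mi <- stage("mi", mi_matrix(dataset, embeddings))
  write_mi_matrix(mi, file.path(out_dir, "mi_matrix.csv"))

  emb_som <- embeddings[[as.character(cfg$som_dim)]]
  cv_part <- make_partitions(dataset$trajectories, "participantwise")

  codes <- stage("som", {
    cross_validated_codes(emb_som$coords, cv_part,
                          epochs = cfg$som$epochs, lr0 = cfg$som$lr0,
                          radius0 = cfg$som$radius0,
                          seed = substream_seed(cfg$seed, "som"),
                          labels = dataset$trajectories$traj_id)
  })
  write_bmu_codes(codes, file.path(out_dir, "bmu_codes.csv"))

  manova_res <- stage("manova", {
    mdata <- labels |>
      dplyr::mutate(condition = factor(.data$condition_id),
                    participant = factor(.data$owner_id))
    manova_cv(emb_som$coords, mdata, c("condition", "participant"), cv_part,
              epochs = cfg$som$epochs, lr0 = cfg$som$lr0,
              radius0 = cfg$som$radius0,
              seed = substream_seed(cfg$seed, "manova"))
  })
  write_manova_table(manova_res$summary,
                     file.path(out_dir, "manova_condition_participant.csv"))

  reduction <- stage("reduction", {
    # per-fold response sets: code ALL trajectories with each fold's map
    folds <- cv_part$folds
    Y_list <- lapply(seq_along(folds), function(f) {
      train_idx <- setdiff(seq_len(nrow(emb_som$coords)), folds[[f]])
      lat <- som_init(ncol(emb_som$coords),
                      seed = substream_seed(cfg$seed, "red", f),
                      X = emb_som$coords[train_idx, , drop = FALSE])
      lat <- som_train(lat, emb_som$coords[train_idx, , drop = FALSE],
                       cfg$som$epochs, cfg$som$lr0, cfg$som$radius0,
                       seed = substream_seed(cfg$seed, "red-train", f))
      as.matrix(bmu_coordinates(lat, emb_som$coords)[, -1])
    })
    model_reduction(Y_list, labels, cfg$stats$reduction_candidates,
                    alpha = cfg$stats$alpha)
  })
  red_tbl <- if (!is.null(reduction$fit)) {
    purrr::imap_dfr(reduction$fit, function(f, i) {
      dplyr::mutate(f$table, fold = paste0("partition", i), .before = 1)
    }) |>
      dplyr::filter(.data$statistic == "Wilks") |>
      dplyr::select("fold", "term", "p_value") |>
      tidyr::pivot_wider(names_from = "fold", values_from = "p_value")
  } else {
    tibble::tibble(term = character())
  }
  readr::write_csv(red_tbl, file.path(out_dir, "manova_properties.csv"))

  manifest <- list(
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("handovr")),
    n_participants = nrow(dataset$participants),
    n_trials = nrow(dataset$trials),
    n_trajectories = nrow(dataset$trajectories),
    nmds_dims = cfg$nmds_dims,
    retained_factors = reduction$retained,
    outputs = list.files(out_dir, recursive = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = dataset, distances = D, embeddings = embeddings,
                 classification = classification, mi = mi, codes = codes,
                 manova = manova_res, reduction = reduction,
                 manifest = manifest, out_dir = out_dir))
}

# ---------------------------------------------------------------------------
# Trajectory serialization: one delimited file per trial-and-hand with a
# header `t, a01..a20`, plus a JSON sidecar carrying the trial record.

write_trial_files <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(dataset$trajectories))) {
    row <- dataset$trajectories[i, ]
    m <- row$angles[[1]]
    df <- tibble::as_tibble(m)
    df <- dplyr::mutate(df, t = (seq_len(nrow(m)) - 1) * dataset$config$dt,
                        .before = 1)
    base <- file.path(dir, row$traj_id)
    readr::write_csv(df, paste0(base, ".csv"))
    trial <- dataset$trials[dataset$trials$trial_id == row$trial_id, ]
    sidecar <- c(as.list(dplyr::select(trial, -dplyr::any_of("angles"))),
                 list(owner_id = row$owner_id, role = row$role,
                      dt = dataset$config$dt))
    jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(dir)
}

#' Load externally supplied trials and trajectories
#'
#' Reads a directory in the trajectory interchange format written by
#' [run_pipeline()]: per trajectory a delimited file (`t, a01..a20`) plus a
#' JSON sidecar with the trial record (condition factors, giver/receiver,
#' owner and role). Validates the schema and returns a `handover_dataset`
#' (without participant profiles unless a `participants.csv` is present).
#'
#' @param dir Directory containing `*.csv` trajectory files with `*.json`
#'   sidecars, and optionally `participants.csv`.
#' @return A `handover_dataset`.
#' @export
load_external_trials <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "participants.csv"]
  if (length(files) == 0) {
    abort(sprintf("no trajectory files found in '%s'.", dir),
          class = "handovr_schema_error")
  }
  trials_l <- list()
  trajs_l <- list()
  dt <- NULL
  for (f in files) {
    sidecar_path <- sub("\\.csv$", ".json", f)
    if (!file.exists(sidecar_path)) {
      abort(sprintf("missing sidecar for trajectory '%s'.", basename(f)),
            class = "handovr_schema_error")
    }
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    needed <- c("trial_id", "owner_id", "role", names(condition_levels()))
    missing <- setdiff(needed, names(side))
    if (length(missing) > 0) {
      abort(sprintf("sidecar '%s' lacks field(s): %s", basename(sidecar_path),
                    paste(missing, collapse = ", ")),
            class = "handovr_schema_error")
    }
    df <- readr::read_csv(f, show_col_types = FALSE)
    ang_cols <- setdiff(names(df), "t")
    if (length(ang_cols) != N_ANGLE_CHANNELS) {
      abort(sprintf("trajectory '%s' has %d angle channels; expected %d.",
                    basename(f), length(ang_cols), N_ANGLE_CHANNELS),
            class = "handovr_schema_error")
    }
    m <- as.matrix(df[, ang_cols])
    if (nrow(m) < 2 || any(!is.finite(m))) {
      abort(sprintf("trajectory '%s' is too short or non-finite.", basename(f)),
            class = "handovr_schema_error")
    }
    dt <- dt %||% side$dt %||% 0.01
    trials_l[[side$trial_id]] <- tibble::as_tibble(
      side[intersect(names(side),
                     c("trial_index", "trial_id", "pair_id", "condition_id",
                       names(condition_levels()), "giver_id", "receiver_id",
                       "replicate", "valid"))])
    trajs_l[[length(trajs_l) + 1L]] <- tibble::tibble(
      traj_id = sub("\\.csv$", "", basename(f)),
      trial_id = side$trial_id,
      pair_id = side$pair_id %||% NA_character_,
      owner_id = side$owner_id, role = side$role,
      n_steps = nrow(m), angles = list(m))
  }
  trials <- dplyr::distinct(dplyr::bind_rows(trials_l))
  if (!"valid" %in% names(trials)) trials$valid <- TRUE
  participants_path <- file.path(dir, "participants.csv")
  participants <- if (file.exists(participants_path)) {
    readr::read_csv(participants_path, show_col_types = FALSE)
  } else {
    tibble::tibble(identity = sort(unique(c(trials$giver_id, trials$receiver_id))))
  }
  structure(list(participants = participants, trials = trials,
                 trajectories = dplyr::bind_rows(trajs_l),
                 config = generator_config(dt = dt)),
            class = "handover_dataset")
}
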