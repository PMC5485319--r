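# Decision-forest artefact detection under subject-disjoint nested
# cross-validation.

#' Forest configuration for nested cross-validation
#'
#' @param n_trees Number of trees (default 100).
#' @param max_depth_grid Candidate maximum tree depths; 0 means unlimited
#'   (default `c(0, 8, 16)`).
#' @param min_leaf_grid Candidate minimum leaf sizes (default `c(1, 5)`).
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100, max_depth_grid = c(0, 8, 16),
                          min_leaf_grid = c(1, 5)) {
  if (!is_count(n_trees, 1) || length(max_depth_grid) < 1 ||
      length(min_leaf_grid) < 1) {
    stop_invalid("need n_trees >= 1 and non-empty hyperparameter grids")
  }
  structure(list(n_trees = as.integer(n_trees),
                 max_depth_grid = as.integer(max_depth_grid),
                 min_leaf_grid = as.integer(min_leaf_grid)),
            class = "forest_config")
}

#' Build a balanced one-image-per-subject dataset from clean/corrupted pairs
#'
#' For each subject, either the artefact-free or the artefact-degraded image
#' is picked at random, under the constraint that the two classes are
#' represented in exact balance (`floor(n/2)` vs `ceiling(n/2)`).
#' Deterministic per seed.
#'
#' @param pairs List of lists with elements `clean`, `corrupted`
#'   (both `mri_image`) and `subject_id`.
#' @param seed Integer seed.
#' @return A list with `images`, `labels` (0 = clean, 1 = corrupted), and
#'   `subject_ids`.
#' @export
build_paired_dataset <- function(pairs, seed) {
  ids <- vapply(pairs, function(p) as.character(p$subject_id), "")
  if (anyDuplicated(ids)) stop_invalid("subject_ids must be unique")
  n <- length(pairs)
  with_seed(derive_seed(seed, 505), {
    corrupted_idx <- sample(n, n %/% 2)
    labels <- integer(n)
    labels[corrupted_idx] <- 1L
    images <- vector("list", n)
    for (i in seq_len(n)) {
      images[[i]] <- if (labels[i] == 1L) pairs[[i]]$corrupted
                     else pairs[[i]]$clean
    }
    list(images = images, labels = labels, subject_ids = ids)
  })
}

# stratified fold assignment: within each class, shuffle and deal
# round-robin; returns integer fold id per row
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# max_depth 0 means unlimited; a depth-d binary tree has at most 2^d
# leaves, so the depth grid maps onto randomForest's maxnodes (capped at
# the training size, which is the largest attainable leaf count)
fit_forest <- function(X, y, n_trees, max_depth, min_leaf, seed) {
  maxnodes <- if (max_depth <= 0) NULL else
    min(2^max_depth, nrow(X))
  with_seed(seed, {
    randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                               ntree = n_trees, maxnodes = maxnodes,
                               nodesize = min_leaf)
  })
}

predict_forest <- function(fit, X) {
  as.integer(as.character(stats::predict(fit, X)))
}

#' Nested cross-validation accuracy of a decision forest
#'
#' Outer folds are stratified by label and disjoint by subject. Within each
#' outer training split, an inner k-fold grid search selects the
#' hyperparameter combination with the highest mean inner accuracy (ties go
#' to the first combination in grid order); a forest with that combination
#' is refit on the full outer-train split and scored on the outer-test
#' split. The overall accuracy pools all outer-test predictions.
#'
#' @param matrix A `feature_matrix`.
#' @param outer_k Number of outer folds (default 5).
#' @param inner_k Number of inner folds (default 3).
#' @param config A `forest_config`.
#' @param seed Integer seed controlling fold shuffling and forest training.
#' @return An object of class `artefact_cv` with fields `overall_accuracy`,
#'   `per_fold_accuracies`, `confusion` (TP, TN, FP, FN), `chosen` (selected
#'   hyperparameters per outer fold), and `seeds`.
#' @export
nested_cv_accuracy <- function(matrix, outer_k = 5, inner_k = 3,
                               config = forest_config(), seed = 1) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(config, "forest_config"))
  if (outer_k < 2 || inner_k < 2) stop_invalid("outer_k and inner_k must be >= 2")
  y <- matrix$label
  if (min(table(y)) < outer_k) {
    stop_invalid("need at least outer_k subjects per class")
  }
  X <- matrix[, setdiff(names(matrix), c("subject_id", "label")), drop = FALSE]
  X <- as.data.frame(X)
  grid <- expand.grid(max_depth = config$max_depth_grid,
                      min_leaf = config$min_leaf_grid,
                      KEEP.OUT.ATTRS = FALSE)
  outer_fold <- stratified_folds(y, outer_k, derive_seed(seed, 601))
  preds <- integer(length(y))
  per_fold <- numeric(outer_k)
  chosen <- vector("list", outer_k)
  for (of in seq_len(outer_k)) {
    tr <- which(outer_fold != of)
    te <- which(outer_fold == of)
    inner_fold <- stratified_folds(y[tr], inner_k, derive_seed(seed, 602, of))
    grid_acc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      acc <- numeric(inner_k)
      for (inf in seq_len(inner_k)) {
        itr <- tr[inner_fold != inf]
        ite <- tr[inner_fold == inf]
        fit <- fit_forest(X[itr, , drop = FALSE], y[itr], config$n_trees,
                          grid$max_depth[gi], grid$min_leaf[gi],
                          derive_seed(seed, 603, of, gi, inf))
        acc[inf] <- mean(predict_forest(fit, X[ite, , drop = FALSE]) == y[ite])
      }
      grid_acc[gi] <- mean(acc)
    }
    best <- which.max(grid_acc)  # first maximum = first in grid order
    chosen[[of]] <- list(max_depth = grid$max_depth[best],
                         min_leaf = grid$min_leaf[best],
                         inner_accuracy = grid_acc[best])
    fit <- fit_forest(X[tr, , drop = FALSE], y[tr], config$n_trees,
                      grid$max_depth[best], grid$min_leaf[best],
                      derive_seed(seed, 604, of))
    preds[te] <- predict_forest(fit, X[te, , drop = FALSE])
    per_fold[of] <- mean(preds[te] == y[te])
  }
  tp <- sum(preds == 1 & y == 1)
  tn <- sum(preds == 0 & y == 0)
  fp <- sum(preds == 1 & y == 0)
  fn <- sum(preds == 0 & y == 1)
  structure(list(overall_accuracy = (tp + tn) / length(y),
                 per_fold_accuracies = per_fold,
                 confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
                 chosen = chosen,
                 outer_fold = outer_fold,
                 predictions = preds,
                 seeds = list(master = seed)),
            class = "artefact_cv")
}

#' @export
print.artefact_cv <- function(x, ...) {
  cat("<artefact_cv> overall accuracy: ",
      sprintf("%.3f", x$overall_accuracy), "\n", sep = "")
  cat("  per-fold: ", paste(sprintf("%.3f", x$per_fold_accuracies),
                            collapse = " "), "\n", sep = "")
  cm <- x$confusion
  cat("  confusion TP/TN/FP/FN: ", paste(cm, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# ---- experiment driver -----------------------------------------------------

build_trajectory_from_config <- function(tc) {
  geom <- tc$geometry
  if (is.null(geom)) stop_invalid("trajectory config needs a 'geometry' field")
  switch(geom,
    cartesian = make_cartesian_trajectory(tc$n_lines,
                                          tc$n_samples %||% tc$n_lines),
    radial = make_radial_trajectory(tc$n_spokes,
                                    tc$n_samples %||% tc$n_spokes),
    spiral = make_spiral_trajectory(tc$n_interleaves, tc$n_samples,
                                    tc$n_turns %||% 8,
                                    tc$grid_size %||% 256),
    stop_invalid("unknown trajectory geometry '%s' (use cartesian, radial, or spiral)",
                 geom))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-subject simulation for one dataset seed. For bulk motion the rigid
# transform depends only on the subject seed, so the clean/moved k-space
# pair is computed once per subject and reused across all (offset, fraction)
# grid cells; merging and reconstruction are cheap by comparison.
simulate_subject_bank <- function(cfg, dataset_seed) {
  traj <- build_trajectory_from_config(cfg$trajectory)
  n <- cfg$n_subjects
  shape <- cfg$shape
  bank <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- derive_seed(dataset_seed, 701, i)
    if (identical(cfg$phantom, "cardiac")) {
      ph <- make_cardiac_phantom(sseed, shape)
      bank[[i]] <- list(volume = ph$volume, mask = ph$mask,
                        subject_id = sprintf("s%03d", i))
    } else {
      vol <- make_brain_phantom(sseed, shape)
      tf <- sample_bulk_transform(derive_seed(dataset_seed, 702, i),
                                  cfg$motion$max_translation_mm %||% 3.64,
                                  cfg$motion$max_rotation_deg %||% 5)
      kp <- bulk_kspace_pair(vol, tf, traj)
      bank[[i]] <- list(kpair = kp, subject_id = sprintf("s%03d", i))
    }
  }
  list(trajectory = traj, bank = bank)
}

run_cell_bulk <- function(sim, offset, fraction) {
  traj <- sim$trajectory
  sched <- bulk_schedule(traj$n_readouts, offset, fraction)
  lapply(sim$bank, function(b) {
    rec <- reconstruct_pair(b$kpair$clean,
                            merge_kspace(list(b$kpair$clean, b$kpair$moved),
                                         sched))
    list(clean = rec$clean, corrupted = rec$corrupted,
         subject_id = b$subject_id)
  })
}

#' Run a full detection experiment over a motion grid
#'
#' For each grid cell (bulk motion: offset x exchange fraction; respiratory
#' motion: breathing cycle count), generates per-subject phantoms, simulates
#' clean/corrupted pairs, builds a balanced one-image-per-subject dataset,
#' extracts features with one frozen spec set, and runs nested
#' cross-validation.
#'
#' @param config A nested list (or path to a YAML/JSON file) with fields:
#'   `phantom` ("brain" or "cardiac"), `shape`, `trajectory`
#'   (`geometry` plus its parameters), `motion` (`type` "bulk" with
#'   `offsets`/`fractions`, or "respiratory" with `cycles`,
#'   `max_displacement_mm`, `n_states`), `features` (per-kind `counts`),
#'   `n_subjects`, `cv` (`outer_k`, `inner_k`, `n_trees`, `max_depth_grid`,
#'   `min_leaf_grid`), `seed`, and optionally `n_dataset_seeds`.
#' @param verbose Print one line per grid cell.
#' @return An object of class `artefact_experiment` with a `results`
#'   data.frame (one row per grid cell and dataset seed), the per-cell CV
#'   details, and the config.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  cfg <- validate_experiment_config(config)
  master <- cfg$seed
  n_ds <- cfg$n_dataset_seeds %||% 1
  fc <- forest_config(cfg$cv$n_trees %||% 100,
                      cfg$cv$max_depth_grid %||% c(0, 8, 16),
                      cfg$cv$min_leaf_grid %||% c(1, 5))
  results <- list()
  details <- list()
  for (ds in seq_len(n_ds)) {
    ds_seed <- derive_seed(master, 801, ds)
    sim <- simulate_subject_bank(cfg, ds_seed)
    if (identical(cfg$motion$type, "respiratory")) {
      cells <- lapply(cfg$motion$cycles, function(cy) list(cycles = cy))
    } else {
      cells <- list()
      for (off in cfg$motion$offsets) {
        for (fr in cfg$motion$fractions) {
          cells[[length(cells) + 1]] <- list(offset = off, fraction = fr)
        }
      }
    }
    roi <- if (identical(cfg$phantom, "cardiac")) {
      compute_roi(lapply(sim$bank, `[[`, "mask"),
                  c(sim$trajectory$grid_size, sim$trajectory$grid_size))
    } else {
      compute_roi(NULL, c(sim$trajectory$grid_size, sim$trajectory$grid_size))
    }
    specs <- do.call(sample_feature_specs,
                     c(list(seed = derive_seed(master, 802), roi = roi),
                       cfg$features %||% list()))
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      t0 <- proc.time()[3]
      if (identical(cfg$motion$type, "respiratory")) {
        model <- respiratory_model(cell$cycles,
                                   cfg$motion$max_displacement_mm %||% 7,
                                   cfg$motion$n_states %||% 8)
        pairs <- lapply(sim$bank, function(b) {
          rec <- simulate_respiratory_artefact(b$volume, b$mask,
                                               sim$trajectory, model)
          list(clean = rec$clean, corrupted = rec$corrupted,
               subject_id = b$subject_id)
        })
      } else {
        pairs <- run_cell_bulk(sim, cell$offset, cell$fraction)
      }
      dset <- build_paired_dataset(pairs, derive_seed(ds_seed, 803, ci))
      fm <- extract_feature_matrix(dset$images, dset$labels,
                                   dset$subject_ids, specs)
      cv <- nested_cv_accuracy(fm, cfg$cv$outer_k %||% 5,
                               cfg$cv$inner_k %||% 3, fc,
                               derive_seed(ds_seed, 804, ci))
      row <- data.frame(dataset_seed = ds, accuracy = cv$overall_accuracy)
      for (nm in names(cell)) row[[nm]] <- cell[[nm]]
      results[[length(results) + 1]] <- row
      details[[length(details) + 1]] <- cv
      if (verbose) {
        cat(sprintf("[cell %d/%d ds %d] %s -> accuracy %.3f (%.1fs)\n",
                    ci, length(cells), ds,
                    paste(names(cell), unlist(cell), sep = "=",
                          collapse = " "),
                    cv$overall_accuracy, proc.time()[3] - t0))
      }
    }
  }
  structure(list(results = do.call(rbind, results),
                 details = details, config = cfg),
            class = "artefact_experiment")
}

#' @export
print.artefact_experiment <- function(x, ...) {
  cat("<artefact_experiment> ", nrow(x$results), " grid cells\n", sep = "")
  print(x$results)
  invisible(x)
}

read_experiment_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

validate_experiment_config <- function(cfg) {
  req <- c("phantom", "shape", "trajectory", "motion", "n_subjects", "seed")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) {
    stop_invalid("experiment config is missing field(s): %s",
                 paste(miss, collapse = ", "))
  }
  if (!cfg$phantom %in% c("brain", "cardiac")) {
    stop_invalid("config field 'phantom' must be 'brain' or 'cardiac', got '%s'",
                 cfg$phantom)
  }
  mt <- cfg$motion$type %||% "bulk"
  if (!mt %in% c("bulk", "respiratory")) {
    stop_invalid("config field 'motion.type' must be 'bulk' or 'respiratory', got '%s'", mt)
  }
  cfg$motion$type <- mt
  if (mt == "bulk" &&
      (is.null(cfg$motion$offsets) || is.null(cfg$motion$fractions))) {
    stop_invalid("bulk motion config needs 'motion.offsets' and 'motion.fractions'")
  }
  if (mt == "respiratory" && is.null(cfg$motion$cycles)) {
    stop_invalid("respiratory motion config needs 'motion.cycles'")
  }
  cfg$shape <- as.integer(cfg$shape)
  # the trajectory grid must match the phantom's in-plane size
  tr <- build_trajectory_from_config(cfg$trajectory)
  if (tr$grid_size != cfg$shape[1] || tr$grid_size != cfg$shape[2]) {
    stop_invalid("trajectory grid_size (%d) must equal in-plane shape (%d x %d)",
                 tr$grid_size, cfg$shape[1], cfg$shape[2])
  }
  cfg
}
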