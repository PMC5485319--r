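# feature matrices for classifier tests are built directly (no imaging),
# which keeps the CV machinery tests fast and focused
synthetic_feature_matrix <- function(n, p = 10, signal = 0, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + signal * labels
  out <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                    label = labels, X)
  class(out) <- c("feature_matrix", "data.frame")
  out
}

test_that("paired dataset is exactly balanced with one image per subject", {
  pairs <- lapply(1:60, function(i) {
    list(clean = image2d(matrix(0, 8, 8)), corrupted = image2d(matrix(1, 8, 8)),
         subject_id = paste0("subj", i))
  })
  d <- build_paired_dataset(pairs, seed = 3)
  expect_equal(sum(d$labels == 0), 30)
  expect_equal(sum(d$labels == 1), 30)
  expect_equal(sort(d$subject_ids), sort(paste0("subj", 1:60)))
  # picked image matches its label
  for (i in seq_len(60)) {
    expect_equal(unique(as.vector(d$images[[i]]$data)), d$labels[i])
  }
  d2 <- build_paired_dataset(pairs, seed = 3)
  expect_identical(d$labels, d2$labels)
  d3 <- build_paired_dataset(pairs, seed = 4)
  expect_false(identical(d$labels, d3$labels))

  pairs[[2]]$subject_id <- "subj1"
  expect_error(build_paired_dataset(pairs, 1), "unique")
})

test_that("nested CV separates a perfectly informative feature", {
  fm <- synthetic_feature_matrix(40, signal = 50)
  cv <- nested_cv_accuracy(fm, outer_k = 5, inner_k = 3,
                           config = forest_config(n_trees = 50), seed = 2)
  expect_equal(cv$overall_accuracy, 1)
  expect_equal(unname(cv$confusion["TP"] + cv$confusion["TN"]), 40)
})

test_that("nested CV is deterministic and subject-disjoint across folds", {
  fm <- synthetic_feature_matrix(40, signal = 1)
  cv1 <- nested_cv_accuracy(fm, config = forest_config(n_trees = 30), seed = 5)
  cv2 <- nested_cv_accuracy(fm, config = forest_config(n_trees = 30), seed = 5)
  expect_identical(cv1$overall_accuracy, cv2$overall_accuracy)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(vapply(cv1$chosen, `[[`, 0, "max_depth"),
                   vapply(cv2$chosen, `[[`, 0, "max_depth"))

  # each subject (row) appears in exactly one outer test fold
  expect_equal(sort(unique(cv1$outer_fold)), 1:5)
  expect_equal(length(cv1$outer_fold), 40)
  for (f in 1:5) {
    tr_subj <- fm$subject_id[cv1$outer_fold != f]
    te_subj <- fm$subject_id[cv1$outer_fold == f]
    expect_length(intersect(tr_subj, te_subj), 0)
  }
})

test_that("uninformative features score at chance level", {
  fm <- synthetic_feature_matrix(200, signal = 0)
  cv <- nested_cv_accuracy(fm, config = forest_config(n_trees = 50), seed = 7)
  # central 99% binomial interval around 0.5 at n = 200
  half <- stats::qnorm(0.995) * sqrt(0.25 / 200)
  expect_gt(cv$overall_accuracy, 0.5 - half)
  expect_lt(cv$overall_accuracy, 0.5 + half)
})

test_that("nested CV input validation", {
  fm <- synthetic_feature_matrix(6)
  expect_error(nested_cv_accuracy(fm, outer_k = 5, inner_k = 3), "per class")
  expect_error(nested_cv_accuracy(synthetic_feature_matrix(40), outer_k = 1),
               ">= 2")
})

test_that("run_experiment: a no-exchange grid cell is unlearnable", {
  cfg <- list(phantom = "brain", shape = c(48, 48, 32),
              trajectory = list(geometry = "cartesian", n_lines = 48),
              motion = list(type = "bulk", offsets = 0.2, fractions = 0),
              features = list(counts = c(box = 50)),
              n_subjects = 20,
              cv = list(outer_k = 5, inner_k = 2,
                        n_trees = 50, max_depth_grid = 8, min_leaf_grid = 1),
              seed = 31)
  ex <- run_experiment(cfg)
  expect_equal(nrow(ex$results), 1)
  expect_equal(ex$results$fraction, 0)
  # chance level at n = 20: generous binomial bound
  expect_gte(ex$results$accuracy, 0.15)
  expect_lte(ex$results$accuracy, 0.85)
})

test_that("run_experiment table mirrors the motion grid", {
  cfg <- list(phantom = "brain", shape = c(48, 48, 32),
              trajectory = list(geometry = "cartesian", n_lines = 48),
              motion = list(type = "bulk", offsets = c(0.1, 0.5),
                            fractions = c(0.1, 0.3)),
              features = list(counts = c(box = 50)),
              n_subjects = 12,
              cv = list(outer_k = 3, inner_k = 2, n_trees = 30,
                        max_depth_grid = 8, min_leaf_grid = 1),
              seed = 32)
  ex <- run_experiment(cfg)
  expect_equal(nrow(ex$results), 4)
  expect_setequal(ex$results$offset, c(0.1, 0.1, 0.5, 0.5))
  expect_setequal(ex$results$fraction, c(0.1, 0.3, 0.1, 0.3))
  expect_true(all(ex$results$accuracy >= 0 & ex$results$accuracy <= 1))
})

test_that("experiment config validation names the offending field", {
  expect_error(run_experiment(list(phantom = "brain")), "missing field")
  cfg <- list(phantom = "lung", shape = c(48, 48, 32),
              trajectory = list(geometry = "cartesian", n_lines = 48),
              motion = list(type = "bulk", offsets = 0, fractions = 0),
              n_subjects = 4, seed = 1)
  expect_error(run_experiment(cfg), "phantom")
  cfg$phantom <- "brain"
  cfg$trajectory$geometry <- "zigzag"
  expect_error(run_experiment(cfg), "zigzag")
})
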