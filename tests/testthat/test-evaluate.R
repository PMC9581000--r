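test_that("metrics match hand-computed confusion-matrix arithmetic", {
  truth <- c(0, 0, 1, 1, 2, 2)
  pred <- c(0, 1, 1, 1, 2, 0)
  # class 0: P = 1/2, R = 1/2, F1 = 1/2; class 1: P = 2/3, R = 1 -> 4/5;
  # class 2: P = 1, R = 1/2 -> 2/3. Equal support -> mean
  expect_equal(f1_weighted(truth, pred), mean(c(1/2, 4/5, 2/3)))
  expect_equal(f1_weighted(truth, truth), 1)
  # R2 against explicit sums of squares
  y <- c(1, 3, 5, 7); yh <- c(2, 3, 4, 8)
  expect_equal(r_squared(y, yh), 1 - sum((y - yh)^2) / sum((y - mean(y))^2))
  # MCC: binary case cross-checked against the classic formula
  t2 <- c(0, 0, 0, 1, 1, 1); p2 <- c(0, 0, 1, 1, 1, 0)
  tp <- 2; tn <- 2; fp <- 1; fn <- 1
  expect_equal(mcc(t2, p2),
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  expect_equal(mcc(t2, t2), 1)
})

test_that("cross-validation yields one score pair per repeat with stable CoV", {
  gen <- planted_library(S = 60, R = 10, noise_fraction = 0.2, seed = 13)
  es <- estimator_spec("RF", "regression")
  cv <- cross_validate(gen$library, es, response_value = 1,
                       params = list(num_trees = 100), repeats = 25, seed = 5)
  expect_equal(nrow(cv$scores), 25L)
  expect_named(cv$scores, c("repeat_id", "train_score", "test_score",
                            "test_mcc"))
  # CoV recomputed independently from the stored per-repeat scores
  expect_equal(cv$cov_test, sd(cv$scores$test_score) / mean(cv$scores$test_score))
  expect_equal(glance(cv)$mean_test, mean(tidy(cv)$test_score))
  expect_error(cross_validate(gen$library, es, repeats = 1),
               class = "promoterkit_value_error")
})

test_that("noiseless planted regression cross-validates accurately", {
  gen <- generate_library(synthetic_spec(R = 12, S = 200, n_causal = 3,
                                         mutation_rate = 0.5,
                                         noise_fraction = 0, seed = 17))
  cv <- cross_validate(gen$library, estimator_spec("RF", "regression"),
                       response_value = 1, params = list(num_trees = 200),
                       repeats = 10, seed = 3)
  expect_gte(cv$mean_test, 0.8)
})

test_that("no sequence string leaks across any CV split", {
  base <- random_library(30, 8, seed = 14)
  reps <- make_library(rep(base$sequence[1:3], each = 2),
                       expression = rnorm(6), ids = paste0("rr", 1:6))
  lib <- merge_libraries(base, reps)
  seen <- new.env()
  trace_splits <- function(repeats, seed) {
    for (r in seq_len(repeats)) {
      sp <- split_train_test(lib, 0.9, seed = seed + r)
      expect_length(intersect(unique(sp$train$sequence),
                              unique(sp$test$sequence)), 0)
    }
  }
  trace_splits(25, 100)
})

test_that("confusion matrices conserve counts and flag task mismatch", {
  gen <- planted_library(S = 90, R = 8, noise_fraction = 0, seed = 15)
  lib <- gen$library
  fs <- select_positions(lib, 0.2)
  ts <- target_spec(lib$expression, 3)
  est <- grid_search_train(lib,
                           estimator_spec("RF", "classification",
                                          grid = list(num_trees = 300),
                                          tuning_repeats = 1),
                           fs, ts)
  cm <- confusion_matrix(est, lib)
  expect_equal(dim(cm), c(3L, 3L))
  expect_equal(sum(cm), nrow(lib))
  # row sums = true class counts
  truth <- apply_bins(lib$expression, ts$bin_edges)
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(truth))))

  reg <- grid_search_train(lib,
                           estimator_spec("RF", "regression",
                                          grid = list(num_trees = 50),
                                          tuning_repeats = 1),
                           fs, target_spec(lib$expression, 1))
  expect_error(confusion_matrix(reg, lib),
               class = "promoterkit_estimator_error")
})

test_that("a perfect predictor yields a diagonal confusion matrix", {
  # noiseless, deep forest, training-set evaluation: expected near-perfect;
  # assert structure on the truly diagonal fixture via predictions == truth
  gen <- planted_library(S = 60, R = 8, noise_fraction = 0, seed = 16)
  lib <- gen$library
  est <- grid_search_train(lib,
                           estimator_spec("RF", "classification",
                                          grid = list(num_trees = 500),
                                          tuning_repeats = 1),
                           select_positions(lib, 0), target_spec(lib$expression, 3))
  cm <- confusion_matrix(est, lib)
  if (sum(diag(cm)) == sum(cm)) {
    expect_equal(unname(diag(cm)),
                 unname(as.vector(table(apply_bins(lib$expression,
                                                   est$target_spec$bin_edges)))))
  }
  expect_equal(sum(cm), nrow(lib))
})

test_that("tree-ensemble importances normalize and recover causal positions", {
  gen <- generate_library(synthetic_spec(R = 20, S = 150, n_causal = 3,
                                         effect_size = 2, mutation_rate = 0.3,
                                         noise_fraction = 0.1, seed = 19))
  lib <- gen$library
  fs <- select_positions(lib, 0.2)
  est <- grid_search_train(lib,
                           estimator_spec("RF", "regression",
                                          grid = list(num_trees = 500),
                                          tuning_repeats = 1),
                           fs, target_spec(lib$expression, 1))
  prof <- feature_importance(est)
  total <- sum(prof$matrix) + prof$gc_importance
  expect_equal(total, 1, tolerance = 1e-9)
  expect_true(all(prof$matrix >= 0))
  top3 <- position_importance(prof)$position[1:3]
  expect_setequal(top3, gen$truth$causal_labels)

  svm_est <- grid_search_train(lib,
                               estimator_spec("SVM", "regression",
                                              grid = list(cost = 1, gamma = NA),
                                              tuning_repeats = 1),
                               fs, target_spec(lib$expression, 1))
  expect_error(feature_importance(svm_est),
               class = "promoterkit_estimator_error")
})

test_that("GBT importances map back onto position-nucleotide cells", {
  gen <- planted_library(S = 80, R = 10, noise_fraction = 0.1, seed = 20)
  lib <- gen$library
  est <- grid_search_train(lib,
                           estimator_spec("GBT", "regression",
                                          grid = list(num_trees = 100,
                                                      learning_rate = 0.1,
                                                      max_depth = 3),
                                          tuning_repeats = 1),
                           select_positions(lib, 0.2),
                           target_spec(lib$expression, 1))
  prof <- feature_importance(est)
  expect_equal(sum(prof$matrix) + prof$gc_importance, 1, tolerance = 1e-6)
})

test_that("exported artifacts round-trip and guard the tree index", {
  gen <- planted_library(S = 50, R = 8, seed = 23)
  lib <- gen$library
  es <- estimator_spec("RF", "regression")
  cv <- cross_validate(lib, es, response_value = 1,
                       params = list(num_trees = 50), repeats = 3, seed = 2)
  est <- grid_search_train(lib,
                           estimator_spec("RF", "regression",
                                          grid = list(num_trees = 50),
                                          tuning_repeats = 1),
                           select_positions(lib, 0.2),
                           target_spec(lib$expression, 1))
  prof <- feature_importance(est)
  dir <- withr::local_tempdir()
  paths <- export_artifacts(cv, prof, est,
                            out_prefix = file.path(dir, "run"),
                            tree_index = 1)
  expect_true(all(file.exists(paths)))
  m <- read_importance_csv(file.path(dir, "run_importance.csv"))
  expect_equal(m[c("A", "C", "G", "T"), ], prof$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m["GC", 1], prof$gc_importance, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(export_artifacts(cv, prof, est,
                                out_prefix = file.path(dir, "run"),
                                tree_index = 10000),
               class = "promoterkit_value_error")
})

test_that("permuted targets give chance-level scores (negative control)", {
  gen <- generate_library(synthetic_spec(R = 12, S = 120, n_causal = 3,
                                         mutation_rate = 0.4,
                                         noise_fraction = 0.1, seed = 29))
  lib <- gen$library
  set.seed(31)
  lib$expression <- sample(lib$expression)
  cv <- cross_validate(lib, estimator_spec("RF", "regression"),
                       response_value = 1, params = list(num_trees = 100),
                       repeats = 10, seed = 7)
  expect_lte(cv$mean_test, 0.1)
  cvc <- cross_validate(lib, estimator_spec("RF", "classification"),
                        response_value = 3, params = list(num_trees = 100),
                        repeats = 10, seed = 9)
  # chance level for 3 balanced classes is 1/3
  expect_lt(abs(cvc$mean_test - 1 / 3), 3 * sd(cvc$scores$test_score))
})
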