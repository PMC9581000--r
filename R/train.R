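# Model fitting: RF / GBT / SVM with repeated-split hyperparameter search.

#' Default hyperparameter grids
#'
#' Candidate grids used when an [estimator_spec()] does not override them.
#' `max_depth = 0` means unlimited depth; `gamma = NA` requests the
#' scale heuristic `1 / (n_features * var(X))`.
#'
#' @param kind One of `"RF"`, `"GBT"`, `"SVM"`.
#' @return A named list of candidate value vectors.
#' @export
default_grid <- function(kind) {
  switch(kind,
    RF = list(num_trees = c(100, 300, 1000), max_depth = c(0, 5, 10),
              min_node = c(1, 3)),
    GBT = list(num_trees = c(100, 300), learning_rate = c(0.01, 0.1),
               max_depth = c(2, 3, 5)),
    SVM = list(cost = c(0.1, 1, 10, 100), gamma = c(NA, 0.01, 0.1)),
    abort(paste0("Unknown estimator kind: ", kind),
          class = "promoterkit_estimator_error"))
}

#' Estimator specification
#'
#' Describes which model family to fit, the prediction task, the
#' hyperparameter grid, and how the grid is scored: each candidate is
#' evaluated as the mean validation score over `tuning_repeats` seeded
#' replicate-joint 9:1 splits of the training data (weighted F1 for
#' classification, R2 for regression).
#'
#' @param kind `"RF"` (random forest), `"GBT"` (gradient boosted trees) or
#'   `"SVM"` (RBF-kernel support vector machine).
#' @param task `"regression"` or `"classification"`.
#' @param grid Named list of candidate hyperparameter values; defaults to
#'   [default_grid()].
#' @param tuning_repeats Number of tuning splits per grid point (default 100).
#' @param tuning_train_fraction Train fraction of each tuning split.
#' @param seed Integer seed.
#' @return An object of class `estimator_spec`.
#' @export
estimator_spec <- function(kind = c("RF", "GBT", "SVM"),
                           task = c("regression", "classification"),
                           grid = NULL, tuning_repeats = 100L,
                           tuning_train_fraction = 0.9, seed = 1L) {
  if (!is.character(kind) || !kind[1] %in% c("RF", "GBT", "SVM")) {
    abort(paste0("Unknown estimator kind: ", kind[1]),
          class = "promoterkit_estimator_error")
  }
  kind <- kind[1]
  task <- match.arg(task)
  grid <- grid %||% default_grid(kind)
  if (length(grid) == 0) abort("Hyperparameter grid must be nonempty",
                               class = "promoterkit_value_error")
  if (tuning_repeats < 1) abort("tuning_repeats must be >= 1",
                                class = "promoterkit_value_error")
  structure(list(kind = kind, task = task, grid = grid,
                 tuning_repeats = as.integer(tuning_repeats),
                 tuning_train_fraction = tuning_train_fraction,
                 seed = as.integer(seed)),
            class = "estimator_spec")
}

grid_points <- function(grid) {
  # cross-product, first key varying fastest; order fixes tie-breaking
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

fit_model <- function(kind, task, params, X, y, seed) {
  if (task == "classification") y <- factor(y, levels = sort(unique(y)))
  if (kind == "RF") {
    # classic RF defaults: mtry = p/3 for regression, sqrt(p) for classification
    mtry <- params$mtry %||% if (task == "regression")
      max(1L, floor(ncol(X) / 3)) else max(1L, floor(sqrt(ncol(X))))
    ranger::ranger(
      x = X, y = y,
      num.trees = params$num_trees %||% 300,
      mtry = min(mtry, ncol(X)),
      max.depth = params$max_depth %||% 0,
      min.node.size = params$min_node %||% if (task == "regression") 5 else 1,
      importance = "impurity", seed = seed, num.threads = 1
    )
  } else if (kind == "GBT") {
    nclass <- if (task == "classification") length(levels(y)) else 0L
    obj <- if (task == "classification") "multi:softmax" else "reg:squarederror"
    prm <- list(eta = params$learning_rate %||% 0.1,
                max_depth = params$max_depth %||% 3,
                objective = obj, nthread = 1)
    if (task == "classification") prm$num_class <- nclass
    prm$seed <- seed
    ylab <- if (task == "classification") as.integer(y) - 1L else y
    dtrain <- xgboost::xgb.DMatrix(X, label = ylab, nthread = 1)
    booster <- xgboost::xgb.train(params = prm, data = dtrain,
                                  nrounds = params$num_trees %||% 100,
                                  verbose = 0)
    structure(list(booster = booster, levels = levels(y)),
              class = "promoterkit_gbt")
  } else if (kind == "SVM") {
    gamma <- params$gamma
    if (is.null(gamma) || is.na(gamma)) {
      v <- stats::var(as.vector(X))
      gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
    }
    e1071::svm(x = X, y = y, kernel = "radial",
               cost = params$cost %||% 1, gamma = gamma, scale = FALSE)
  } else {
    abort(paste0("Unknown estimator kind: ", kind),
          class = "promoterkit_estimator_error")
  }
}

predict_model <- function(model, kind, task, X) {
  if (kind == "RF") {
    p <- predict(model, data = X, num.threads = 1)$predictions
  } else if (kind == "GBT") {
    p <- predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
    if (task == "classification") p <- model$levels[p + 1L]
  } else {
    p <- predict(model, X)
  }
  if (task == "classification") as.integer(as.character(p)) else as.numeric(p)
}

#' Train an estimator with grid-search hyperparameter tuning
#'
#' For every grid point the tuning score is the mean validation score over
#' `tuning_repeats` replicate-joint 9:1 splits of the training library; the
#' best grid point (ties broken by grid order) is then refit on the full
#' training set. Scores are R2 for regression and weighted F1 for
#' classification.
#'
#' @param train_lib The training promoter library.
#' @param espec An [estimator_spec()].
#' @param fspec A [select_positions()] feature spec derived from `train_lib`.
#' @param tspec A [target_spec()] built from the training expression values.
#' @param column Expression column; defaults to the first.
#' @return An object of class `trained_estimator` holding the fitted model,
#'   the feature/target specs, `best_params` and the per-candidate
#'   `tuning_scores` tibble.
#' @export
grid_search_train <- function(train_lib, espec, fspec, tspec, column = NULL) {
  column <- primary_expr(train_lib, column)
  X <- one_hot_encode(train_lib, fspec)
  y <- encode_targets(tspec, train_lib[[column]])
  if (tspec$task == "classification" &&
      length(unique(y)) < tspec$response_value) {
    abort("A class is absent from the training data",
          class = "promoterkit_value_error")
  }
  pts <- grid_points(espec$grid)
  can_tune <- length(unique(train_lib$sequence)) >= 2
  scores <- matrix(NA_real_, length(pts), espec$tuning_repeats)
  if (can_tune && length(pts) > 1) {
    for (r in seq_len(espec$tuning_repeats)) {
      sp <- split_train_test(train_lib, espec$tuning_train_fraction,
                             seed = espec$seed + r)
      Xa <- one_hot_encode(sp$train, fspec); Xb <- one_hot_encode(sp$test, fspec)
      ya <- encode_targets(tspec, sp$train[[column]])
      yb <- encode_targets(tspec, sp$test[[column]])
      for (g in seq_along(pts)) {
        sc <- tryCatch({
          mdl <- fit_model(espec$kind, espec$task, pts[[g]], Xa, ya,
                           seed = espec$seed + r)
          pred <- predict_model(mdl, espec$kind, espec$task, Xb)
          score_predictions(tspec$task, yb, pred)
        }, error = function(e) NA_real_)
        scores[g, r] <- sc
      }
    }
  }
  mean_scores <- rowMeans(scores, na.rm = TRUE)
  if (all(is.nan(mean_scores))) {
    if (can_tune && length(pts) > 1) {
      abort("All grid points failed during tuning",
            class = "promoterkit_value_error")
    }
    mean_scores <- rep(0, length(pts))
  }
  best <- which.max(replace(mean_scores, is.nan(mean_scores), -Inf))
  model <- fit_model(espec$kind, espec$task, pts[[best]], X, y,
                     seed = espec$seed)
  tuning <- tibble::tibble(
    candidate = vapply(pts, function(p)
      paste(names(p), unlist(p), sep = "=", collapse = ","), ""),
    mean_score = mean_scores,
    sd_score = apply(scores, 1, sd, na.rm = TRUE)
  )
  structure(list(spec = espec, feature_spec = fspec, target_spec = tspec,
                 model = model, best_params = pts[[best]],
                 tuning_scores = tuning, column = column,
                 train_targets = train_lib[[column]],
                 position_labels = position_labels(train_lib),
                 seq_length = seq_length(train_lib)),
            class = "trained_estimator")
}

#' @export
print.trained_estimator <- function(x, ...) {
  cat("Trained", x$spec$kind, x$spec$task, "estimator;",
      n_features(x$feature_spec), "features\n")
  cat("Best parameters:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict expression from promoter sequences
#'
#' Applies the stored feature spec (entropy-retained positions, GC flag) and
#' target spec (inverse standardization for `response_value = 0`) to new
#' sequences. Predictions are deterministic.
#'
#' @param object A [grid_search_train()] fit.
#' @param sequences Character vector of A/C/G/T sequences of the training
#'   length, or a data frame / promoter library with a `sequence` column.
#' @param ... Unused.
#' @return Numeric predictions (regression, original scale) or integer class
#'   labels 0..k-1 (classification).
#' @export
predict.trained_estimator <- function(object, sequences, ...) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (any(grepl("[^ACGT]", sequences))) {
    abort("Sequences must use A/C/G/T only", class = "promoterkit_alphabet_error")
  }
  if (any(nchar(sequences) != object$seq_length)) {
    abort(paste0("Sequences must have the training length ",
                 object$seq_length), class = "promoterkit_length_error")
  }
  lib <- tibble::tibble(id = as.character(seq_along(sequences)),
                        sequence = sequences)
  attr(lib, "position_labels") <- object$position_labels
  X <- one_hot_encode(lib, object$feature_spec)
  p <- predict_model(object$model, object$spec$kind, object$spec$task, X)
  if (object$spec$task == "regression") decode_targets(object$target_spec, p)
  else p
}

#' Save or load a trained estimator
#'
#' The fitted model is serialized with `saveRDS()`; the feature and target
#' specifications are additionally written to a human-readable JSON sidecar
#' (`<path>.spec.json`) so that a prediction setup is reproducible and
#' auditable without deserializing the model.
#'
#' @param est A trained estimator.
#' @param path Destination file path.
#' @return `path` (`save_estimator`) or the estimator (`load_estimator`).
#' @export
save_estimator <- function(est, path) {
  saveRDS(est, path)
  sidecar <- list(
    kind = est$spec$kind, task = est$spec$task,
    best_params = est$best_params,
    feature_spec = list(
      retained_positions = est$feature_spec$retained_positions,
      nucleotide_order = est$feature_spec$nucleotide_order,
      include_gc = est$feature_spec$include_gc,
      entropy_cutoff_bits = est$feature_spec$entropy_cutoff_bits),
    target_spec = est$target_spec[setdiff(names(est$target_spec), "class")]
  )
  jsonlite::write_json(sidecar, paste0(path, ".spec.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  readRDS(path)
}
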