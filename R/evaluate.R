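# Performance evaluation: repeated replicate-joint CV, confidence,
# feature importance, artifact export.

#' Repeated replicate-joint cross-validation
#'
#' Evaluates an estimator configuration with `repeats` independent 9:1
#' train/test splits that jointly move identical sequences (replicates) to
#' one side, so test sequences are never seen in training. Feature selection
#' (the entropy cutoff) is re-derived on each training fold to avoid
#' selection leakage. The summary reports the mean, standard deviation and
#' coefficient of variation (sd/mean) of the test scores — the workflow's
#' prediction-confidence measure.
#'
#' @param lib A promoter library.
#' @param espec An [estimator_spec()]. During CV each fold is fit with
#'   `params` (no per-fold grid search).
#' @param response_value Target coding (see [target_spec()]).
#' @param entropy_cutoff_bits Entropy cutoff re-applied per training fold.
#' @param include_gc Whether GC content is a feature.
#' @param params Hyperparameters for the per-fold fits; defaults to the
#'   first point of the spec's grid.
#' @param repeats Number of CV repeats (default 25).
#' @param train_fraction Train fraction of each split (default 0.9).
#' @param seed Integer seed.
#' @param column Expression column; defaults to the first.
#' @param with_mcc Also record the Matthews correlation coefficient
#'   (classification only).
#' @return An object of class `promoter_cv` with a `scores` tibble (one row
#'   per repeat: train_score, test_score), summary statistics, and the
#'   settings echo. Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
cross_validate <- function(lib, espec, response_value = 1L,
                           entropy_cutoff_bits = 0.2, include_gc = TRUE,
                           params = NULL, repeats = 25L, train_fraction = 0.9,
                           seed = 1L, column = NULL, with_mcc = FALSE) {
  if (repeats < 2) abort("repeats must be >= 2", class = "promoterkit_value_error")
  column <- primary_expr(lib, column)
  params <- params %||% grid_points(espec$grid)[[1]]
  rows <- vector("list", repeats)
  excluded <- 0L
  for (r in seq_len(repeats)) {
    sp <- split_train_test(lib, train_fraction, seed = seed + r)
    tsp <- tryCatch(target_spec(sp$train[[column]], response_value),
                    error = function(e) NULL)
    ok <- !is.null(tsp)
    if (ok && tsp$task == "classification") {
      ytr <- encode_targets(tsp, sp$train[[column]])
      ok <- length(unique(ytr)) == response_value
    }
    if (!ok) {
      warn(paste0("Repeat ", r, " excluded (degenerate training targets)"))
      excluded <- excluded + 1L
      next
    }
    fsp <- select_positions(sp$train, entropy_cutoff_bits, include_gc)
    Xtr <- one_hot_encode(sp$train, fsp)
    Xte <- one_hot_encode(sp$test, fsp)
    ytr <- encode_targets(tsp, sp$train[[column]])
    yte <- encode_targets(tsp, sp$test[[column]])
    mdl <- fit_model(espec$kind, espec$task, params, Xtr, ytr, seed = seed + r)
    ptr <- predict_model(mdl, espec$kind, espec$task, Xtr)
    pte <- predict_model(mdl, espec$kind, espec$task, Xte)
    rows[[r]] <- tibble::tibble(
      repeat_id = r,
      train_score = score_predictions(espec$task, ytr, ptr),
      test_score = score_predictions(espec$task, yte, pte),
      test_mcc = if (with_mcc && espec$task == "classification")
        mcc(yte, pte) else NA_real_
    )
  }
  if (excluded > repeats / 2) {
    abort("More than half of the CV repeats were excluded",
          class = "promoterkit_value_error")
  }
  scores <- dplyr::bind_rows(rows)
  mts <- mean(scores$test_score)
  sdts <- sd(scores$test_score)
  if (is.finite(mts) && abs(mts) < 1e-8) {
    warn("Mean test score is near zero; coefficient of variation is unstable")
  }
  structure(list(
    scores = scores,
    metric = if (espec$task == "regression") "R2" else "weighted F1",
    mean_test = mts, sd_test = sdts, cov_test = sdts / mts,
    mean_train = mean(scores$train_score),
    n_repeats = repeats, n_excluded = excluded,
    settings = list(kind = espec$kind, task = espec$task, params = params,
                    response_value = response_value,
                    entropy_cutoff_bits = entropy_cutoff_bits,
                    train_fraction = train_fraction, seed = seed)
  ), class = "promoter_cv")
}

#' @export
print.promoter_cv <- function(x, ...) {
  cat("Cross-validation (", nrow(x$scores), " repeats, ", x$metric, ")\n",
      sep = "")
  cat("  mean test score ", signif(x$mean_test, 4),
      " (sd ", signif(x$sd_test, 4),
      ", CoV ", signif(x$cov_test, 4), ")\n", sep = "")
  invisible(x)
}

#' Confusion matrix of a classification estimator on a library
#'
#' @param est A trained classification estimator.
#' @param lib A promoter library to evaluate (true classes are derived from
#'   its expression values through the estimator's stored bin edges).
#' @param column Expression column; defaults to the estimator's.
#' @return A k x k integer matrix; rows are true classes, columns predicted.
#'   Entries sum to `nrow(lib)`.
#' @export
confusion_matrix <- function(est, lib, column = NULL) {
  if (est$spec$task != "classification") {
    abort("Confusion matrices require a classification estimator",
          class = "promoterkit_estimator_error")
  }
  column <- column %||% est$column
  truth <- encode_targets(est$target_spec, lib[[column]])
  pred <- predict(est, lib$sequence)
  lev <- est$target_spec$class_labels
  cm <- table(factor(truth, lev), factor(pred, lev))
  m <- matrix(as.integer(cm), nrow = length(lev),
              dimnames = list(true = lev, predicted = lev))
  m
}

#' Feature importance of a tree-based estimator
#'
#' Extracts impurity-based feature importances (normalized to sum to 1) and
#' maps them back onto (position, nucleotide) cells plus the GC-content
#' feature. Only the tree ensembles (RF, GBT) expose importances; SVM errors.
#'
#' @param est A trained RF or GBT estimator.
#' @param top_k How many top features to tabulate.
#' @return An object of class `importance_profile` with `matrix` (4 x P,
#'   rows A/C/G/T), `gc_importance`, `positions` and a `top` tibble sorted
#'   descending.
#' @export
feature_importance <- function(est, top_k = 10L) {
  kind <- est$spec$kind
  fs <- est$feature_spec
  feat_names <- colnames(one_hot_encode(
    structure(tibble::tibble(id = "x",
                             sequence = strrep("A", est$seq_length)),
              position_labels = est$position_labels), fs))
  if (kind == "RF") {
    imp <- ranger::importance(est$model)
  } else if (kind == "GBT") {
    it <- xgboost::xgb.importance(model = est$model$booster)
    imp <- setNames(rep(0, length(feat_names)), feat_names)
    imp[it$Feature] <- it$Gain
  } else {
    abort("Feature importance is only defined for tree-based estimators (RF, GBT)",
          class = "promoterkit_estimator_error")
  }
  imp <- imp[feat_names]
  imp[is.na(imp)] <- 0
  if (sum(imp) > 0) imp <- imp / sum(imp)
  P <- length(fs$retained_positions)
  m <- matrix(imp[seq_len(4L * P)], nrow = 4,
              dimnames = list(NUCLEOTIDES, fs$retained_positions))
  gc_imp <- if (fs$include_gc) unname(imp[["GC"]]) else NA_real_
  long <- tibble::tibble(
    position = rep(fs$retained_positions, each = 4),
    nucleotide = rep(NUCLEOTIDES, P),
    importance = as.vector(m)
  )
  if (fs$include_gc) {
    long <- dplyr::bind_rows(long, tibble::tibble(
      position = NA_integer_, nucleotide = "GC", importance = gc_imp))
  }
  top <- dplyr::slice_max(long, .data$importance, n = top_k, with_ties = FALSE)
  structure(list(matrix = m, gc_importance = gc_imp,
                 positions = fs$retained_positions, top = top),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat("Feature importance over", length(x$positions), "positions")
  if (!is.na(x$gc_importance)) cat(" + GC (", signif(x$gc_importance, 3), ")",
                                   sep = "")
  cat("\nTop features:\n")
  print(utils::head(as.data.frame(x$top), 5))
  invisible(x)
}

#' Aggregate importance per position
#'
#' Sums the four nucleotide importances at each position, the usual
#' ranking for identifying critical promoter positions.
#'
#' @param profile An [feature_importance()] result.
#' @return A tibble with `position` and `importance`, sorted descending.
#' @export
position_importance <- function(profile) {
  tibble::tibble(position = profile$positions,
                 importance = colSums(profile$matrix)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Export evaluation artifacts
#'
#' Writes (a) the importance matrix as a CSV consumable by logo renderers
#' (rows A, C, G, T and GC; columns = position labels), (b) the per-repeat
#' evaluation summary CSV, and optionally (c) a text dump of a single tree's
#' decision rules.
#'
#' @param report A [cross_validate()] result.
#' @param profile An [feature_importance()] result (or `NULL`).
#' @param est The trained estimator (needed for tree export).
#' @param out_prefix Path prefix for the written files.
#' @param tree_index Optional 1-based tree index to export as rules text.
#' @return Character vector of written file paths, invisibly.
#' @export
export_artifacts <- function(report, profile = NULL, est = NULL,
                             out_prefix = "promoterkit", tree_index = NULL) {
  paths <- character(0)
  p <- paste0(out_prefix, "_evaluation.csv")
  readr::write_csv(dplyr::mutate(report$scores, metric = report$metric), p,
                   progress = FALSE)
  paths <- c(paths, p)
  if (!is.null(profile)) {
    m <- profile$matrix
    gc_row <- rep(NA_real_, ncol(m))
    imp <- rbind(m, GC = gc_row)
    imp["GC", 1] <- profile$gc_importance
    df <- data.frame(feature = rownames(imp), imp, check.names = FALSE)
    p <- paste0(out_prefix, "_importance.csv")
    readr::write_csv(df, p, progress = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(tree_index)) {
    if (is.null(est) || est$spec$kind != "RF") {
      abort("Tree export requires a trained RF estimator",
            class = "promoterkit_estimator_error")
    }
    if (tree_index > est$model$num.trees) {
      abort(paste0("tree_index ", tree_index, " exceeds ensemble size ",
                   est$model$num.trees), class = "promoterkit_value_error")
    }
    info <- ranger::treeInfo(est$model, tree = tree_index)
    p <- paste0(out_prefix, "_tree", tree_index, ".txt")
    writeLines(utils::capture.output(print(info)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an exported importance matrix back
#' @param path Path written by [export_artifacts()].
#' @return A matrix with rows A, C, G, T, GC.
#' @export
read_importance_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$feature
  colnames(m) <- colnames(df)[-1]
  m
}
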