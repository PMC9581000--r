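# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a position profile
#'
#' @param x A [position_entropy()] result.
#' @param ... Unused.
#' @return A tibble with one row per (position, nucleotide): `count`,
#'   `frequency`, and the position's `entropy_bits`.
#' @export
tidy.position_profile <- function(x, ...) {
  P <- ncol(x$counts)
  tibble::tibble(
    position = rep(x$positions, each = 4),
    nucleotide = rep(NUCLEOTIDES, P),
    count = as.vector(x$counts),
    frequency = as.vector(x$frequencies),
    entropy_bits = rep(x$entropy_bits, each = 4)
  )
}

#' Tidy an expression profile
#'
#' @param x A [position_expression()] result.
#' @param ... Unused.
#' @return A tibble with one row per (position, nucleotide): `mean`, `sd`
#'   and `support`; unsupported cells carry `NA` means.
#' @export
tidy.expression_profile <- function(x, ...) {
  P <- ncol(x$mean)
  tibble::tibble(
    position = rep(x$positions, each = 4),
    nucleotide = rep(NUCLEOTIDES, P),
    mean = as.vector(x$mean),
    sd = as.vector(x$sd),
    support = as.vector(x$support)
  )
}

#' Tidy a diversity report
#' @param x A [sequence_diversity()] result.
#' @param ... Unused.
#' @return A tibble with per-sequence distances to the reference.
#' @export
tidy.diversity_report <- function(x, ...) {
  tibble::tibble(index = seq_along(x$per_sequence_distance),
                 distance = x$per_sequence_distance)
}

#' Tidy / summarize a cross-validation result
#'
#' `tidy()` returns the per-repeat train and test scores; `glance()` the
#' one-row summary with the mean, sd and coefficient of variation of the
#' test scores.
#'
#' @param x A [cross_validate()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.promoter_cv <- function(x, ...) x$scores

#' @rdname tidy.promoter_cv
#' @export
glance.promoter_cv <- function(x, ...) {
  tibble::tibble(metric = x$metric, mean_test = x$mean_test,
                 sd_test = x$sd_test, cov_test = x$cov_test,
                 mean_train = x$mean_train,
                 n_repeats = nrow(x$scores), n_excluded = x$n_excluded)
}

#' Tidy a trained estimator
#' @param x A [grid_search_train()] result.
#' @param ... Unused.
#' @return The per-candidate tuning-score tibble.
#' @export
tidy.trained_estimator <- function(x, ...) x$tuning_scores

#' @rdname tidy.trained_estimator
#' @export
glance.trained_estimator <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind, task = x$spec$task,
                 n_features = n_features(x$feature_spec),
                 best_params = paste(names(x$best_params),
                                     unlist(x$best_params),
                                     sep = "=", collapse = ","))
}

#' Tidy an importance profile
#' @param x A [feature_importance()] result.
#' @param ... Unused.
#' @return A tibble with one row per feature cell (position, nucleotide,
#'   importance), GC as a final row with `NA` position.
#' @export
tidy.importance_profile <- function(x, ...) {
  P <- length(x$positions)
  out <- tibble::tibble(
    position = rep(x$positions, each = 4),
    nucleotide = rep(NUCLEOTIDES, P),
    importance = as.vector(x$matrix)
  )
  if (!is.na(x$gc_importance)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      position = NA_integer_, nucleotide = "GC",
      importance = x$gc_importance))
  }
  out
}

#' Plot per-position entropy and nucleotide sampling
#'
#' @param object A [position_entropy()] result.
#' @param ... Unused.
#' @return A ggplot: entropy bars per position.
#' @export
autoplot.position_profile <- function(object, ...) {
  df <- tibble::tibble(position = object$positions,
                       entropy_bits = object$entropy_bits)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$entropy_bits)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Position (TSS = 0)", y = "Entropy (bits)") +
    ggplot2::ylim(0, 2)
}

#' Plot a position-expression heat map
#' @param object A [position_expression()] result.
#' @param ... Unused.
#' @return A ggplot tile map of mean expression per (position, nucleotide).
#' @export
autoplot.expression_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position, y = .data$nucleotide,
                               fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "Position (TSS = 0)", y = NULL,
                  fill = paste0("Mean ", object$column))
}

#' Plot cross-validation score distributions
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot of train/test scores across repeats.
#' @export
autoplot.promoter_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scores,
                            cols = c("train_score", "test_score"),
                            names_to = "set", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$score)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = object$metric)
}

#' Plot a feature-importance logo-style profile
#'
#' Stacked per-position nucleotide importances — the data behind a sequence
#' logo of the estimator's learned preferences.
#'
#' @param object A [feature_importance()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_profile <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$position))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$importance,
                                   fill = .data$nucleotide)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Position (TSS = 0)", y = "Importance",
                  fill = "Nucleotide")
}

#' Plot the fitness trajectory of a design run
#' @param object A [design_promoters()] result.
#' @param ... Unused.
#' @return A ggplot of best fitness per generation.
#' @export
autoplot.design_result <- function(object, ...) {
  hist <- attr(object, "fitness_history")
  df <- tibble::tibble(generation = seq_along(hist), best_fitness = hist)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation,
                                   y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Best fitness")
}
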