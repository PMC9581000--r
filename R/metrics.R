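# Scoring metrics: R2, weighted F1, Matthews correlation coefficient.

#' Prediction scores
#'
#' `r_squared()` is the coefficient of determination 1 - SS_res / SS_tot
#' (can be negative on held-out data). `f1_weighted()` averages per-class F1
#' scores weighted by the true class support. `mcc()` is the multiclass
#' Matthews correlation coefficient computed from the confusion matrix.
#'
#' @param truth Observed values (numeric) or class labels.
#' @param estimate Predictions of the same length.
#' @return A single numeric score.
#' @export
r_squared <- function(truth, estimate) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((truth - estimate)^2) / ss_tot
}

#' @rdname r_squared
#' @export
f1_weighted <- function(truth, estimate) {
  classes <- sort(unique(truth))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1s * support) / sum(support)
}

#' @rdname r_squared
#' @export
mcc <- function(truth, estimate) {
  lev <- sort(unique(c(truth, estimate)))
  cm <- table(factor(truth, lev), factor(estimate, lev))
  n <- sum(cm)
  tk <- rowSums(cm)   # true per class
  pk <- colSums(cm)   # predicted per class
  cov_tp <- n * sum(diag(cm)) - sum(tk * pk)
  denom <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  if (denom == 0) return(0)
  cov_tp / denom
}

score_predictions <- function(task, truth, estimate) {
  if (task == "regression") r_squared(truth, estimate)
  else f1_weighted(truth, estimate)
}
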