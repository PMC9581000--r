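# Featurization: entropy-filtered one-hot encoding + GC, target coding,
# replicate-joint train/test splitting.

#' Select sequence positions by training-set entropy
#'
#' Positions whose Shannon entropy on the training library exceeds
#' `cutoff_bits` are retained as features; low-entropy (near-invariant)
#' positions carry too little sampled variation to support prediction.
#' The filter must be derived from the training subset only, so it is
#' re-applied inside every cross-validation repeat.
#'
#' @param train_lib The training promoter library.
#' @param cutoff_bits Entropy cutoff in bits, in `[0, 2]`; default 0.2.
#' @param include_gc Whether the overall sequence GC content is appended as
#'   one extra feature.
#' @return An object of class `feature_spec` with `retained_positions`
#'   (position labels, original order), `nucleotide_order`, `include_gc` and
#'   `entropy_cutoff_bits`. Feature count is `4 * P + include_gc`.
#' @export
select_positions <- function(train_lib, cutoff_bits = 0.2, include_gc = TRUE) {
  if (cutoff_bits < 0 || cutoff_bits > 2) {
    abort("cutoff_bits must lie in [0, 2]", class = "promoterkit_value_error")
  }
  prof <- position_entropy(train_lib)
  keep <- prof$entropy_bits > cutoff_bits
  if (!any(keep)) {
    abort(paste0("No position exceeds ", cutoff_bits,
                 " bits of entropy; lower the cutoff"),
          class = "promoterkit_value_error")
  }
  structure(list(retained_positions = prof$positions[keep],
                 nucleotide_order = NUCLEOTIDES,
                 include_gc = include_gc,
                 entropy_cutoff_bits = cutoff_bits),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("Feature spec:", length(x$retained_positions), "positions (cutoff",
      x$entropy_cutoff_bits, "bits)",
      if (x$include_gc) "+ GC content" else "", "->",
      n_features(x), "features\n")
  invisible(x)
}

#' Number of features implied by a feature spec
#' @param spec A `feature_spec`.
#' @return `4 * |retained positions| + 1` if GC is included, else `4 * P`.
#' @export
n_features <- function(spec) {
  4L * length(spec$retained_positions) + as.integer(spec$include_gc)
}

#' One-hot encode library sequences
#'
#' Encodes each sequence as position-major, nucleotide-minor (A, C, G, T)
#' indicator columns over the spec's retained positions, optionally followed
#' by a final GC-content column computed on the full-length sequence (not
#' only the retained positions).
#'
#' @param lib A promoter library (or any data frame with a `sequence`
#'   column of the right length).
#' @param spec A [select_positions()] feature spec.
#' @return A numeric matrix of dimension S x `n_features(spec)`, with
#'   column names like `pos-35_A` and `GC`.
#' @export
one_hot_encode <- function(lib, spec) {
  labels <- position_labels(lib)
  idx <- match(spec$retained_positions, labels)
  if (anyNA(idx)) {
    abort("Feature spec references positions absent from the library",
          class = "promoterkit_value_error")
  }
  m <- seq_matrix(lib$sequence)
  S <- nrow(m)
  P <- length(idx)
  X <- matrix(0, S, 4L * P)
  for (p in seq_len(P)) {
    col0 <- 4L * (p - 1L)
    nt <- m[, idx[p]]
    for (b in seq_along(NUCLEOTIDES)) {
      X[, col0 + b] <- as.numeric(nt == NUCLEOTIDES[b])
    }
  }
  colnames(X) <- paste0("pos", rep(spec$retained_positions, each = 4), "_",
                        rep(NUCLEOTIDES, P))
  if (spec$include_gc) {
    X <- cbind(X, GC = gc_content(lib$sequence))
  }
  X
}

#' Bin a numeric target into equal-frequency classes
#'
#' Builds `k` quantile (equal-sized) buckets over `values` and returns the
#' 0-based bin label per value plus the learned edges, which can be re-applied
#' to held-out data with [apply_bins()]. Values outside the learned range
#' clamp to the extreme classes.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of classes (>= 2).
#' @return A list with `labels` (integers 0..k-1) and `bin_edges`.
#' @examples
#' bin_targets(1:9, 3)$labels
#' @export
bin_targets <- function(values, k) {
  k <- as.integer(k)
  if (k < 2) abort("k must be >= 2", class = "promoterkit_value_error")
  edges <- unname(quantile(values, probs = seq(0, 1, length.out = k + 1)))
  if (anyDuplicated(edges)) {
    abort(paste0("Cannot form ", k,
                 " distinct quantile bins (tied edges); use a smaller k"),
          class = "promoterkit_value_error")
  }
  labels <- apply_bins(values, edges)
  list(labels = labels, bin_edges = edges)
}

#' @rdname bin_targets
#' @param bin_edges Edges learned by `bin_targets()` on training data.
#' @export
apply_bins <- function(values, bin_edges) {
  k <- length(bin_edges) - 1L
  lab <- findInterval(values, bin_edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  lab[values <= bin_edges[1]] <- 1L
  pmin(pmax(lab, 1L), k) - 1L
}

#' Standardize a numeric target to zero mean and unit variance
#'
#' @param values Numeric vector with positive variance.
#' @return A list with `values` (standardized) and `scaler` (`mean`, `sd`)
#'   for exact inverse transformation.
#' @export
standardize_targets <- function(values) {
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    abort("Cannot standardize a constant target", class = "promoterkit_value_error")
  }
  m <- mean(values)
  list(values = (values - m) / s, scaler = list(mean = m, sd = s))
}

#' Target coding for model training
#'
#' Encodes expression values according to `response_value`: `0` regression on
#' standardized values (predictions are transformed back), `1` regression on
#' the raw values, and `k >= 2` classification into k equal-frequency bins
#' learned on the training values only.
#'
#' @param values Training expression values.
#' @param response_value Integer >= 0.
#' @return An object of class `target_spec` with `task`, `response_value`,
#'   and either `scaler` or `bin_edges`/`class_labels`; plus `encode()`-ready
#'   fields used by [grid_search_train()].
#' @export
target_spec <- function(values, response_value = 1L) {
  response_value <- as.integer(response_value)
  if (response_value < 0) abort("response_value must be >= 0",
                                class = "promoterkit_value_error")
  if (response_value >= 2) {
    b <- bin_targets(values, response_value)
    structure(list(task = "classification", response_value = response_value,
                   bin_edges = b$bin_edges,
                   class_labels = seq_len(response_value) - 1L),
              class = "target_spec")
  } else if (response_value == 0) {
    s <- standardize_targets(values)
    structure(list(task = "regression", response_value = 0L,
                   scaler = s$scaler),
              class = "target_spec")
  } else {
    structure(list(task = "regression", response_value = 1L),
              class = "target_spec")
  }
}

encode_targets <- function(tspec, values) {
  switch(as.character(tspec$response_value),
         "0" = (values - tspec$scaler$mean) / tspec$scaler$sd,
         "1" = values,
         apply_bins(values, tspec$bin_edges))
}

decode_targets <- function(tspec, values) {
  if (tspec$response_value == 0) values * tspec$scaler$sd + tspec$scaler$mean
  else values
}

#' Replicate-joint train/test split
#'
#' Splits a library into training and test sets at the group level, where a
#' group is all records sharing the exact same sequence string (replicates).
#' Every group lands wholly on one side, so no test sequence is ever seen in
#' training. The number of test groups is `ceiling(G * (1 - train_fraction))`.
#'
#' @param lib A promoter library with at least 2 distinct sequences.
#' @param train_fraction Fraction of groups assigned to training (default 0.9).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return A list with promoter libraries `train` and `test`.
#' @export
split_train_test <- function(lib, train_fraction = 0.9, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie in (0, 1)", class = "promoterkit_value_error")
  }
  groups <- unique(lib$sequence)
  G <- length(groups)
  if (G < 2) abort("Need at least 2 distinct sequences to split",
                   class = "promoterkit_value_error")
  n_test <- ceiling(G * (1 - train_fraction))
  n_test <- min(n_test, G - 1L)
  set.seed(seed)
  test_groups <- sample(groups, n_test)
  is_test <- lib$sequence %in% test_groups
  keep_attrs <- function(tbl) new_promoter_library(
    tbl, expr_cols = expr_cols(lib), position_labels = position_labels(lib))
  list(train = keep_attrs(lib[!is_test, , drop = FALSE]),
       test = keep_attrs(lib[is_test, , drop = FALSE]))
}
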