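# Seeded synthetic promoter libraries with planted position-nucleotide
# effects, for end-to-end validation of the whole workflow.

#' Specification of a synthetic promoter library
#'
#' The generator emulates a mutagenized promoter library: each sequence is
#' derived from a base sequence by independent per-position mutation (with
#' probability `mutation_rate` the base nucleotide is replaced by one of the
#' other three, uniformly), and expression follows a planted additive
#' position-nucleotide weight model plus Gaussian noise:
#' `expression = sum_i weights[nt_i, i] + N(0, noise_sd)`.
#'
#' @param R Sequence length (default 40, a typical promoter window).
#' @param S Number of distinct sequences (default 200).
#' @param base_sequence Base DNA string of length R; random if `NULL`.
#' @param n_causal Number of causal positions when `weights` is `NULL`.
#' @param effect_size Weight spread at causal positions: nucleotides A,C,G,T
#'   get weights `(0, 1, 2, 3) * effect_size` (in a random per-position
#'   nucleotide order).
#' @param weights Optional explicit 4 x R weight matrix (rows A,C,G,T).
#' @param mutation_rate Per-position probability of deviating from base.
#' @param noise_sd Absolute Gaussian noise standard deviation; if `NULL`,
#'   set to `noise_fraction` times the standard deviation of the noiseless
#'   expression signal.
#' @param noise_fraction Relative noise level (default 0.1).
#' @param replicate_count Independent noisy measurements per sequence.
#' @param mutable_positions Integer indices (1..R) of positions allowed to
#'   mutate; defaults to all. Mirrors libraries where only a subset of
#'   positions was experimentally varied.
#' @param interaction_pairs Optional list of `list(i, j, strength)` pairwise
#'   epistasis terms added when both positions deviate from base (creates
#'   harder, non-additive fixtures).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(R = 40L, S = 200L, base_sequence = NULL,
                           n_causal = 3L, effect_size = 1, weights = NULL,
                           mutation_rate = 0.2, noise_sd = NULL,
                           noise_fraction = 0.1, replicate_count = 1L,
                           mutable_positions = NULL,
                           interaction_pairs = NULL, seed = 1L) {
  R <- as.integer(R)
  if (!is.null(base_sequence)) {
    if (grepl("[^ACGT]", base_sequence)) {
      abort("base_sequence must use A/C/G/T only",
            class = "promoterkit_alphabet_error")
    }
    R <- nchar(base_sequence)
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    abort("mutation_rate must lie in [0, 1]", class = "promoterkit_value_error")
  }
  if (!is.null(weights) && !all(dim(weights) == c(4L, R))) {
    abort("weights must be a 4 x R matrix (rows A, C, G, T)",
          class = "promoterkit_value_error")
  }
  structure(list(R = R, S = as.integer(S), base_sequence = base_sequence,
                 n_causal = as.integer(n_causal), effect_size = effect_size,
                 weights = weights, mutation_rate = mutation_rate,
                 noise_sd = noise_sd, noise_fraction = noise_fraction,
                 replicate_count = as.integer(replicate_count),
                 mutable_positions = mutable_positions,
                 interaction_pairs = interaction_pairs,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic promoter library with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `library` (a [promoter_library()] of
#'   `S * replicate_count` records) and `truth` (the planted `weights`
#'   matrix, `causal_positions` as 1-based indices and as position labels,
#'   `base_sequence` and the realized `noise_sd`).
#' @export
generate_library <- function(spec) {
  set.seed(spec$seed)
  R <- spec$R
  base <- spec$base_sequence %||%
    paste(sample(NUCLEOTIDES, R, replace = TRUE), collapse = "")
  base_codes <- match(strsplit(base, "", fixed = TRUE)[[1]], NUCLEOTIDES)
  mutable <- spec$mutable_positions %||% seq_len(R)
  weights <- spec$weights
  causal <- integer(0)
  if (is.null(weights)) {
    weights <- matrix(0, 4, R, dimnames = list(NUCLEOTIDES, NULL))
    causal <- sort(sample(mutable, min(spec$n_causal, length(mutable))))
    for (j in causal) {
      weights[sample.int(4L), j] <- c(0, 1, 2, 3) * spec$effect_size
    }
  } else {
    causal <- which(apply(weights, 2, function(w) diff(range(w)) > 0))
  }
  # sequences: keep base with prob 1 - mutation_rate, else one of the other 3
  codes <- matrix(rep(base_codes, each = spec$S), spec$S, R)
  mut <- matrix(FALSE, spec$S, R)
  mut[, mutable] <- stats::runif(spec$S * length(mutable)) < spec$mutation_rate
  if (any(mut)) {
    idx <- which(mut)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    codes[idx] <- ((codes[idx] - 1L + shift) %% 4L) + 1L
  }
  signal <- vapply(seq_len(spec$S), function(i) {
    sum(weights[cbind(codes[i, ], seq_len(R))])
  }, numeric(1))
  if (!is.null(spec$interaction_pairs)) {
    for (ip in spec$interaction_pairs) {
      both <- codes[, ip[[1]]] != base_codes[ip[[1]]] &
              codes[, ip[[2]]] != base_codes[ip[[2]]]
      signal <- signal + ip[[3]] * both
    }
  }
  noise_sd <- spec$noise_sd %||% (spec$noise_fraction * sd(signal))
  if (!is.finite(noise_sd)) noise_sd <- 0
  seqs <- apply(codes, 1, function(row) paste(NUCLEOTIDES[row], collapse = ""))
  n_rep <- spec$replicate_count
  tbl <- tibble::tibble(
    id = paste0("syn", rep(seq_len(spec$S), each = n_rep),
                if (n_rep > 1) paste0("_rep", rep(seq_len(n_rep), spec$S)) else ""),
    sequence = rep(seqs, each = n_rep),
    expression = rep(signal, each = n_rep) +
      rnorm(spec$S * n_rep, 0, noise_sd)
  )
  lib <- new_promoter_library(tbl, expr_cols = "expression",
                              position_labels = seq.int(-R, -1L))
  labels <- position_labels(lib)
  list(library = lib,
       truth = list(weights = weights,
                    causal_positions = causal,
                    causal_labels = labels[causal],
                    base_sequence = base,
                    noise_sd = noise_sd))
}

#' Write a synthetic library and its ground-truth sidecar
#'
#' @param gen A [generate_library()] result.
#' @param out_prefix Path prefix; writes `<prefix>_library.csv` and
#'   `<prefix>_truth.json`.
#' @return The written paths, invisibly.
#' @export
write_synthetic <- function(gen, out_prefix) {
  lib_path <- paste0(out_prefix, "_library.csv")
  truth_path <- paste0(out_prefix, "_truth.json")
  write_promoter_library(gen$library, lib_path)
  truth <- gen$truth
  truth$weights <- as.data.frame(truth$weights)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(lib_path, truth_path))
}
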