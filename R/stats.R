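# Per-position statistics: entropy, consensus, diversity, position-expression.

seq_matrix <- function(sequences) {
  # S x R character matrix of nucleotides
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}

#' Per-position nucleotide counts, frequencies and Shannon entropy
#'
#' For every sequence position i the nucleotide distribution across the
#' library is summarised as counts, frequencies p and the Shannon entropy
#' H_i = -sum_b p_b log2 p_b (bits), with 0 * log2(0) taken as 0. H_i ranges
#' from 0 (invariant position) to 2 (uniform over A/C/G/T).
#'
#' @param lib A promoter library.
#' @return An object of class `position_profile` with components `counts`
#'   (4 x R integer matrix, rows A/C/G/T), `frequencies` (4 x R),
#'   `entropy_bits` (length-R vector) and `positions` (labels). Has
#'   [tidy.position_profile()] and [autoplot.position_profile()] methods.
#' @examples
#' lib <- promoter_library(data.frame(id = c("a", "b"),
#'   sequence = c("ACGT", "AAGT"), expression = c(1, 2)))
#' position_entropy(lib)$entropy_bits
#' @export
position_entropy <- function(lib) {
  validate_sequences(lib$sequence, lib$id)
  m <- seq_matrix(lib$sequence)
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(factor(m[, j], levels = NUCLEOTIDES), nbins = 4L)
  }, integer(4))
  rownames(counts) <- NUCLEOTIDES
  freqs <- sweep(counts, 2, colSums(counts), "/")
  H <- apply(freqs, 2, function(p) {
    nz <- p > 0
    -sum(p[nz] * log2(p[nz]))
  })
  structure(list(counts = counts, frequencies = freqs,
                 entropy_bits = unname(H),
                 positions = position_labels(lib)),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat("Position profile over", ncol(x$counts), "positions,",
      sum(x$counts[, 1]), "sequences\n")
  cat("Entropy (bits): min", round(min(x$entropy_bits), 3),
      "median", round(stats::median(x$entropy_bits), 3),
      "max", round(max(x$entropy_bits), 3), "\n")
  invisible(x)
}

#' Consensus sequence of a library
#'
#' The most common nucleotide at each position; ties are broken by the fixed
#' alphabet order A < C < G < T so the result is deterministic.
#'
#' @param lib A promoter library.
#' @return A single DNA string of length R.
#' @export
consensus_sequence <- function(lib) {
  prof <- position_entropy(lib)
  paste(NUCLEOTIDES[apply(prof$counts, 2, which.max)], collapse = "")
}

hamming_norm <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av != bv)
}

#' Sequence diversity of a library
#'
#' Diversity is the normalized count of nucleotide differences, between 0
#' (all sequences identical) and 1 (every position differs). In `reference`
#' mode each sequence is compared against a reference (the library consensus
#' unless one is supplied); in `pairwise` mode the mean over all unordered
#' sequence pairs is reported. `auto` uses pairwise distances up to
#' `pairwise_limit` samples and falls back to the cheaper reference mode for
#' larger libraries.
#'
#' @param lib A promoter library.
#' @param reference Optional reference sequence of length R.
#' @param mode One of `"auto"`, `"reference"`, `"pairwise"`.
#' @param pairwise_limit Sample-count threshold for the auto switch.
#' @return An object of class `diversity_report` with `mode`,
#'   `per_sequence_distance` (reference mode), `mean_distance` and
#'   `reference_used`.
#' @export
sequence_diversity <- function(lib, reference = NULL,
                               mode = c("auto", "reference", "pairwise"),
                               pairwise_limit = 1000L) {
  mode <- match.arg(mode)
  validate_sequences(lib$sequence, lib$id)
  S <- nrow(lib)
  R <- seq_length(lib)
  if (!is.null(reference) && nchar(reference) != R) {
    abort("Reference sequence length must equal the library sequence length",
          class = "promoterkit_length_error")
  }
  if (mode == "auto") {
    mode <- if (S > pairwise_limit) "reference" else "pairwise"
  }
  ref <- reference %||% consensus_sequence(lib)
  per_seq <- vapply(lib$sequence, hamming_norm, numeric(1), b = ref,
                    USE.NAMES = FALSE)
  if (mode == "reference") {
    mean_d <- mean(per_seq)
  } else {
    if (S < 2) {
      mean_d <- 0
    } else {
      m <- seq_matrix(lib$sequence)
      # mean pairwise mismatch per position, summed over positions
      total <- 0
      for (j in seq_len(R)) {
        cnt <- tabulate(factor(m[, j], levels = NUCLEOTIDES), nbins = 4L)
        same <- sum(choose(cnt, 2))
        total <- total + (choose(S, 2) - same)
      }
      mean_d <- total / (choose(S, 2) * R)
    }
  }
  structure(list(mode = mode, per_sequence_distance = per_seq,
                 mean_distance = mean_d, reference_used = ref),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Sequence diversity (", x$mode, " mode): mean distance ",
      signif(x$mean_distance, 4), "\n", sep = "")
  invisible(x)
}

#' GC content of DNA sequences
#'
#' @param sequence Character vector of non-empty A/C/G/T strings.
#' @return Numeric vector in `[0, 1]`: the fraction of G or C per sequence.
#' @examples
#' gc_content(c("ACGT", "GGCC"))
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence)) || length(sequence) == 0) {
    abort("gc_content requires non-empty sequences",
          class = "promoterkit_value_error")
  }
  if (any(grepl("[^ACGT]", sequence))) {
    abort("gc_content accepts A/C/G/T only", class = "promoterkit_alphabet_error")
  }
  gc <- nchar(gsub("[AT]", "", sequence))
  gc / nchar(sequence)
}

#' Mean expression per nucleotide-position pair
#'
#' Computes, for each position i and nucleotide b, the mean (and sample
#' standard deviation, ddof = 1) of the expression of all sequences carrying
#' b at i, together with the number of supporting samples. Cells with no
#' support are `NA` (undefined, never 0); standard deviations require at
#' least two supporting samples.
#'
#' @param lib A promoter library.
#' @param column Expression column to profile; defaults to the first.
#' @return An object of class `expression_profile` with 4 x R matrices
#'   `mean`, `sd` and `support`, plus `positions`.
#' @export
position_expression <- function(lib, column = NULL) {
  column <- primary_expr(lib, column)
  validate_sequences(lib$sequence, lib$id)
  m <- seq_matrix(lib$sequence)
  x <- lib[[column]]
  R <- ncol(m)
  mean_m <- sd_m <- matrix(NA_real_, 4, R, dimnames = list(NUCLEOTIDES, NULL))
  supp <- matrix(0L, 4, R, dimnames = list(NUCLEOTIDES, NULL))
  for (j in seq_len(R)) {
    for (b in seq_along(NUCLEOTIDES)) {
      sel <- m[, j] == NUCLEOTIDES[b]
      n <- sum(sel)
      supp[b, j] <- n
      if (n > 0) mean_m[b, j] <- mean(x[sel])
      if (n > 1) sd_m[b, j] <- sd(x[sel])
    }
  }
  structure(list(mean = mean_m, sd = sd_m, support = supp,
                 positions = position_labels(lib), column = column),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Position-expression profile of '", x$column, "' over ",
      ncol(x$mean), " positions\n", sep = "")
  invisible(x)
}

#' Summary tables for a promoter library
#'
#' Gathers the data behind the standard exploratory plots: an expression
#' histogram, a cross-library scatter table when at least two expression
#' columns exist, cumulative per-position nucleotide counts, and the
#' per-position entropies.
#'
#' @param lib A promoter library.
#' @param bins Number of histogram bins.
#' @return A list of tibbles: `histogram` (bin mid, count), `cross_library`
#'   (or `NULL`), `nucleotide_counts` (long: position, nucleotide, count),
#'   `entropy` (position, entropy_bits).
#' @export
library_summary <- function(lib, bins = 30L) {
  cols <- expr_cols(lib)
  x <- lib[[cols[1]]]
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  histogram <- tibble::tibble(mid = h$mids, count = h$counts)
  cross <- NULL
  if (length(cols) >= 2) {
    cross <- tibble::as_tibble(as.data.frame(lib)[, c("id", cols)])
  }
  prof <- position_entropy(lib)
  counts_long <- tidyr::pivot_longer(
    tibble::as_tibble(t(prof$counts)) |>
      dplyr::mutate(position = prof$positions, .before = 1),
    cols = dplyr::all_of(NUCLEOTIDES),
    names_to = "nucleotide", values_to = "count")
  entropy <- tibble::tibble(position = prof$positions,
                            entropy_bits = prof$entropy_bits)
  list(histogram = histogram, cross_library = cross,
       nucleotide_counts = counts_long, entropy = entropy)
}
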