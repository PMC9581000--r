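# Independent entropy oracle: direct evaluation of H = -sum p log2 p on a
# count vector, written without reference to the package internals.
entropy_oracle <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

test_that("position entropy matches hand values and respects conservation", {
  lib <- make_library(c("AACA", "CACA", "GGCA", "TGCA"))
  prof <- position_entropy(lib)
  # pos1 uniform A/C/G/T -> 2 bits; pos2 A:2,G:2 -> 1 bit; pos3 all C -> 0
  expect_equal(prof$entropy_bits, c(2, 1, 0, 0))
  expect_equal(unname(colSums(prof$counts)), rep(4L, 4))
  expect_equal(unname(colSums(prof$frequencies)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(prof$entropy_bits >= 0 & prof$entropy_bits <= 2))
})

test_that("position entropy agrees with the direct oracle on random counts", {
  set.seed(202)
  for (i in 1:1000) {
    counts <- as.vector(stats::rmultinom(1, size = sample(4:50, 1),
                                         prob = runif(4)))
    # realize a library whose single position has exactly these counts
    nts <- rep(c("A", "C", "G", "T"), counts)
    lib <- make_library(nts, expression = seq_along(nts))
    H <- position_entropy(lib)$entropy_bits
    expect_equal(H, entropy_oracle(counts), tolerance = 1e-12)
  }
})

test_that("consensus takes the modal nucleotide with A<C<G<T tie-break", {
  expect_equal(consensus_sequence(make_library(c("AAC", "AAC", "ATC"))), "AAC")
  expect_equal(consensus_sequence(make_library(c("AC", "CA"))), "AA")
  expect_equal(consensus_sequence(make_library("GATTACA", expression = 1)),
               "GATTACA")
  # a library containing its own consensus keeps it when duplicated
  lib <- make_library(c("ACG", "ACG", "ATG", "GCG"))
  cons <- consensus_sequence(lib)
  lib2 <- make_library(c(lib$sequence, cons, cons),
                       expression = seq_len(nrow(lib) + 2))
  expect_equal(consensus_sequence(lib2), cons)
})

test_that("sequence diversity spans 0 (identical) to 1 (all differ)", {
  same <- make_library(c("ACGT", "ACGT"), ids = c("a", "b"))
  expect_equal(sequence_diversity(same, mode = "pairwise")$mean_distance, 0)
  expect_equal(sequence_diversity(same, mode = "reference")$mean_distance, 0)
  opp <- make_library(c("ACGT", "TGCA"))
  expect_equal(sequence_diversity(opp, mode = "pairwise")$mean_distance, 1)
  ref <- sequence_diversity(make_library(c("ACGT", "ACGA")),
                            reference = "ACGT", mode = "reference")
  expect_equal(ref$per_sequence_distance, c(0, 0.25))
  expect_equal(ref$mean_distance, 0.125)
  expect_error(sequence_diversity(opp, reference = "ACG"),
               class = "promoterkit_length_error")
})

test_that("pairwise diversity equals mean pairwise Hamming distance", {
  # brute-force pairwise oracle on random small libraries
  set.seed(7)
  for (i in 1:20) {
    lib <- random_library(sample(3:8, 1), sample(3:6, 1), seed = i)
    d <- sequence_diversity(lib, mode = "pairwise")$mean_distance
    seqs <- strsplit(lib$sequence, "")
    pairs <- utils::combn(length(seqs), 2)
    oracle <- mean(apply(pairs, 2, function(p)
      mean(seqs[[p[1]]] != seqs[[p[2]]])))
    expect_equal(d, oracle, tolerance = 1e-12)
  }
  # S = 2 pairwise equals the plain normalized Hamming distance
  two <- make_library(c("AACC", "AGCC"))
  expect_equal(sequence_diversity(two, mode = "pairwise")$mean_distance, 0.25)
})

test_that("auto mode switches to reference above the pairwise limit", {
  lib <- random_library(12, 5, seed = 3)
  expect_equal(sequence_diversity(lib, pairwise_limit = 1000)$mode, "pairwise")
  expect_equal(sequence_diversity(lib, pairwise_limit = 10)$mode, "reference")
})

test_that("position expression matches a group-by-mean oracle", {
  lib <- make_library(c("AC", "AA"), expression = c(2, 4))
  ep <- position_expression(lib)
  expect_equal(unname(ep$mean["A", 1]), 3)
  expect_equal(unname(ep$mean["C", 2]), 2)
  expect_equal(unname(ep$mean["A", 2]), 4)
  expect_true(is.na(ep$mean["G", 1]))
  expect_true(all(is.na(ep$sd[ep$support < 2])))

  single <- make_library("GAT", expression = 5)
  eps <- position_expression(single)
  expect_equal(unname(eps$mean[cbind(match(c("G", "A", "T"),
                                           c("A", "C", "G", "T")), 1:3)]),
               c(5, 5, 5))
  expect_equal(sum(!is.na(eps$mean)), 3)

  dup <- make_library(c("TT", "TT"), expression = c(1, 3))
  epd <- position_expression(dup)
  expect_equal(unname(epd$mean["T", ]), c(2, 2))
  expect_equal(unname(epd$sd["T", ]), c(sqrt(2), sqrt(2)))

  # random-library oracle via aggregate()
  for (i in 1:10) {
    lib <- random_library(sample(5:20, 1), sample(3:10, 1), seed = 100 + i)
    ep <- position_expression(lib)
    chars <- do.call(rbind, strsplit(lib$sequence, ""))
    for (j in seq_len(ncol(chars))) {
      agg <- aggregate(lib$expression, list(nt = chars[, j]), mean)
      for (r in seq_len(nrow(agg))) {
        expect_equal(unname(ep$mean[agg$nt[r], j]), agg$x[r],
                     tolerance = 1e-12)
      }
    }
    expect_equal(ep$support, position_entropy(lib)$counts,
                 ignore_attr = TRUE)
  }
})

test_that("gc_content computes the G+C fraction and rejects bad input", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content(c("AT", "GC")), c(0, 1))
  expect_error(gc_content(""), class = "promoterkit_value_error")
  expect_error(gc_content("ACGU"), class = "promoterkit_alphabet_error")
})

test_that("library summary emits histogram, counts, entropy and scatter data", {
  lib <- make_library(c("ACGT", "AAGT", "ACGA"), expression = c(1, 2, 3))
  smry <- library_summary(lib)
  expect_equal(sum(smry$histogram$count), 3)
  expect_null(smry$cross_library)
  expect_equal(nrow(smry$entropy), 4)
  expect_equal(sum(smry$nucleotide_counts$count), 3 * 4)

  two <- promoter_library(
    data.frame(id = c("a", "b"), sequence = c("AC", "AG"),
               e1 = c(1, 2), e2 = c(3, 4)),
    expression = c("e1", "e2"))
  smry2 <- library_summary(two)
  expect_equal(dim(smry2$cross_library), c(2L, 3L))
})

test_that("tidiers return one row per position-nucleotide cell", {
  lib <- make_library(c("ACGT", "AAGT", "ACGA"))
  td <- tidy(position_entropy(lib))
  expect_equal(nrow(td), 16)
  expect_equal(sum(td$count), 12)
  te <- tidy(position_expression(lib))
  expect_named(te, c("position", "nucleotide", "mean", "sd", "support"))
})
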