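# promoterkit

Synthetic promoter libraries — collections of fixed-length DNA sequences
upstream of a reporter gene, each with a measured expression strength — are a
workhorse of bacterial strain engineering. `promoterkit` is an R toolkit for
the full analysis cycle of such libraries:

1. **Statistical profiling** — per-position nucleotide counts and Shannon
   entropy `H_i = -Σ_b p_b log2(p_b)` (bits), consensus sequence, sequence
   diversity (normalized Hamming distance to a reference or over all pairs),
   and position–nucleotide expression profiles (the mean expression of all
   sequences carrying nucleotide *b* at position *i*).
2. **Expression modelling** — one-hot sequence encoding plus GC content,
   entropy-based position filtering, quantile-binned (classification) or
   raw/standardized (regression) targets, and random-forest,
   gradient-boosted-tree or RBF-SVM estimators tuned by grid search over
   repeated replicate-joint 9:1 splits.
3. **Confidence evaluation** — repeated cross-validation that jointly moves
   all copies of an identical sequence (replicates) to one side of the
   split, scored by R² (regression) or weighted F1 (classification), with
   the coefficient of variation of the test scores as the confidence
   measure, plus impurity-based feature importances mapped back to
   (position, nucleotide) cells for logo-style visualization.
4. **Promoter design** — a genetic algorithm (tournament selection,
   two-point crossover, point mutation, elitism, and an elite
   local-search step) that searches sequence space against the trained
   estimator for new promoters with a target activity, excluding sequences
   already in the library.
5. **Synthetic data** — a seeded generator of libraries with planted
   additive position–nucleotide effects, so every step above can be
   validated against known ground truth.

Functions take data frames and return tibbles; result objects have
broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods.

## Worked example

```r
library(promoterkit)

# a seeded synthetic library: 200 sequences of 40 nt, 3 causal positions,
# 10% measurement noise
gen <- generate_library(synthetic_spec(R = 40, S = 200, n_causal = 3,
                                       mutation_rate = 0.2,
                                       noise_fraction = 0.1, seed = 11))
lib <- gen$library

position_entropy(lib)
#> Position profile over 40 positions, 200 sequences
#> Entropy (bits): min 0.76 median 1.003 max 1.191

sequence_diversity(lib)
#> Sequence diversity (pairwise mode): mean distance 0.3388

cv <- cross_validate(lib, estimator_spec("RF", "regression"),
                     response_value = 1, params = list(num_trees = 300),
                     repeats = 25, seed = 11)
cv
#> Cross-validation (25 repeats, R2)
#>   mean test score 0.9352 (sd 0.04009, CoV 0.04287)
```

The mean test R² of 0.94 says the forest predicts expression of unseen
sequences almost as well as the 10% noise floor allows; the CoV of 0.043
says that estimate is stable across splits. Feature importance recovers the
three planted causal positions:

```r
est <- grid_search_train(lib,
  estimator_spec("RF", "regression", grid = list(num_trees = 500),
                 tuning_repeats = 1, seed = 11),
  select_positions(lib, 0.2), target_spec(lib$expression, 1))
head(position_importance(feature_importance(est)), 3)
#>   position importance
#> 1      -30      0.442
#> 2      -15      0.253
#> 3       -7      0.159
gen$truth$causal_labels
#> [1] -30 -15  -7
```

Designing a new promoter with a target activity of 8 (the library runs
roughly 2–10):

```r
design_promoters(est, design_target(target_value = 8),
                 ga_params(population_size = 100, generations = 40,
                           seed = 11), lib)
#>   id       sequence     predicted distance_to_reference  fitness
#> 1 design_1 ACTAGAATC...      8.00                 0.375  3.89e-5
```

The designed sequences are new (never in the library), predicted within
4e-5 of the target, and reported with their distance to the library
consensus.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "promoterkit", package = "promoterkit")` with
subcommands `stats`, `train`, `evaluate`, `design` and `simulate`.

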