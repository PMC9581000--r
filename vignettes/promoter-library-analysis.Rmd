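---
title: "Methods: promoter library statistics, expression models and sequence design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter library statistics, expression models and sequence design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterkit)
```

# The data model

A promoter library is a table of S records: an identifier, a DNA sequence
over {A, C, G, T} of common length R, and one or more numeric expression
measurements; optionally a standard deviation and a replicate count per
record. Positions are labelled by genomic coordinate, by default
`-R ... -1` upstream of a transcription start at 0, so a feature named
`pos-35_T` reads as "T at position −35". All downstream machinery — entropy
filtering, one-hot features, importance maps — is expressed in these
coordinates.

Two preprocessing steps are optional and off by default:

* **Replicate regeneration.** When only a mean and standard deviation per
  sequence are available, `regenerate_replicates()` draws `n_replicates`
  values per record from `N(mean, sd)`. This assumes measurement noise is
  approximately normal; draws are deliberately not truncated at zero
  (a warning is raised if negative values occur), because clamping would
  bias the regenerated mean upward for low expressers.
* **Outlier removal.** No principled outlier criterion is implied by the
  data model, so `remove_outliers()` uses the simplest defensible rule —
  absolute z-score of expression above a threshold (default 3.0) — and
  reports exactly which ids it dropped. We order removal before replicate
  regeneration when both are used, so an aberrant mean is removed before it
  is amplified into replicates.

# Statistical profile

Per position i the nucleotide distribution is summarised by the Shannon
entropy in bits,

$$H_i = -\sum_{b \in \{A,C,G,T\}} p_b \log_2 p_b,$$

with the convention `0 * log2(0) = 0`, so `H_i` ranges from 0 (invariant
position) to 2 (uniform). Sequence diversity is the normalized Hamming
distance — 0 for identical sequences, 1 when every position differs —
either to a reference (the library consensus unless supplied) or averaged
over all unordered pairs. Pairwise diversity is computed by per-position
pair counting rather than explicit O(S²R) comparison, and above
`pairwise_limit` (default 1000) samples the cheaper reference mode is used
automatically. The consensus takes the modal nucleotide per position with
ties broken by the fixed order A < C < G < T — the tie-break is arbitrary
but deterministic, which matters because the consensus is reused as the
default design reference.

The position-expression profile records, for each (position, nucleotide)
cell, the mean and sample standard deviation (ddof = 1) of expression over
the supporting sequences. Cells with no support are `NA`, never 0 — a
nucleotide that was not sampled at a position has unknown, not zero,
expression; cells with one supporter have a mean but an `NA` sd. The
support matrix always equals the count matrix of the position profile, a
conservation invariant tested in the suite.

# Features and targets

Model inputs are the one-hot encoding of each retained position
(position-major, nucleotide-minor in A, C, G, T order) plus a final
GC-content column computed on the **full** sequence — GC is a global
sequence property, so it is not restricted to the retained positions. The
feature count is therefore `4P + 1` for P retained positions.

Positions are retained when their training-set entropy **exceeds**
`entropy_cutoff` (default 0.2 bits). Near-invariant positions carry almost
no sampled variation, so their indicators are uninformative at best and
noise at worst. The filter is always computed on the training subset — and
recomputed inside every cross-validation repeat — because selecting
features on data that includes the test set leaks information.

The target coding follows a single integer `response_value`:

* `0` — regression on standardized values (zero mean, unit variance on the
  training set); predictions are transformed back to the original scale.
* `1` — regression on the raw values (the default).
* `k >= 2` — classification into k equal-frequency (quantile) bins. Bin
  edges are learned on the training values only and re-applied to held-out
  data, with out-of-range values clamped to the extreme classes; learning
  edges on the pooled data would leak the test distribution into training.
  With fewer than k distinct values the quantile edges collide and the
  coding errors with a suggestion to lower k.

Train/test splitting is **replicate-joint**: the grouping key is the exact
sequence string, and every group lands wholly in train or test, so a
sequence measured five times can never straddle the split. The number of
test groups is `ceiling(G * (1 - train_fraction))`; with the default 9:1
ratio a 63-sequence library yields 56 training and 7 test groups. The
split is not stratified by class: stratification would interact with the
grouping in small libraries (a class's groups can be fewer than the
desired per-class test count), and the repeated-split evaluation averages
over the resulting variation instead.

# Estimators and tuning

Three families are supported behind one interface: random forest (`ranger`),
gradient-boosted trees (`xgboost`) and an RBF-kernel SVM (`e1071`). For the
forest we use the classic regression default `mtry = p/3` (and
`sqrt(p)` for classification): with one-hot promoter features only a few
of the hundreds of columns are informative, and the smaller `sqrt(p)`
draw dilutes them noticeably. SVM features are used as-is — indicators and
GC already live in [0, 1] — and the default `gamma` is the scale
heuristic `1 / (p * var(X))`.

Hyperparameters are tuned by grid search: each candidate is scored by the
mean validation score over `tuning_repeats` (default 100) replicate-joint
9:1 splits of the training data, the argmax is refit on the full training
set, and ties break by grid order so the result is reproducible under a
fixed seed. Repeated random splits are used rather than k-fold
partitioning: they keep the 9:1 geometry at any sample size (100-fold
partitioning is undefined below 100 groups) and give a direct spread
estimate per candidate. Default grids (all overridable):
RF trees {100, 300, 1000} × depth {unlimited, 5, 10} × min leaf {1, 3};
GBT trees {100, 300} × learning rate {0.01, 0.1} × depth {2, 3, 5};
SVM cost {0.1, 1, 10, 100} × gamma {scale, 0.01, 0.1}.

# Evaluation and confidence

`cross_validate()` runs `repeats` (default 25) independent replicate-joint
9:1 splits, re-deriving the entropy filter per training fold, and records
train and test scores — R² for regression, support-weighted F1 for
classification, optionally the Matthews correlation coefficient. The
confidence measure is the coefficient of variation (sd/mean) of the test
scores. Negative test R² values are kept as-is; clipping them would
understate the spread, and a warning flags the unstable-CoV case of a
near-zero mean. Repeats whose training fold loses a class are excluded
with a warning; more than 50% exclusions is an error.

Impurity-based importances of the tree ensembles are normalized to sum to
1 and mapped back to (position, nucleotide) cells plus GC, exportable as a
logo-ready CSV (rows A, C, G, T, GC; columns = position labels). SVMs have
no comparable importance and error explicitly.

# Promoter design

`design_promoters()` searches sequence space against the trained estimator
with a genetic algorithm: uniform-random initial population, tournament
selection (size 3), two-point crossover (probability 0.7), per-position
point mutation to a *different* nucleotide (probability 1/R by default),
and elitism of one. After each generation a steepest-descent local search
over all 3R single-nucleotide substitutions of the current best runs until
no neighbour improves — a standard memetic refinement that costs a few
batched predictions and prevents the search from stalling one substitution
short of an optimum; on six-mer spaces the search then reproducibly
matches exhaustive enumeration. Every sequence ever evaluated is archived
with its fitness, and the reported designs are the best distinct feasible
archive entries.

Fitness is `|predicted − target|` for regression (with an optional
reference-distance term, weight 0 by default, for users who want designs
near the library's sampled neighbourhood where the estimator is most
trustworthy), and for classification the normalized Hamming distance to
the nearest reference plus a constant penalty of 10.0 — large against a
[0, 1] distance — when the predicted class misses the target. An additive
penalty rather than hard rejection lets early, entirely infeasible
populations still evolve toward the feasible region. Sequences already in
the library are excluded twice over: they receive a worst-case fitness
during the search *and* are filtered from the returned results, so the
exclusion holds even if a library member were the global optimum.
`brute_force_design()` evaluates every sequence up to R = 10 under the
identical fitness and is the package's own correctness oracle.

# The synthetic generator

`generate_library()` emulates a mutagenized promoter library: each
sequence keeps the base nucleotide at each position with probability
`1 - mutation_rate`, else switches uniformly to one of the other three, so
the expected distance to the base sequence equals the mutation rate.
Expression is a planted additive model — each causal position assigns
weights `(0, 1, 2, 3) × effect_size` to the four nucleotides in a random
order — plus Gaussian noise, specified either absolutely (`noise_sd`) or
relative to the realized signal sd (`noise_fraction`, default 0.1).
`mutable_positions` restricts mutation to a subset of positions, mirroring
real libraries where only part of the window is varied; an optional
pairwise interaction term creates non-additive fixtures. Defaults
(R = 40, S = 200, 3 causal positions, mutation rate 0.2, 10% noise)
describe a mid-sized, moderately diverse library: 40 nt is a typical
analysis window, a few hundred members is a realistic screening effort,
and rate 0.2 yields pairwise diversities near 0.35, within the range
spanned by published libraries.

What passing tests on this generator do **not** show: real promoter
libraries have correlated mutations (oligo synthesis designs), epistasis
between boxes, heteroscedastic and occasionally non-normal measurement
noise, and causal structure concentrated in known motifs rather than
random positions. The generator validates the machinery — leakage-free
splitting, feature mapping, recovery of planted signal at a known noise
floor — not biological generality.

# Numerical choices and degenerate inputs

* Entropy uses log base 2; `p = 0` cells contribute exactly 0; the profile
  invariants (column counts sum to S, frequencies to 1 within 1e-12) are
  asserted in tests against a direct evaluation of the formula.
* Quantile bin edges use R's default (type 7) interpolated quantiles, the
  same linear-interpolation scheme as pandas' `qcut`, so class sizes for
  distinct values differ by at most 1.
* Constant targets: standardization errors; binning errors (tied edges);
  outlier removal warns and returns the library unchanged.
* Empty libraries error everywhere; a single-sequence library has a
  consensus (itself) and zero diversity but cannot be split.
* All randomness (splits, tuning, GA, generator) flows from integer seeds;
  the same seed gives byte-identical outputs, and seeded determinism is
  itself under test.

# Problem sizes

The test suite and the acceptance script run entirely on generated data at
deliberate desk scale: oracle checks use 1,000 random count vectors and
libraries of S ≤ 20; model checks use S = 60–200, R = 6–40; the design
oracle enumerates all 4^6 = 4,096 six-mers; cross-validation uses 10–25
repeats with forests of 100–500 trees. These sizes exercise every code
path while keeping a full run in the tens of seconds on one CPU; all of
them scale up by changing the corresponding arguments.

# Known limitations

* Entropy is defined for nucleotide positions only; the GC-content feature
  is continuous and is not assigned an entropy (any such number would
  depend on an arbitrary discretization).
* No k-mer, physicochemical or structural features; no neural estimators;
  no multi-objective design (e.g. activity vs. synthesis constraints such
  as restriction sites or homopolymers).
* Classification probability calibration is out of scope; predicted
  classes are hard labels.
* The CSV reader is the only ingestion path (no FASTA/GenBank), matching
  how such libraries are typically shared.
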