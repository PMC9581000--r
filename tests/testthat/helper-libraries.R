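# Shared fixture builders: everything is generated in code at test time.

make_library <- function(sequences, expression = seq_along(sequences),
                         ids = paste0("p", seq_along(sequences)), ...) {
  promoter_library(data.frame(id = ids, sequence = sequences,
                              expression = expression), ...)
}

# Random library of S distinct-ish sequences of length R with random targets.
random_library <- function(S, R, seed = 1) {
  set.seed(seed)
  seqs <- replicate(S, paste(sample(c("A", "C", "G", "T"), R, replace = TRUE),
                             collapse = ""))
  make_library(seqs, expression = rnorm(S))
}

# Small planted-signal library for model tests: additive weights at
# `n_causal` positions, optional noise.
planted_library <- function(S = 80, R = 12, n_causal = 3, noise_fraction = 0,
                            mutation_rate = 0.5, effect_size = 2, seed = 42) {
  generate_library(synthetic_spec(
    R = R, S = S, n_causal = n_causal, effect_size = effect_size,
    mutation_rate = mutation_rate, noise_fraction = noise_fraction,
    seed = seed))
}

# An estimator that predicts (approximately) a constant: RF trained on a
# constant target always returns that constant.
constant_estimator <- function(value = 5, R = 6, seed = 7) {
  set.seed(seed)
  seqs <- unique(replicate(30, paste(sample(c("A", "C", "G", "T"), R,
                                            replace = TRUE), collapse = "")))
  lib <- make_library(seqs, expression = rep(value, length(seqs)))
  fs <- select_positions(lib, 0)
  ts <- target_spec(lib$expression, 1)
  es <- estimator_spec("RF", "regression",
                       grid = list(num_trees = 50), tuning_repeats = 1)
  grid_search_train(lib, es, fs, ts)
}
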