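# Promoter design: genetic-algorithm search over sequence space against a
# trained estimator, plus an exhaustive oracle for small spaces.

#' Design target
#'
#' In regression mode the search minimizes |predicted - target_value|, with
#' an optional distance term pulling candidates toward the reference
#' sequence(s). In classification mode candidates must fall in
#' `target_class`; among feasible sequences the normalized Hamming distance
#' to the nearest reference is minimized (infeasible candidates carry an
#' additive penalty so early populations still evolve).
#'
#' @param target_value Desired expression (regression mode).
#' @param target_class Desired class label (classification mode).
#' @param reference Character vector of reference sequence(s); defaults to
#'   the library consensus at design time.
#' @param distance_weight Weight of the reference-distance term in
#'   regression fitness (default 0).
#' @return An object of class `design_target`.
#' @export
design_target <- function(target_value = NULL, target_class = NULL,
                          reference = NULL, distance_weight = 0) {
  if (is.null(target_value) == is.null(target_class)) {
    abort("Set exactly one of target_value (regression) or target_class (classification)",
          class = "promoterkit_value_error")
  }
  mode <- if (is.null(target_class)) "regression" else "classification"
  structure(list(mode = mode, target_value = target_value,
                 target_class = target_class, reference = reference,
                 distance_weight = distance_weight),
            class = "design_target")
}

#' Genetic-algorithm parameters
#'
#' Conventional defaults: population 100, 50 generations, per-position
#' mutation probability 1/R (set at run time when `NULL`), two-point
#' crossover with probability 0.7, tournament selection of size 3, elitism
#' of one individual.
#'
#' @param population_size,generations,mutation_prob,crossover_prob,tournament_size
#'   GA controls.
#' @param n_results Number of designed sequences to return.
#' @param seed Integer seed.
#' @return An object of class `ga_params`.
#' @export
ga_params <- function(population_size = 100L, generations = 50L,
                      mutation_prob = NULL, crossover_prob = 0.7,
                      tournament_size = 3L, n_results = 3L, seed = 1L) {
  if (population_size < 2) abort("population_size must be >= 2",
                                 class = "promoterkit_value_error")
  if (generations < 1) abort("generations must be >= 1",
                             class = "promoterkit_value_error")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_prob = mutation_prob,
                 crossover_prob = crossover_prob,
                 tournament_size = as.integer(tournament_size),
                 n_results = as.integer(n_results),
                 seed = as.integer(seed)),
            class = "ga_params")
}

# integer-coded population: S x R matrix over 1..4 (A,C,G,T)
decode_population <- function(pop) {
  apply(pop, 1, function(row) paste(NUCLEOTIDES[row], collapse = ""))
}

min_ref_distance <- function(sequences, references) {
  ref_m <- do.call(rbind, strsplit(references, "", fixed = TRUE))
  seq_m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  vapply(seq_len(nrow(seq_m)), function(i) {
    min(rowMeans(ref_m != matrix(seq_m[i, ], nrow(ref_m), ncol(seq_m),
                                 byrow = TRUE)))
  }, numeric(1))
}

INFEASIBLE_PENALTY <- 10.0   # on a [0,1] distance scale
LIBRARY_PENALTY <- 1e9       # library members must never win

design_fitness <- function(est, target, sequences, library_set) {
  pred <- predict(est, sequences)
  if (target$mode == "regression") {
    fit <- abs(pred - target$target_value)
    if (target$distance_weight > 0) {
      fit <- fit + target$distance_weight *
        min_ref_distance(sequences, target$reference)
    }
  } else {
    d <- min_ref_distance(sequences, target$reference)
    fit <- d + INFEASIBLE_PENALTY * (pred != target$target_class)
  }
  fit[sequences %in% library_set] <- LIBRARY_PENALTY
  list(fitness = fit, predicted = pred)
}

resolve_target <- function(est, target, lib) {
  if (target$mode != est$spec$task) {
    abort(paste0("Design target mode (", target$mode,
                 ") does not match estimator task (", est$spec$task, ")"),
          class = "promoterkit_value_error")
  }
  if (is.null(target$reference)) {
    target$reference <- if (!is.null(lib)) consensus_sequence(lib)
                        else strrep("A", est$seq_length)
  }
  target
}

#' Design promoter sequences with a genetic algorithm
#'
#' Searches sequence space for promoters whose predicted activity matches
#' the design target, using tournament selection, two-point crossover,
#' per-position point mutation (always to a different nucleotide) and
#' elitism of one. The initial population is uniform random. Sequences
#' already present in the library are excluded — they receive the worst
#' possible fitness during the search and are filtered from the results.
#'
#' @param est A trained estimator.
#' @param target A [design_target()] matching the estimator task.
#' @param params [ga_params()].
#' @param lib The promoter library whose sequences are excluded (and whose
#'   consensus is the default reference). May be `NULL`.
#' @return An object of class `design_result`: a tibble of up to
#'   `n_results` distinct feasible sequences with predicted activity/class
#'   and distance to the nearest reference, plus attribute
#'   `fitness_history` (best fitness per generation).
#' @export
design_promoters <- function(est, target, params = ga_params(), lib = NULL) {
  target <- resolve_target(est, target, lib)
  R <- est$seq_length
  library_set <- if (!is.null(lib)) unique(lib$sequence) else character(0)
  pmut <- params$mutation_prob %||% (1 / R)
  set.seed(params$seed)
  pop <- matrix(sample.int(4L, params$population_size * R, replace = TRUE),
                params$population_size, R)
  history <- numeric(params$generations)
  archive <- new.env(parent = emptyenv())  # best fitness per seen sequence
  evaluate <- function(pop) {
    seqs <- decode_population(pop)
    res <- design_fitness(est, target, seqs, library_set)
    for (i in seq_along(seqs)) {
      prev <- archive[[seqs[i]]]
      if (is.null(prev) || res$fitness[i] < prev$fitness) {
        archive[[seqs[i]]] <- list(fitness = res$fitness[i],
                                   predicted = res$predicted[i])
      }
    }
    res$fitness
  }
  fit <- evaluate(pop)
  for (gen in seq_len(params$generations)) {
    elite_i <- which.min(fit)
    # tournament selection
    n <- params$population_size
    parents <- vapply(seq_len(n), function(i) {
      cand <- sample.int(n, params$tournament_size, replace = TRUE)
      cand[which.min(fit[cand])]
    }, integer(1))
    newpop <- pop[parents, , drop = FALSE]
    # two-point crossover on consecutive pairs
    for (i in seq(1, n - 1, by = 2)) {
      if (stats::runif(1) < params$crossover_prob && R >= 2) {
        cut <- sort(sample.int(R, 2))
        span <- seq(cut[1], cut[2])
        tmp <- newpop[i, span]
        newpop[i, span] <- newpop[i + 1, span]
        newpop[i + 1, span] <- tmp
      }
    }
    # point mutation to a different nucleotide
    mut <- matrix(stats::runif(n * R) < pmut, n, R)
    if (any(mut)) {
      idx <- which(mut)
      shift <- sample.int(3L, length(idx), replace = TRUE)
      newpop[idx] <- ((newpop[idx] - 1L + shift) %% 4L) + 1L
    }
    # elitism of 1
    newpop[1, ] <- pop[elite_i, ]
    pop <- newpop
    fit <- evaluate(pop)
    # memetic step: steepest single-substitution descent from the current
    # best keeps the search from stalling just short of a local optimum
    repeat {
      b <- which.min(fit)
      nbrs <- matrix(pop[b, ], nrow = 3L * R, ncol = R, byrow = TRUE)
      k <- 0L
      for (j in seq_len(R)) for (s in 1:3) {
        k <- k + 1L
        nbrs[k, j] <- ((nbrs[k, j] - 1L + s) %% 4L) + 1L
      }
      nfit <- evaluate(nbrs)
      if (min(nfit) < fit[b]) {
        pop[b, ] <- nbrs[which.min(nfit), ]
        fit[b] <- min(nfit)
      } else break
    }
    history[gen] <- min(min(fit), if (gen > 1) history[gen - 1] else Inf)
  }
  seen <- ls(archive)
  fits <- vapply(seen, function(s) archive[[s]]$fitness, numeric(1))
  preds <- vapply(seen, function(s) archive[[s]]$predicted, numeric(1))
  feasible <- fits < LIBRARY_PENALTY & !(seen %in% library_set)
  if (target$mode == "classification") {
    feasible <- feasible & preds == target$target_class
  }
  if (!any(feasible)) {
    warn("Genetic algorithm found no feasible sequence")
    out <- tibble::tibble(id = character(0), sequence = character(0),
                          predicted = numeric(0),
                          distance_to_reference = numeric(0),
                          fitness = numeric(0))
  } else {
    ord <- order(fits[feasible], seen[feasible])
    keep <- head(which(feasible)[ord], params$n_results)
    out <- tibble::tibble(
      id = paste0("design_", seq_along(keep)),
      sequence = seen[keep],
      predicted = preds[keep],
      distance_to_reference = min_ref_distance(seen[keep], target$reference),
      fitness = fits[keep]
    )
  }
  structure(out, fitness_history = history, target = target,
            class = c("design_result", class(out)))
}

#' Exhaustive design oracle for small sequence spaces
#'
#' Evaluates every length-R A/C/G/T sequence under the same fitness as
#' [design_promoters()] and returns the global optimum (ties broken
#' lexicographically). Intended as a correctness oracle; limited to R <= 10.
#'
#' @param est A trained estimator.
#' @param target A [design_target()].
#' @param R Sequence length (must equal the estimator's training length).
#' @param lib Optional library whose sequences are excluded.
#' @return A list with `sequence`, `fitness` and `predicted`.
#' @export
brute_force_design <- function(est, target, R, lib = NULL) {
  if (R > 10) abort("Exhaustive search is limited to R <= 10 (4^R sequences)",
                    class = "promoterkit_value_error")
  target <- resolve_target(est, target, lib)
  library_set <- if (!is.null(lib)) unique(lib$sequence) else character(0)
  grid <- do.call(expand.grid, c(rep(list(NUCLEOTIDES), R),
                                 list(stringsAsFactors = FALSE)))
  # lexicographic order: leftmost position most significant
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  seqs <- do.call(paste0, grid)
  res <- design_fitness(est, target, seqs, library_set)
  best <- which.min(res$fitness)   # first index wins ties -> lexicographic
  list(sequence = seqs[best], fitness = res$fitness[best],
       predicted = res$predicted[best])
}
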