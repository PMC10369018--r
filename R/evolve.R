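# Genetic algorithm: Latin hypercube initialization, min-max interpolated
# fitness, with-replacement proportional selection, two-scale Gaussian
# mutation.

#' Mutation configuration
#'
#' Each parameter of a copied genome is independently hit by a small
#' mutation (probability 0.33, Gaussian sd 0.5) and/or a large one
#' (probability 0.01, sd 5). The standard deviations are scaled to the
#' order of magnitude of the initialization range `[-50, 50]`. Mutated
#' values are not clipped: the initialization range is not a constraint.
#'
#' @param small_prob,small_sd Probability and sd of small mutations.
#' @param large_prob,large_sd Probability and sd of large mutations.
#' @return An object of class `mutation_config`.
#' @export
mutation_config <- function(small_prob = 0.33, small_sd = 0.5,
                            large_prob = 0.01, large_sd = 5) {
  stopifnot(small_prob >= 0, small_prob <= 1, large_prob >= 0,
            large_prob <= 1, small_sd > 0, large_sd > 0)
  structure(list(small_prob = small_prob, small_sd = small_sd,
                 large_prob = large_prob, large_sd = large_sd),
            class = "mutation_config")
}

#' Initialize a population by maximin Latin hypercube sampling
#'
#' Draws `n` genomes in `[low, high]^genome_length` with the Latin
#' hypercube property (per dimension, exactly one point in each of `n`
#' equal-width bins, randomized within the bin) under the maximin
#' criterion, which maximizes the minimum inter-point distance. Backed by
#' [lhs::maximinLHS()].
#'
#' @param n Population size (>= 2).
#' @param genome_length Number of parameters per genome.
#' @param low,high Initialization range, default `[-50, 50]`.
#' @param seed Integer seed; the design is reproducible given the seed.
#' @return An `n x genome_length` numeric matrix of class `population`
#'   (attribute `generation_index = 0`).
#' @export
init_population_lhs <- function(n, genome_length, low = -50, high = 50,
                                seed = NULL) {
  if (n < 2) stop("population size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::maximinLHS(n, genome_length)
  P <- low + (high - low) * u
  structure(P, class = c("population", "matrix", "array"),
            generation_index = 0L)
}

#' Normalized fitness from penalized scores
#'
#' Scores are first min-max interpolated within the generation (`0` for
#' the generation minimum, `1` for the maximum), then normalized to sum to
#' one. A degenerate all-equal generation gets uniform fitness `1/n`
#' rather than a division by zero.
#'
#' @param penalized_scores Numeric vector of `S_p` values (finite).
#' @return Nonnegative fitness vector summing to 1.
#' @examples
#' fitness_from_scores(c(0, 50, 100))  # 0, 1/3, 2/3
#' @export
fitness_from_scores <- function(penalized_scores) {
  if (!length(penalized_scores)) stop("need at least one score")
  if (!all(is.finite(penalized_scores))) stop("scores must be finite")
  rng <- range(penalized_scores)
  if (rng[1] == rng[2])
    return(rep(1 / length(penalized_scores), length(penalized_scores)))
  u <- (penalized_scores - rng[1]) / (rng[2] - rng[1])
  u / sum(u)
}

#' Fitness-proportional (roulette-wheel) selection
#'
#' Draws `n` parent indices independently with replacement, each index
#' picked with probability equal to its normalized fitness.
#'
#' @param fitnesses Fitness vector summing to 1.
#' @param n Number of parents to draw.
#' @return Integer vector of `n` parent indices.
#' @export
select_parents <- function(fitnesses, n) {
  if (abs(sum(fitnesses) - 1) > 1e-8)
    stop("fitnesses must sum to 1")
  sample.int(length(fitnesses), n, replace = TRUE, prob = fitnesses)
}

#' Mutate a genome (or a whole population)
#'
#' Per parameter, independently: with probability `small_prob` add
#' `Normal(0, small_sd)` noise; with probability `large_prob` add
#' `Normal(0, large_sd)` noise. Both can hit the same parameter. Values
#' are not clipped to the initialization range.
#'
#' @param genome Numeric vector, or a matrix with one genome per row.
#' @param config A [mutation_config()].
#' @return Mutated object of the same shape.
#' @export
mutate_genome <- function(genome, config = mutation_config()) {
  m <- length(genome)
  small <- stats::runif(m) < config$small_prob
  large <- stats::runif(m) < config$large_prob
  out <- genome
  if (any(small))
    out[small] <- out[small] + stats::rnorm(sum(small), 0, config$small_sd)
  if (any(large))
    out[large] <- out[large] + stats::rnorm(sum(large), 0, config$large_sd)
  out
}

#' Run the genetic algorithm
#'
#' Initializes `n` genomes by maximin Latin hypercube sampling in
#' `[-50, 50]`, then loops for `generations`: evaluate every agent over
#' the 4+1 round protocol, compute normalized fitness from penalized
#' scores, sample parents with replacement proportionally to fitness, copy
#' and mutate. Start positions for the four scored rounds are redrawn
#' uniformly in the arena each generation, per agent by default
#' (`shared_starts = TRUE` gives all agents the same four starts for
#' variance reduction).
#'
#' Randomness is organized in named streams (initialization, starts,
#' selection, mutation) derived deterministically from `seed`, so the run
#' is fully reproducible.
#'
#' @param arena An [arena_config()].
#' @param objective `"explore"` or `"survive"`.
#' @param n Population size.
#' @param generations Number of generations.
#' @param n_hidden Hidden-layer size of every brain (default 3).
#' @param mutation A [mutation_config()].
#' @param seed Master integer seed.
#' @param shared_starts Share the four random starts across agents within a
#'   generation?
#' @param initial_population Optional `n x param_count(n_hidden)` matrix
#'   overriding the Latin hypercube initialization (e.g. to plant known
#'   genomes).
#' @param out_dir Optional directory; if given, a generation log CSV and a
#'   best-genome JSON per generation are written there.
#' @return An object of class `evolution_result`: list with `records` (one
#'   row per generation: `generation`, `best_penalized_score`,
#'   `mean_penalized_score`, `best_reference_score`), `best_genomes` (list
#'   of the per-generation best genome vectors), `final_population`, and
#'   the configuration used.
#' @export
run_evolution <- function(arena, objective = c("explore", "survive"),
                          n = 500, generations = 60, n_hidden = 3L,
                          mutation = mutation_config(), seed = 1,
                          shared_starts = FALSE,
                          initial_population = NULL,
                          out_dir = NULL) {
  objective <- match.arg(objective)
  stopifnot(generations >= 1, n >= 2)
  len <- param_count(n_hidden)
  set.seed(seed)
  stage <- sample.int(2147480000L, 4)  # init, starts, selection, mutation
  mix <- function(s, g) (s + g * 7919) %% 2147483647L + 1L

  if (is.null(initial_population)) {
    P <- init_population_lhs(n, len, seed = stage[1])
  } else {
    P <- as.matrix(initial_population)
    stopifnot(nrow(P) == n, ncol(P) == len)
  }
  L <- arena$side_length

  records <- data.frame(generation = integer(generations),
                        best_penalized_score = numeric(generations),
                        mean_penalized_score = numeric(generations),
                        best_reference_score = numeric(generations))
  best_genomes <- vector("list", generations)

  for (g in seq_len(generations)) {
    set.seed(mix(stage[2], g))
    if (shared_starts) {
      starts <- matrix(stats::runif(8, 0, L), 4, 2)
    } else {
      starts <- array(stats::runif(n * 4 * 2, 0, L), dim = c(n, 4L, 2L))
    }
    ev <- eval_genomes(P, n_hidden, arena, objective, starts)
    best <- which.max(ev$penalized_score)
    records$generation[g] <- g
    records$best_penalized_score[g] <- ev$penalized_score[best]
    records$mean_penalized_score[g] <- mean(ev$penalized_score)
    records$best_reference_score[g] <- ev$reference_score[best]
    best_genomes[[g]] <- P[best, ]

    if (!is.null(out_dir)) {
      write_brain(unpack_brain(P[best, ], n_hidden),
                  file.path(out_dir, sprintf("best_genome_gen%03d.json", g)),
                  extra = list(generation = g, seed = seed,
                               penalized_score = ev$penalized_score[best]))
    }

    if (g < generations) {
      f <- fitness_from_scores(ev$penalized_score)
      set.seed(mix(stage[3], g))
      parents <- select_parents(f, n)
      P2 <- P[parents, , drop = FALSE]
      set.seed(mix(stage[4], g))
      P <- mutate_genome(P2, mutation)
    }
  }

  res <- structure(list(records = records, best_genomes = best_genomes,
                        final_population = P,
                        arena = arena, objective = objective, n = n,
                        generations = generations, n_hidden = n_hidden,
                        mutation = mutation, seed = seed,
                        shared_starts = shared_starts),
                   class = "evolution_result")
  if (!is.null(out_dir))
    utils::write.csv(records, file.path(out_dir, "generation_log.csv"),
                     row.names = FALSE)
  res
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf(paste0("<evolution_result> objective %s, n = %d, %d ",
                     "generations, seed %d\n  final best penalized score: ",
                     "%.1f (reference-round score %.0f)\n"),
              x$objective, x$n, x$generations, x$seed,
              x$records$best_penalized_score[x$generations],
              x$records$best_reference_score[x$generations]))
  invisible(x)
}

#' Best genome of a finished run
#'
#' @param result An [run_evolution()] result.
#' @param generation Generation to take the best genome from (default:
#'   last).
#' @return A [brain_params()].
#' @export
best_brain <- function(result, generation = result$generations) {
  unpack_brain(result$best_genomes[[generation]], result$n_hidden)
}
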