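# Reduced-scale evolution runs shared by the emergent-behaviour tests:
# n = 500 agents, 60 generations, lifespan 1000, reference speed and
# steering, seeds 1-3. Runs are cached per session (deterministic given
# the seed, so caching does not change any result).

evolved_cache <- new.env(parent = emptyenv())

reduced_arena <- function() arena_config(max_lifespan = 1000L)

evolved_run <- function(objective, seed) {
  key <- paste(objective, seed, sep = "_")
  if (is.null(evolved_cache[[key]])) {
    evolved_cache[[key]] <- run_evolution(reduced_arena(), objective,
                                          n = 500, generations = 60,
                                          seed = seed)
  }
  evolved_cache[[key]]
}

# replay a best agent from the arena centre plus 8 random starts
replay_best <- function(result, objective, replay_seed) {
  a <- reduced_arena()
  bb <- best_brain(result)
  set.seed(replay_seed)
  starts <- rbind(c(300, 300), matrix(stats::runif(16, 50, 550), 8, 2))
  bind_trajectories(lapply(seq_len(nrow(starts)), function(i) {
    run_round(bb, a, objective, starts[i, ], stats::runif(1, -pi, pi))
  }))
}
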