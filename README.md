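# evosteer

Neuroevolution of steering controllers for self-propelled agents in a
bounded arena.

`evosteer` is for movement ecologists and behavioural modellers who want
to ask: *what movement rules emerge when an embodied agent with a minimal
brain is optimized for an ecological objective?* An agent moves at
constant speed `s` in a closed square arena and can only change heading.
Its entire sensory input is the distance `d_w` and signed angle `theta_w`
to the closest point of the wall. Each time step a tiny sigmoid
perceptron — 2 inputs, one hidden layer of 3 neurons, 1 output, 13
parameters in total — maps the normalized cues to a turning angle

```
o1  = sigma(b0 + sum_k v_k * sigma(b_k + w_k1 * d̄_w + w_k2 * θ̄_w))
Δφ  = (o1 − 0.5) · i_steering,          i_steering = 2π by default
θ'  = θ + Δφ;   x' = x + s·cos(θ');   y' = y + s·sin(θ')
```

A genetic algorithm evolves the 13 parameters: maximin Latin hypercube
initialization in `[−50, 50]`, four scored rounds per agent (random
starts, fixed initial headings `0, −π, −π/2, π/2`) plus a fifth
monitoring round from the centre, min–max interpolated and normalized
fitness on the penalized score `S_p = S − Σ p_t Δφ²`, with-replacement
proportional selection, and two-scale Gaussian mutation (33 % small,
sd 0.5; 1 % large, sd 5). Two objectives are built in — **survive**
(steps alive) and **explore** (distinct grid cells visited) — alongside
the closed-form fish wall-avoidance rule
`Δφ = sin(θ_w)·exp(−(d_w/l_w)²)`, supervised fitting of networks to that
rule, and circular-statistics analyses of the emergent trajectories.

## Worked example

Evolve explorers at reduced scale (500 agents, 60 generations, lifespan
1000 — a couple of minutes on one CPU), then replay and analyse the best
controller:

```r
library(evosteer)

arena <- arena_config(max_lifespan = 1000L)
res <- run_evolution(arena, objective = "explore", n = 500,
                     generations = 60, seed = 1)
print(res)
#> <evolution_result> objective explore, n = 500, 60 generations, seed 1
#>   final best penalized score: 1267.0 (reference-round score 322)

brain <- best_brain(res)
replay <- run_round(brain, arena, "explore", start = c(300, 300),
                    heading0 = 0)
print(replay)
#> <round_result> 1000 steps survived, score 322, turn cost 0, death: lifespan

wall_following_fraction(replay, band = 100)
#> [1] 0.5334665
near <- signed_turn_distribution(replay, "near")
circular_mean(near$values)
#> [1] 1.349742
```

The best agent survives its full lifespan and discovers 322 of the 400
grid cells in a single round (a straight-line drifter manages about 20).
It spends 53 % of its time within 100 px of the boundary — wall
following — and its near-wall (`d_w < 50` px) circular mean of
`δφ₊ = Δφ·sign(θ_w)` is +1.35 rad: strongly positive, i.e. it turns
*away* from the closest wall. Under the survive objective the same
pipeline instead evolves freezing: tight back-and-forth oscillation on a
50-px segment (`segment_length_estimate()`).

The hidden-layer-size sweep against the fish rule:

```r
ts <- rule_training_set(empirical_rule(60), arena_config())
compare_structures(c(1, 3, 6), ts, seed = 1)
#>   n_hidden       rmse
#> 1        1 0.20771841
#> 2        3 0.08600001
#> 3        6 0.02645102
```

One neuron cannot represent the rise-and-fall of `sin(θ_w)` (RMSE stuck
at ~0.21 rad); three neurons reach under a tenth of the rule's 1-rad
amplitude, and further neurons add no material improvement (see the
methods vignette, `vignettes/evolving-steering.Rmd`).

A thin command-line front end over the same functions lives in
`inst/cli/evosteer.R` (`evolve`, `fit-rule`, `compare-structures`,
`replay`, `analyze`).

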