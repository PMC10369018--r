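Package: evosteer
Title: Neuroevolution of Steering Controllers for Self-Propelled Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates self-propelled agents moving at constant speed in a
    bounded square arena, steered at each time step by a small feed-forward
    neural network (2 inputs, one hidden layer, 1 sigmoid output) that reads
    the agent's distance and angle to the closest wall. Network weights are
    optimized by a genetic algorithm (Latin hypercube initialization,
    fitness-proportional selection, two-scale Gaussian mutation) under
    survival or arena-exploration objectives. Includes a closed-form fish
    wall-avoidance rule, supervised fitting of networks to that rule to
    gauge the minimal sufficient network size, and circular-statistics
    tools to infer interaction rules, presence densities and turning-angle
    distributions from simulated trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
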