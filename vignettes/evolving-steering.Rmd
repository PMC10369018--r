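---
title: "Evolving steering controllers in a bounded arena: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving steering controllers in a bounded arena: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evosteer)
```

## The model

An agent is a self-propelled particle: it moves at constant speed $s$
(50 px per time step by default) inside a closed square arena of side
$L = 600$ px and can only control its heading. Its entire sensory world is
the closest point of the boundary, perceived as two cues: the distance
$d_w$ and the signed angle $\theta_w$ between its heading and the bearing
to that point. With our sign convention, $\theta_w = 0$ means facing the
wall head-on and $\theta_w > 0$ means the wall lies to the agent's right.
Both cues are normalized to $[0,1]$ before entering the controller:
$\bar d_w = d_w/(L/2)$ (the centre of a square is exactly $L/2$ from the
nearest wall) and $\bar\theta_w = (\theta_w + \pi)/(2\pi)$.

The controller is a multilayer perceptron with two inputs, one hidden
layer of $K$ sigmoid neurons ($K = 3$ by default) and one sigmoid output,

$$o_1 = \sigma\!\Big(b_0 + \sum_{k=1}^{K} v_k\,
  \sigma(b_k + w_{k1}\bar d_w + w_{k2}\bar\theta_w)\Big),
  \qquad \sigma(z) = \frac{1}{1+e^{-z}},$$

for $4K + 1$ parameters in total — 13 for the reference network. The
output is centred and scaled into a turning angle
$\Delta\phi = (o_1 - 0.5)\, i_\text{steering}$ with
$i_\text{steering} = 2\pi$ by default, so one step can turn by anything
in $(-\pi, \pi)$. The heading updates first, then the position moves by
$s$ along the *new* heading. An agent whose position leaves the closed
square dies; death ends the round but is not an error of the model.

## The genetic algorithm

Each generation holds $n$ genomes (the flat 13-parameter vectors).
Generation zero is drawn by maximin Latin hypercube sampling over
$[-50, 50]^{13}$ (`lhs::maximinLHS`), which stratifies every parameter
into $n$ bins while spreading points apart. Every agent is then scored
over four rounds from four uniformly random start positions with initial
headings $0, -\pi, -\pi/2, \pi/2$ (fixed order), plus a fifth round from
the arena centre whose score is only recorded for cross-generation
monitoring, never used for fitness.

Two objectives are implemented: **survive** (score = steps completed
while inside) and **explore** (score = distinct cells of the
$20 \times 20$ grid entered at least once, the starting cell included).
Turning can be penalized: $C_t = \sum p_t\,\Delta\phi^2$, and the
penalized score is $S_p = S - C_t$. Within a generation, $S_p$ is min-max
interpolated to $[0,1]$ and normalized to sum to one; parents are drawn
with replacement proportionally to that fitness; each copy is mutated
per-parameter with small (probability 0.33, sd 0.5) and independent large
(probability 0.01, sd 5) Gaussian perturbations, unclipped.

Decisions the description of the algorithm leaves open, fixed here once:

* the heading-to-round mapping is the listed fixed order, so score
  differences across agents come only from brains and starts;
* the four random starts are redrawn per agent and generation
  (`shared_starts = TRUE` shares them for variance reduction);
* small and large mutations are independent events that can co-occur on
  one parameter;
* there is no elitism: the best genome is archived each generation but
  not protected in the population;
* an all-equal-score generation (possible early) receives uniform
  fitness rather than a division by zero;
* the starting cell counts as discovered at $t = 0$; cells flown *over*
  mid-step are not credited — the model is discrete-time, and at
  $s = 50$ px with 30-px cells an agent can jump a cell diagonal. This
  shapes optimal exploration strategies and is deliberate;
* the killing step still pays its turning cost, and does not count
  toward the survival score;
* an agent exactly on the boundary is alive (closed square).

## The empirical wall-avoidance rule

As an external reference the package carries the simplified
wall-avoidance rule measured in the rummy-nose tetra:
$\Delta\phi = \sin(\theta_w)\exp(-(d_w/l_w)^2)$ — odd in the wall angle
(direction), Gaussian in distance (range). The interaction range `l_w`
is not fixed by the behavioural literature value we mirror; we default
to 60 px, a tenth of the arena side, so that the interaction zone spans
roughly one reference step. `rule_training_set()` expresses the rule in
output units ($o_1^* = \Delta\phi^*/i_\text{steering} + 0.5$), so a
network fitted to it by `fit_network_to_rule()` is directly a usable
brain.

Fitting is ordinary least squares on the network output, by BFGS with an
analytic gradient from 10 random restarts ($\mathcal N(0, 2)$ initial
parameters, 2000 iterations). These budgets were chosen so that the
reached minima stop improving with further budget: at that point the
sweep in `compare_structures()` measures representational capacity, not
optimizer luck. One hidden neuron can only produce a response monotone
in each input and cannot represent the rise-and-fall of $\sin$, so its
RMSE stays near 0.21 rad; three neurons reach about 0.08 rad, under a
tenth of the rule's 1-rad amplitude. We call an improvement *material*
when it exceeds 0.1 rad — a tenth of the rule's maximal turn; by that
yardstick six neurons (≈ 0.02 rad) add nothing material over three,
while three improve materially over one.

## Trajectory analyses

All angle averaging uses the circular mean
$\bar\alpha = \operatorname{atan2}(\sum\sin\alpha_j, \sum\cos\alpha_j)$;
a resultant below $10^{-12}$ is reported as undefined (`NA`), never as a
silent zero. `inferred_rule_heatmap()` recovers the behavioural map from
trajectories alone by binning steps over $(\theta_w, d_w)$ (36 angle ×
30 distance bins by default; the binning behind the published heatmaps
is not documented, so ours is configurable) and taking per-bin circular
means. Near/far regimes use the published 50 px / 150 px cut-offs.
$\delta\phi_+ = \Delta\phi\cdot\operatorname{sign}(\theta_w)$ is
positive when turning away from the wall; steps exactly facing the wall
have $\operatorname{sign}(0) = 0$ and are excluded from the
away/toward dichotomy. U-turns are decision steps with
$|\Delta\phi| > \pi/2$ (the turn distribution is trimodal — small
angles, right angles, U-turns — so the threshold sits in the gap);
`segment_length_estimate()` is the median distance between consecutive
U-turn positions. Compatibility of small far-field angles (< 60°) with
a normal distribution is reported as a Kolmogorov–Smirnov distance, not
a test verdict: the published claim is visual.

One numerical caveat is built into `heatmap_antisymmetry()`: a circular
mean close to $\pm\pi$ describes a full U-turn whose left/right sign is
arbitrary (the mean of angles clustered at the wrap can land on either
side), so bins with $|\bar{\Delta\phi}| > 3$ rad carry no usable sign
and are excluded from the antisymmetry comparison, as are bins with
$|\bar{\Delta\phi}| < 0.01$ rad (no directional signal) or fewer than
50 samples.

## Problem sizes and what reduced scale shows

The published study conditions are $n = 20\,000$ agents, 150
generations, lifespan 5000, 60 independent trials. This package's tests
and acceptance script run the same model at a reduced scale chosen to
keep a laptop-class run in minutes: $n = 500$, 60 generations, lifespan
1000, three seeds. At that scale the following robustly reproduce:

* **Freezing under the survive objective.** Saturated networks that
  U-turn every step appear already in the Latin hypercube initialization
  and survive indefinitely; the best evolved agent oscillates on a
  segment equal to the per-step displacement (50 px), the shortest
  possible at constant speed.
* **Wall avoidance and wall following under the explore objective.**
  The best agents' near-wall ($d_w < 50$ px) circular mean of
  $\delta\phi_+$ is strongly positive (turning away), and more than half
  of their time is spent within 100 px of the boundary.
* **Three hidden neurons suffice** to fit the fish avoidance rule, with
  no material gain from six.

Two population-level symmetries do **not** emerge from three trials, and
their checks are expected to fail at reduced scale: the sign
antisymmetry of the inferred near-wall heatmap, and the far-field
left/right balance ($|$circular mean$| < 0.05$ rad). Each *individual*
best agent is deterministic and typically chiral — it always circulates
the arena one way, modulating turn magnitude rather than direction near
walls — so its heatmap is one-sided. The published antisymmetric average
pools the best agents of 150 generations × 60 trials, letting opposite
chiralities cancel; three seeds cannot provide that cancellation. We
report the checks honestly rather than weaken them: they measure a
property of the population average, not of any evolved individual.

## What the generator does and does not emulate

All inputs are synthetic by design: the simulator itself generates every
trajectory the analyses consume, and the empirical reference is a
closed-form rule, not a dataset. Passing tests therefore demonstrate
internal consistency of model, optimizer and analyses — they do not
validate the model against real animal trajectories, which are outside
this package's scope. Real fish differ in known ways: they swim in
circular tanks, modulate speed, burst-and-coast, and carry sensory and
motor noise, none of which the strictly deterministic constant-speed
agent has.

## Known limitations

* Exact reproduction of the published full-scale runs is impossible in
  principle (their seeds are unpublished); all quantitative checks are
  at the reduced scale above.
* Wall collision is tested only at integer time steps; a step may clip
  a corner region without dying. This matches the discrete-time model.
* `lhs::maximinLHS` is quadratic in the population size; at the
  full-scale $n = 20\,000$ initialization becomes the slow step.
* The GA evaluates rounds vectorized across agents in pure R; a full
  paper-scale replication (60 trials × 150 generations × 20 000 agents
  × 5000 steps) is out of desk-scale reach and was not attempted.
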