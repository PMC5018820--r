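---
title: "Methods: the reciprobot simulation platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reciprobot simulation platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reciprobot)
```

# What the platform models

`reciprobot` is a platform for studying how helping and reciprocity evolve
when behavior must be produced by an actual control mechanism rather than
assumed as a strategy label. Pairs of simulated differential-drive robots
forage on a 1 m × 1 m toroidal arena containing two food sources. With a
small per-step probability a robot becomes immobilized ("stuck"); it frees
itself at a low rate, or five times faster while its partner stays within
1 cm of its body — *helping*, which costs the helper foraging time.
Populations of bitstring genotypes encoding the neural controller's
connection weights evolve under fecundity-proportional Wright–Fisher
selection, with the genetic relatedness of interaction partners under
experimental control. A memory input neuron, reporting the fraction of past
stuck episodes that ended with partner help, gives controllers the
information needed to express reciprocity. Around this core the package
provides standardized behavioral assays, artificial-selection breeding of
reference strategies, Moran fixation screening, and a game-dynamics layer
that analyzes measured payoff matrices.

# Genotype and controller

Each connection weight is encoded as 8 bits, most-significant bit first,
read as an integer $v \in [0, 255]$ and mapped linearly to
$w = w_{\min} + v/255\,(w_{\max} - w_{\min})$. The division by 255 (not
256) makes both bounds exactly reachable. The weight range defaults to
$[-5, 5]$, which spans both the saturating and the near-linear regime of
the logistic activation; it is configurable in `decoding_spec()`. Exact
zero is not on the decoding grid, so tests and probes that need motionless
robots pass plain weight vectors, which every evaluation entry point
accepts in place of a genome.

The controller is a three-layer feed-forward network: one constant bias
input and 17 sensory inputs (8 proximity neurons, 9 camera neurons), 9
hidden neurons, 2 output neurons, all logistic. The printed weight count of
182 forces one bias weight per output neuron
($18 \times 9 + 10 \times 2$); this is the only topology consistent with
the stated layer sizes, and it is the layout `build_network()` uses. With
the memory neuron, its 9 input→hidden weights are appended after the main
input→hidden block so that 182-weight genomes remain prefix-compatible,
giving 191 weights. Outputs map linearly onto wheel velocities in
$[-8.2, 8.2]$ cm/s; the sigmoid maps to $[0, 1]$ before scaling (a
documented convention — the source material does not fix it).

Mutation flips each bit independently at $10^{-2}$ per bit per
reproduction. There is no crossover. `weight_distance()` counts differing
8-bit groups ("loci"), the unit in which mutational distances between
strategies are expressed.

# Arena physics and sensing

The world updates in 100 ms steps. Parameters and their defaults
(`arena_config()`):

| parameter | default | meaning |
|---|---|---|
| `arena_side` | 1 m | toroidal world side |
| `robot_diameter` | 7 cm | hard-disc robot body |
| `food_diameter` | 5.4 cm | non-solid food disc |
| `wheel_vmax` | 8.2 cm/s | wheel speed bound |
| `p_stuck` | 5e-4 /step | stuck-onset hazard |
| `p_self_release` | 5e-4 /step | self-release hazard |
| `help_multiplier` | 5 | release speed-up while helped |
| `help_gap` | 1 cm | edge-to-edge helping distance |
| `prox_range` | 5 cm | proximity range beyond the body |
| `eval_steps` | 20,000 | steps per evaluation |

Design choices where the source description was open, with rationale:

* **Kinematics** — differential drive with axle length equal to the body
  diameter; per step the linear speed is $(v_L + v_R)/2$ and the angular
  speed $(v_R - v_L)/\text{axle}$, Euler-integrated with the heading
  updated before translation. This is the minimal standard model given
  that only wheel velocities are specified.
* **Collisions** — overlapping robot discs are projected back into contact
  along their center line; a stuck robot anchors and only the mobile one
  moves. Robots can always separate by driving apart: entangled phenotypes
  are behavioral, not physical locking.
* **Eating** — a robot eats when its center comes within
  `robot_radius + food_radius` = 6.2 cm of a food center; the food
  immediately respawns at a uniform random position. Respawn (and initial
  placement) rejects positions already within eating distance of a robot,
  so food never appears under a robot and a motionless robot gathers
  exactly nothing.
* **Stuck onset** — leaves the robot in place; the stochastic element is
  the timing, not a relocation. Both robots can be stuck simultaneously,
  each waiting on its own release process. An episode ends "helped" iff
  the partner is within the helping distance at the step the release
  fires, which is also what increments the memory counters.
* **Proximity sensors** — 8 sensors at 45° spacing; the sensor facing
  nearest the partner's bearing responds as $1 - \text{gap}/\text{range}$,
  saturating at contact; only the other robot is solid (food is not
  sensed). Range and falloff are configurable conventions.
* **Camera** — a forward 60° cone in three 20° sectors, three color
  channels per sector. Food renders red, a mobile partner green, a stuck
  partner blue. Activation is the exact angular fraction of the sector
  covered by that color, computed by interval arithmetic on shortest-wrap
  bearings with nearest-object occlusion; range is unlimited on the torus.
* **Randomness** — one R-level RNG stream drives everything in a
  documented draw order (placement, then per-step respawns and one
  stuck/release uniform per robot). `set.seed()` before any entry point
  reproduces a run bit-for-bit; evaluations execute sequentially, so the
  result is trivially identical to the documented sequential contract.

# Evolutionary loop

`run_experiment()` evolves `population_size` (default 100) genotypes.
Each generation every robot is the focal individual in
`evaluations_per_robot` (default 5) evaluations; its fecundity is its own
food total over those evaluations. Partners behave fully but their food in
another robot's focal evaluations is credited to no one, which avoids
double counting since each robot has its own focal evaluations. Pairing
implements relatedness: `related` pairs every focal with a clone
($R = 1$), `unrelated` with a uniform draw from the other $N - 1$
genotypes ($R = 0$), `half_related` with a clone with probability 1/2; a
phase schedule supports the kin-recognition scenario (half-related, then
unrelated). The next generation is sampled with replacement proportionally
to fecundity (uniformly in the degenerate all-zero generation, which keeps
the process defined at initialization) and mutated; optionally each
offspring is replaced by an injected reference genotype with probability
$10^{-2}$, i.e. one individual per generation on average at $N = 100$.
Founding genomes are i.i.d. fair-coin bits.

Helping is measured during runs every `assay_every` (default 25)
generations on the best-fecundity individual plus a uniform sample of 10 —
the measurement cadence is fixed, but the sample is a documented package
choice, as the source protocol does not state one.

# Behavioral assays and the helping-rate estimator

The standardized assay places the focal robot 100 independent times
(1000 steps each) with two food sources and one stuck partner that cannot
free itself; the partner's release hazard is
`p_self_release * help_multiplier` while the focal is within the helping
distance and zero otherwise. Trials start with at least one body diameter
between the robots so no trial begins pre-docked. The chance-level variant
makes the partner contribute nothing to any sensory channel — helping can
then occur only by chance, which requires blinding proximity as well as
the camera. Mood assays clamp the memory input at 0 or 1 for every step.

The helping rate $h$ is the per-step release probability under a censored
geometric model: a release at step $t$ has probability $(1-h)^{t-1} h$,
and an unreleased trial is censored at $T = 1000$. The released proportion
and the release times are exactly the sufficient statistics of this model
— the reason it is the natural reconstruction of an estimate from those
two measurements — and the MLE has the closed form
$$\hat h = \frac{k}{\sum_i t_i + (n - k)\,T}$$
with $k$ releases in $n$ trials. `helping_rate_ci()` inverts the
likelihood-ratio statistic for a profile interval. Under this model
$\hat h$ is bounded by the helped release hazard
($5 \times 5\cdot10^{-4} = 2.5\cdot10^{-3}$): a perfect helper camped at
its partner from step 1 approaches that bound, and full-scale published
helping rates on other estimators' scales are not comparable quantities.
The estimator is validated by parameter recovery (coverage of the 95%
profile interval at $h \in \{10^{-4}, 10^{-3}, 10^{-2}\}$) and by
agreement with independent numeric likelihood maximization to $10^{-10}$
relative tolerance.

`measure_payoff()` runs full evaluations of an ordered genotype pair and
reports the row robot's mean food count with its standard error — the
measurement behind the packaged Selfish/Helper/Reciprocator payoff matrix
(`reference_payoffs()`).

# Artificial selection

`breeding_config()` defines four regimes. The conditional regime clamps
each individual's memory input per evaluation to a fair-coin value;
helping (release events caused) adds `help_bonus` fitness units per event
when the clamp is 1 and subtracts them when it is 0. The bonus magnitude
is not specified by the source protocol; the default of 1 puts one helping
event on the same scale as one food item, balancing selection pressure on
foraging and helping. The Selfish regime is plain unrelated evolution; the
Helper regime adds the bonus unconditionally, and the returned Helper must
assay at ≥ 5× its own chance-level rate (an operationalization of "always
helps"; no acceptance criterion is stated in the source). The
similarity-penalized regime subtracts `similarity_weight` per weight locus
differing from a reference genotype.

The steady-state GA is a minimal documented scheme (the original's
parameters are in unavailable supplementary material): each cycle
evaluates everyone and replaces the worst 10% with mutated copies of
uniformly drawn survivors, so the best individuals persist unmutated.
`fixation_screen()` measures each candidate's 2×2 payoff matrix against a
reference (100 interactions per ordered pair by default, configurable to
the full 1000) and ranks candidates by the Moran fixation probability of a
single copy among $N - 1$ residents.

# Game dynamics

`invasion_threshold()` solves the linear payoff-equality condition
$x P_{ii} + (1-x) P_{ir} = x P_{ri} + (1-x) P_{rr}$; on the packaged
payoff matrix the Reciprocator-vs-Selfish barrier is $5/18 = 0.2\overline{7}$.
The function returns full precision; `printed_frequency()` reproduces the
reference table's printed two-decimal convention, which truncates toward
zero (5/18 prints as 0.27). `classify_two_strategy_game()` applies the
standard orderings (prisoner's dilemma $T > R > P > S$, etc.), reporting
ties as ambiguous.

`moran_fixation_probability()` uses self-excluded expected payoffs and
the map $f = 1 - w + w\pi$; the default intensity $w = 1$ uses payoffs
(positive food counts) directly as fitness, mirroring the
fecundity-proportional robot loop. It is validated against direct
absorption probabilities of the explicit birth–death chain and against
the classical constant-fitness closed form.

`simulate_strategy_dynamics()` iterates Wright–Fisher resampling on
strategy counts (matching the robot loop's generational structure; the
Moran process is used only where it is named, i.e. fixation screening)
with expected payoffs under random pairing excluding self and symmetric
mutation at rate `mu` between strategies — the "mutational distance 1"
idealization. Mutation rates are not specified at either scale; the
defaults $10^{-2}$ at $N = 100$ and $10^{-3}$ at $N = 10^4$ produce the
two characteristic regimes at desk scale: cycling between Selfish-majority
and Reciprocator-majority states in small populations, and a stable
Reciprocator-majority polymorphism in large ones. Simulations start from
an equal split unless counts are given. `occupancy_histogram()` bins
post-initial frequencies on a square grid over two chosen strategy axes.

# Problem sizes used in validation

The packaged tests validate at reduced scale, chosen so the full suite
runs on a single CPU in minutes while leaving each check statistically
meaningful:

* Helped-release speed-up: 10,000 Monte-Carlo episodes per arm, 3-SE
  bands around the geometric means 2000 and 400 and the ratio 5.
* Estimator recovery: 200 replicates per rate, 95% profile intervals.
* Relatedness contrast: $N = 20$, 100 generations, 2000-step evaluations,
  5 runs per pairing condition, final helping rate averaged over a
  population sample per run, one-sided rank test. This is a severe
  scale-down — a 2000-step evaluation contains about one stuck episode,
  and a mean episode outlasts the truncated evaluation, so the fitness
  signal of helping is far weaker than at full scale; the check is
  correspondingly the most fragile in the suite.
* Strategy dynamics: 50,000 generations at $N = 100$ and $N = 10^4$.

What passing these tests does and does not show: the synthetic conditions
exercise the full mechanistic chain (sensing, control, physics, selection,
estimation) under the reference rates, but they do not reproduce
full-scale evolved statistics — published helping-rate magnitudes from
2000-generation campaigns, bred-genotype payoff values, or mutational
distances of reference strategies — which require orders of magnitude more
compute and are explicitly out of scope.

# Known limitations

* Two robots and two food sources are the tested configuration; counts
  are configurable but untested beyond the reference values.
* Whether stuck onset should relocate the robot is an open reading of the
  source description; stuck-in-place is implemented.
* Proximity sensors do not detect food; only the partner is solid.
* No lifetime learning, recurrence, or plasticity in the controller; no
  overlapping generations in the main loop (the steady-state GA lives in
  the breeding module).
* The helping-rate estimator is bounded above by the helped release
  hazard; it measures release behavior, not approach propensity.
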