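# reciprobot

Evolutionary robotics simulations of helping and reciprocity.

## The problem

Game-theoretic models predict that reciprocal cooperation — helping
conditioned on a partner's past helping — should invade and persist in
populations of defectors, yet reciprocity is strikingly rare in nature.
One candidate explanation is mechanistic: in models, a reciprocating
strategy is one mutation away from a defecting one, but when behavior must
be produced by an actual control system, a working reciprocator may require
many coordinated mutations, and no directional selection pressure exists
until conditional helpers are already common (a bootstrapping problem).

`reciprobot` implements an embodied test bed for this question, for
researchers in social evolution and evolutionary robotics. Pairs of
simulated robots with three-layer feed-forward neural controllers (1 bias +
17 sensory inputs, 9 hidden, 2 wheel outputs; 182 connection weights, 191
with the optional memory neuron) forage on a 1 m × 1 m toroidal arena.
Robots become stuck at hazard $5\times10^{-4}$ per 100 ms step, self-release
at the same hazard, or five times faster while their partner stays within
1 cm — helping, which costs foraging time. A memory input neuron reports
the fraction of past stuck episodes that ended with help, enabling
reciprocity. Controller weights are encoded 8 bits each in a bitstring
genotype; populations evolve by a Wright–Fisher process on fecundity (food
gathered over 5 evaluations) with per-bit mutation $10^{-2}$ and
controllable partner relatedness ($R = 0$, $R = 1$, or mixed).

Around the core simulation the package provides:

* **Behavioral assays** — 100-trial standardized helping assays with a
  censored-geometric maximum-likelihood helping-rate estimator
  $\hat h = k / (\sum_i t_i + (n-k)T)$, chance-level (invisible-partner)
  controls, and mood assays with the memory input clamped;
* **Artificial selection** — breeding regimes for reference strategies
  (Selfish, Helper, conditional-helping Reciprocator, and a
  similarity-penalized regime for mutational-distance measurement), with
  Moran fixation-probability screening of candidates;
* **Game dynamics** — analysis of measured payoff matrices: game
  classification ($T > R > P > S$ etc.), invasion thresholds from the
  payoff-equality condition, frequency-dependent Moran fixation
  probabilities, and finite-population Wright–Fisher dynamics of two or
  more strategies with mutation.

## Worked example

```r
library(reciprobot)

# the packaged measured payoff matrix (row player's mean food count)
m <- reference_payoffs()

invasion_threshold(m, "Reciprocator", "Selfish")
#> [1] 0.2777778            # barrier frequency; prints as 0.27 at 2 decimals

classify_two_strategy_game(m, cooperator = "Helper", defector = "Selfish")
#> [1] "prisoners_dilemma"  # 205 > 198 > 152 > 132

# a single Reciprocator among 99 Selfish residents fixes with probability
moran_fixation_probability(
  m$payoffs[c("Reciprocator", "Selfish"), c("Reciprocator", "Selfish")],
  N = 100)
#> [1] 0.01003658           # ~1/N: no selection for rare reciprocity

# large-population dynamics of the three strategies
set.seed(42)
tr <- simulate_strategy_dynamics(m, N = 10000L, mu = 1e-3,
                                 generations = 20000L)
round(colMeans(tr$counts[-1, ]) / 10000, 3)
#>      Selfish       Helper Reciprocator
#>        0.011        0.280        0.708
```

Rare Reciprocators cannot invade (fixation ≈ 1/N below the 0.28 barrier),
yet once common they dominate a stable polymorphism — reciprocity is
adaptive but unreachable by rare mutants, which is the invasion-barrier
signature the embodied simulations investigate.

Running the embodied layer directly:

```r
set.seed(7)
g <- random_genome()                       # random 182-weight controller
run_evaluation(g, g, config = arena_config(eval_steps = 5000L))
#> Evaluation: 5000 steps, food 6/8, helping given 1/0

helping_assay(g, config = assay_config(n_trials = 50L))
#> Assay: 2/50 trials released; helping rate 4.072e-05 per step
```

Evolutionary experiments (`run_experiment()`), breeding
(`breed_reciprocator()`, `breed_unconditional()`, `fixation_screen()`) and
the command-line front end (`inst/cli/reciprobot.R`, subcommands `evolve`,
`assay`, `payoffs`, `dynamics`, `breed`) are documented in the help pages
and the methods vignette (`vignettes/reciprobot-methods.Rmd`).

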