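#' Breeding (artificial-selection) configuration
#'
#' Modified fitness regimes used to breed reference strategies:
#' * `"reciprocator"` — each individual's memory input is clamped per
#'   evaluation to a fair-coin value; fecundity is food plus
#'   `help_bonus` per release event when the clamp is 1, food minus the
#'   bonus per release when it is 0 (selects conditional helping).
#' * `"selfish"` — plain unrelated-condition evolution; the
#'   highest-fecundity final individual is the Selfish reference.
#' * `"helper"` — fecundity is food plus `help_bonus` per release event
#'   unconditionally.
#' * `"reciprocator_near_selfish"` — the reciprocator score minus
#'   `similarity_weight` times the weight-locus distance to a reference
#'   genome (measures how few loci must change to turn a defector into a
#'   reciprocator).
#'
#' @param regime one of the four regimes above.
#' @param population_size population size (200 in the reference
#'   reciprocator campaign).
#' @param generations generations / steady-state cycles (1500 in the
#'   reference campaign).
#' @param help_bonus fitness units per release event; the default 1 puts
#'   one helping event on the same scale as one food item.
#' @param similarity_weight penalty per differing weight locus
#'   (`reciprocator_near_selfish` only).
#' @param reference_genome reference `genome` for the similarity penalty.
#' @param ga `"steady_state"` (each cycle replaces the worst
#'   `replace_frac` of the population with mutated copies of uniformly
#'   drawn survivors) or `"wright_fisher"`.
#' @param replace_frac fraction replaced per steady-state cycle.
#' @param evaluations_per_robot,per_bit_mutation,has_memory,arena as in
#'   [evolution_config()].
#' @return An object of class `breeding_config`.
#' @export
breeding_config <- function(regime = c("reciprocator", "selfish", "helper",
                                       "reciprocator_near_selfish"),
                            population_size = 200L, generations = 1500L,
                            help_bonus = 1, similarity_weight = 0.1,
                            reference_genome = NULL,
                            ga = c("steady_state", "wright_fisher"),
                            replace_frac = 0.1,
                            evaluations_per_robot = 5L,
                            per_bit_mutation = 1e-2, has_memory = NULL,
                            arena = arena_config()) {
  regime <- match.arg(regime)
  ga <- match.arg(ga)
  if (is.null(has_memory))
    has_memory <- regime %in% c("reciprocator", "reciprocator_near_selfish")
  if (regime %in% c("reciprocator", "reciprocator_near_selfish") &&
      !has_memory)
    stop("topology error: this regime requires the memory neuron")
  if (regime == "reciprocator_near_selfish" && is.null(reference_genome))
    stop("reference_genome required for the similarity-penalized regime")
  if (population_size < 2L) stop("population_size must be >= 2")
  structure(list(regime = regime,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 help_bonus = help_bonus,
                 similarity_weight = similarity_weight,
                 reference_genome = reference_genome, ga = ga,
                 replace_frac = replace_frac,
                 evaluations_per_robot = as.integer(evaluations_per_robot),
                 per_bit_mutation = per_bit_mutation,
                 has_memory = has_memory, arena = arena),
            class = "breeding_config")
}

# fitness of every individual under the breeding regime; clamps are drawn
# per evaluation for each robot independently (fair coin) in the
# conditional regimes
breeding_scores <- function(population, config) {
  n <- length(population)
  topo <- network_topology(config$has_memory)
  weights <- lapply(population, genome_weights, topology = topo)
  conditional <- config$regime %in% c("reciprocator",
                                      "reciprocator_near_selfish")
  score <- numeric(n)
  food <- numeric(n)
  for (round in seq_len(config$evaluations_per_robot)) {
    partners <- pair_population(population, "unrelated")
    for (i in seq_len(n)) {
      clamp_focal <- if (conditional) as.numeric(stats::runif(1) < 0.5)
                     else NA_real_
      clamp_partner <- if (conditional) as.numeric(stats::runif(1) < 0.5)
                       else NA_real_
      res <- sim_run(weights[[i]], weights[[partners[i]]],
                     topo$has_memory, unclass(config$arena),
                     config$arena$eval_steps, 0L, clamp_focal,
                     clamp_partner, FALSE, FALSE, NULL)
      food[i] <- food[i] + res$food_counts[1L]
      releases <- res$helping_given[1L]
      score[i] <- score[i] + res$food_counts[1L] +
        (if (config$regime == "helper") config$help_bonus * releases
         else if (conditional)
           (if (clamp_focal == 1) config$help_bonus else
              -config$help_bonus) * releases
         else 0)
    }
  }
  if (config$regime == "reciprocator_near_selfish") {
    dist <- vapply(population, weight_distance,
                   b = config$reference_genome, integer(1))
    score <- score - config$similarity_weight * dist
  }
  attr(score, "food") <- food
  score
}

run_breeding_ga <- function(config, initial_population = NULL,
                            verbose = FALSE) {
  spec <- decoding_spec(has_memory = config$has_memory)
  pop <- if (is.null(initial_population))
    replicate(config$population_size, random_genome(spec),
              simplify = FALSE)
  else initial_population
  n <- length(pop)
  report <- data.frame(generation = integer(0), best_score = numeric(0),
                       mean_score = numeric(0))
  score <- breeding_scores(pop, config)
  for (g in seq_len(config$generations)) {
    if (config$ga == "steady_state") {
      k <- max(1L, floor(config$replace_frac * n))
      worst <- order(score)[seq_len(k)]
      survivors <- setdiff(seq_len(n), worst)
      parents <- survivors[sample.int(length(survivors), k, replace = TRUE)]
      for (j in seq_len(k))
        pop[[worst[j]]] <- mutate_genome(pop[[parents[j]]],
                                         config$per_bit_mutation)
      score <- breeding_scores(pop, config)
    } else {
      shifted <- score - min(score)
      prob <- if (sum(shifted) > 0) shifted else rep(1, n)
      parents <- sample.int(n, n, replace = TRUE, prob = prob)
      pop <- lapply(parents, function(p)
        mutate_genome(pop[[p]], config$per_bit_mutation))
      score <- breeding_scores(pop, config)
    }
    report[nrow(report) + 1L, ] <- list(g, max(score), mean(score))
    if (verbose)
      message(sprintf("breeding cycle %d/%d: best %.2f mean %.2f", g,
                      config$generations, max(score), mean(score)))
  }
  list(population = pop, scores = score, report = report)
}

#' Breed conditional helpers (Reciprocator candidates)
#'
#' Runs the conditional-helping selection regime and returns the final
#' population as candidate genomes, with their final scores and the
#' per-cycle breeding report attached as attributes.
#'
#' @param config a [breeding_config()] with regime `"reciprocator"`.
#' @param initial_population optional starting genomes.
#' @param verbose print progress?
#' @return List of candidate `genome` objects (attributes `scores`,
#'   `report`).
#' @export
breed_reciprocator <- function(config = breeding_config("reciprocator"),
                               initial_population = NULL,
                               verbose = FALSE) {
  if (!config$regime %in% c("reciprocator", "reciprocator_near_selfish"))
    stop("config regime must be a conditional-helping regime")
  out <- run_breeding_ga(config, initial_population, verbose)
  candidates <- out$population
  attr(candidates, "scores") <- out$scores
  attr(candidates, "report") <- out$report
  candidates
}

#' Breed an unconditional reference strategy (Selfish or Helper)
#'
#' Selfish: plain unrelated-condition evolution, returning the
#' highest-scoring final individual.  Helper: fecundity is food plus
#' `help_bonus` per release event; the returned individual is the
#' highest-scoring one whose assayed helping rate reaches
#' `helper_threshold` times its own chance-level rate (falling back to the
#' highest-scoring individual, with a warning, if none qualifies).
#'
#' @param config a [breeding_config()] with regime `"selfish"` or
#'   `"helper"`.
#' @param helper_threshold required ratio of assayed to chance-level
#'   helping rate for a Helper.
#' @param assay an [assay_config()] for the acceptance check.
#' @param initial_population optional starting genomes.
#' @param verbose print progress?
#' @return A single `genome` (attribute `report`).
#' @export
breed_unconditional <- function(config = breeding_config("selfish"),
                                helper_threshold = 5,
                                assay = assay_config(),
                                initial_population = NULL,
                                verbose = FALSE) {
  if (!config$regime %in% c("selfish", "helper"))
    stop("config regime must be selfish or helper")
  out <- run_breeding_ga(config, initial_population, verbose)
  ord <- order(out$scores, decreasing = TRUE)
  topo <- network_topology(config$has_memory)
  pick <- NULL
  if (config$regime == "helper") {
    for (i in ord) {
      g <- out$population[[i]]
      h <- helping_assay(g, topo, assay, config$arena)$helping_rate
      ch <- chance_level_assay(g, topo, assay, config$arena)$helping_rate
      if (h >= helper_threshold * max(ch, .Machine$double.eps)) {
        pick <- g; break
      }
    }
    if (is.null(pick)) {
      warning("no bred individual passed the helper assay threshold; ",
              "returning the highest-scoring one")
      pick <- out$population[[ord[1L]]]
    }
  } else {
    pick <- out$population[[ord[1L]]]
  }
  attr(pick, "report") <- out$report
  pick
}

#' Breed conditional helpers near a reference genotype
#'
#' The similarity-penalized regime: conditional-helping score minus
#' `similarity_weight` per weight locus differing from the reference
#' (used to measure the minimum mutational distance from a Selfish
#' defector to a working reciprocator).
#'
#' @param config a [breeding_config()] with regime
#'   `"reciprocator_near_selfish"` and a `reference_genome`.
#' @inheritParams breed_reciprocator
#' @return List of `genome`s with attribute `distances` (weight-locus
#'   distances to the reference) plus `scores`/`report`.
#' @export
breed_near_reference <- function(config, initial_population = NULL,
                                 verbose = FALSE) {
  if (config$regime != "reciprocator_near_selfish")
    stop("config regime must be reciprocator_near_selfish")
  candidates <- breed_reciprocator(config, initial_population, verbose)
  attr(candidates, "distances") <-
    vapply(candidates, weight_distance, b = config$reference_genome,
           integer(1))
  candidates
}

#' Moran fixation screening of candidate genotypes
#'
#' For each candidate, measures the 2x2 payoff matrix
#' {candidate, reference} and computes the fixation probability of a
#' single candidate copy in a resident population of N - 1 reference
#' players under the frequency-dependent Moran process.  Candidates are
#' returned sorted by fixation probability, descending.
#'
#' @param candidates list of `genome` objects.
#' @param reference reference `genome` (e.g. the bred Selfish strategy).
#' @param N resident population size.
#' @param n_interactions evaluations per ordered pair for the payoff
#'   measurement (100 by default; 1000 reproduces the reference payoff
#'   protocol).
#' @param topology,arena simulation setup shared by all measurements.
#' @param intensity Moran selection intensity.
#' @param payoff_fn function `(genome_row, genome_col) -> list(mean=...)`;
#'   defaults to [measure_payoff()].  Injectable for testing.
#' @return Data frame with columns `candidate` (index),
#'   `fixation_probability`, sorted descending; the payoff matrices are
#'   attached as attribute `payoffs`.
#' @export
fixation_screen <- function(candidates, reference, N = 100L,
                            n_interactions = 100L,
                            topology = network_topology(TRUE),
                            arena = arena_config(), intensity = 1,
                            payoff_fn = NULL) {
  if (length(candidates) == 0L) stop("no candidates to screen")
  if (is.null(payoff_fn))
    payoff_fn <- function(a, b)
      measure_payoff(a, b, n_interactions, topology, arena)
  mats <- vector("list", length(candidates))
  rho <- vapply(seq_along(candidates), function(i) {
    g <- candidates[[i]]
    m <- matrix(c(payoff_fn(g, g)$mean, payoff_fn(g, reference)$mean,
                  payoff_fn(reference, g)$mean,
                  payoff_fn(reference, reference)$mean),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("candidate", "reference"),
                                c("candidate", "reference")))
    mats[[i]] <<- m
    moran_fixation_probability(payoff_matrix(m), N, intensity,
                               invader = "candidate",
                               resident = "reference")
  }, numeric(1))
  out <- data.frame(candidate = seq_along(candidates),
                    fixation_probability = rho)
  out <- out[order(-out$fixation_probability), ]
  rownames(out) <- NULL
  attr(out, "payoffs") <- mats
  out
}
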