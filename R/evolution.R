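#' Evolutionary experiment configuration
#'
#' The generational Wright-Fisher loop: 100 robots, each evaluated 5 times
#' as the focal individual; fecundity is the focal's own food total over
#' those evaluations; the next generation is sampled with replacement in
#' proportion to fecundity and mutated at 1e-2 per bit.  Pairing controls
#' genetic relatedness: `"related"` pairs every focal with a clone of
#' itself (R = 1), `"unrelated"` with a uniform draw from the other N - 1
#' genomes (R = 0), and `"half_related"` with a clone with probability 1/2.
#'
#' @param population_size number of robots N.
#' @param evaluations_per_robot focal evaluations per robot per
#'   generation.
#' @param pairing one of `"unrelated"`, `"related"`, `"half_related"`, or
#'   a data frame with columns `pairing` and `generations` giving a phase
#'   schedule (e.g. the kin-recognition scenario: half_related then
#'   unrelated).
#' @param has_memory logical; evolve robots with the memory neuron?
#' @param generations number of generations (ignored when `pairing` is a
#'   schedule, whose phase lengths then apply).
#' @param per_bit_mutation per-bit mutation probability.
#' @param injection_genotype optional `genome` injected into offspring.
#' @param injection_prob per-offspring injection probability per
#'   generation (1e-2 puts in ~1 individual per generation at N = 100).
#' @param assay_every run helping assays every this many generations
#'   (0 disables them).
#' @param assay_sample assayed individuals: the best-fecundity robot plus
#'   this many uniformly sampled others.
#' @param assay an [assay_config()] used for the periodic assays.
#' @param arena an [arena_config()].
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 100L,
                             evaluations_per_robot = 5L,
                             pairing = "unrelated", has_memory = FALSE,
                             generations = 500L, per_bit_mutation = 1e-2,
                             injection_genotype = NULL,
                             injection_prob = 1e-2, assay_every = 25L,
                             assay_sample = 10L,
                             assay = assay_config(),
                             arena = arena_config()) {
  if (population_size < 2L) stop("population_size must be >= 2")
  if (per_bit_mutation < 0 || per_bit_mutation > 1 ||
      injection_prob < 0 || injection_prob > 1)
    stop("probabilities must be in [0, 1]")
  if (is.character(pairing)) {
    pairing <- match.arg(pairing, c("unrelated", "related", "half_related"))
    schedule <- data.frame(pairing = pairing,
                           generations = as.integer(generations))
  } else {
    schedule <- as.data.frame(pairing)
    stopifnot(all(c("pairing", "generations") %in% names(schedule)))
    schedule$pairing <- vapply(schedule$pairing, match.arg, "",
                               c("unrelated", "related", "half_related"))
    schedule$generations <- as.integer(schedule$generations)
  }
  structure(list(population_size = as.integer(population_size),
                 evaluations_per_robot = as.integer(evaluations_per_robot),
                 schedule = schedule, has_memory = has_memory,
                 per_bit_mutation = per_bit_mutation,
                 injection_genotype = injection_genotype,
                 injection_prob = injection_prob,
                 assay_every = as.integer(assay_every),
                 assay_sample = as.integer(assay_sample),
                 assay = assay, arena = arena),
            class = "evolution_config")
}

#' @export
print.evolution_config <- function(x, ...) {
  cat(sprintf("Evolution: N=%d, %d evals/robot, mutation %g/bit, %s%s\n",
              x$population_size, x$evaluations_per_robot,
              x$per_bit_mutation,
              paste(sprintf("%s x%d", x$schedule$pairing,
                            x$schedule$generations), collapse = " then "),
              if (x$has_memory) " [memory]" else ""))
  invisible(x)
}

#' Partner assignment for one evaluation round
#'
#' @param population list of `genome` objects.
#' @param pairing `"unrelated"`, `"related"` or `"half_related"`.
#' @return Integer vector: for each focal robot, the index of its partner
#'   in `population`; the focal's own index means clone pairing.
#' @export
pair_population <- function(population, pairing = "unrelated") {
  n <- length(population)
  if (n < 2L) stop("population must have at least 2 members")
  pairing <- match.arg(pairing, c("unrelated", "related", "half_related"))
  sample_other <- function(i) {
    j <- sample.int(n - 1L, 1L)
    if (j >= i) j + 1L else j
  }
  vapply(seq_len(n), function(i) {
    switch(pairing,
           related = i,
           unrelated = sample_other(i),
           half_related = if (stats::runif(1) < 0.5) i else sample_other(i))
  }, integer(1))
}

#' Evaluate a population's fecundities
#'
#' Each robot is the focal individual in exactly
#' `evaluations_per_robot` evaluations; its fecundity is its own food
#' total across them.  Partners behave fully but their food in a focal's
#' evaluations is credited to no one (each robot is credited only in its
#' own focal evaluations).
#'
#' @param population list of `genome` objects.
#' @param config an [evolution_config()].
#' @param pairing pairing condition for this generation.
#' @return Numeric fecundity vector (attribute `helping_given` carries the
#'   focal robots' release-event counts, used by breeding regimes).
#' @export
evaluate_population <- function(population, config,
                                pairing = config$schedule$pairing[1L]) {
  n <- length(population)
  topo <- network_topology(config$has_memory)
  weights <- lapply(population, genome_weights, topology = topo)
  fec <- numeric(n)
  helps <- integer(n)
  for (round in seq_len(config$evaluations_per_robot)) {
    partners <- pair_population(population, pairing)
    for (i in seq_len(n)) {
      res <- sim_run(weights[[i]], weights[[partners[i]]],
                     topo$has_memory, unclass(config$arena),
                     config$arena$eval_steps, 0L, NA_real_, NA_real_,
                     FALSE, FALSE, NULL)
      fec[i] <- fec[i] + res$food_counts[1L]
      helps[i] <- helps[i] + res$helping_given[1L]
    }
  }
  attr(fec, "helping_given") <- helps
  fec
}

#' Sample the next generation (Wright-Fisher)
#'
#' Draws N offspring i.i.d. with probability proportional to fecundity
#' (uniformly if every fecundity is zero, which keeps the process defined
#' at initialization), mutates each offspring, then independently replaces
#' each by the injection genotype with probability `injection_prob` when
#' one is configured.
#'
#' @param population list of `genome` objects.
#' @param fecundities non-negative numeric vector, one per member.
#' @param config an [evolution_config()].
#' @return The offspring population (attribute `parents` gives each
#'   offspring's parent index; `NA` marks injected individuals).
#' @export
next_generation <- function(population, fecundities, config) {
  n <- length(population)
  if (length(fecundities) != n) stop("fecundity vector length mismatch")
  if (any(fecundities < 0)) stop("invariant violation: negative fecundity")
  prob <- if (sum(fecundities) > 0) fecundities else rep(1, n)
  parents <- sample.int(n, n, replace = TRUE, prob = prob)
  offspring <- lapply(parents, function(p)
    mutate_genome(population[[p]], config$per_bit_mutation))
  if (!is.null(config$injection_genotype) && config$injection_prob > 0) {
    inject <- stats::runif(n) < config$injection_prob
    offspring[inject] <- list(config$injection_genotype)
    parents[inject] <- NA_integer_
  }
  attr(offspring, "parents") <- parents
  offspring
}

#' Run an evolutionary experiment
#'
#' Initializes a population of random genomes (or takes a provided seed
#' population, e.g. all-Helper), then loops evaluate -> record stats ->
#' reproduce through the pairing schedule.  Fully reproducible for a fixed
#' RNG seed set before the call.
#'
#' @param config an [evolution_config()].
#' @param initial_population optional list of `genome` objects of length
#'   `population_size`.
#' @param verbose print per-generation progress to stderr?
#' @return An object of class `evolution_run`: `stats` (data frame with
#'   generation, pairing, mean/sd fecundity and mean assayed helping
#'   rate), and `population` (final genomes).
#' @export
run_experiment <- function(config, initial_population = NULL,
                           verbose = FALSE) {
  spec <- decoding_spec(has_memory = config$has_memory)
  pop <- if (is.null(initial_population)) {
    replicate(config$population_size, random_genome(spec),
              simplify = FALSE)
  } else {
    stopifnot(length(initial_population) == config$population_size)
    initial_population
  }
  total_gen <- sum(config$schedule$generations)
  stats_df <- data.frame(generation = integer(0), pairing = character(0),
                         mean_fecundity = numeric(0),
                         fecundity_sd = numeric(0),
                         mean_helping_rate = numeric(0))
  gen <- 0L
  for (phase in seq_len(nrow(config$schedule))) {
    pairing <- config$schedule$pairing[phase]
    for (g in seq_len(config$schedule$generations[phase])) {
      gen <- gen + 1L
      fec <- evaluate_population(pop, config, pairing)
      hr <- NA_real_
      if (config$assay_every > 0L && gen %% config$assay_every == 0L)
        hr <- mean(assay_population(pop, fec, config))
      stats_df[nrow(stats_df) + 1L, ] <-
        list(gen, pairing, mean(fec), stats::sd(fec), hr)
      if (verbose)
        message(sprintf("gen %d/%d [%s]: mean fecundity %.2f", gen,
                        total_gen, pairing, mean(fec)))
      pop <- next_generation(pop, fec, config)
    }
  }
  structure(list(stats = stats_df, population = pop, config = config),
            class = "evolution_run")
}

#' Helping rates of a population sample
#'
#' Assays the best-fecundity individual plus `assay_sample` uniformly
#' sampled others (the periodic measurement cadence of the evolutionary
#' runs).
#'
#' @param population list of genomes.
#' @param fecundities fecundity vector (best individual taken from it);
#'   may be `NULL` to assay a pure uniform sample.
#' @param config an [evolution_config()].
#' @return Numeric vector of ML helping rates of the assayed individuals.
#' @export
assay_population <- function(population, fecundities, config) {
  n <- length(population)
  idx <- integer(0)
  if (!is.null(fecundities)) idx <- which.max(fecundities)
  k <- min(config$assay_sample, n)
  idx <- unique(c(idx, sample.int(n, k)))
  topo <- network_topology(config$has_memory)
  vapply(idx, function(i)
    helping_assay(population[[i]], topo, config$assay,
                  config$arena)$helping_rate, numeric(1))
}

#' @export
print.evolution_run <- function(x, ...) {
  n <- nrow(x$stats)
  cat(sprintf("Evolution run: %d generations, final mean fecundity %.2f\n",
              n, if (n) x$stats$mean_fecundity[n] else NA))
  invisible(x)
}

#' Write the per-generation run log as TSV
#'
#' @param run an `evolution_run`.
#' @param path output path.
#' @export
write_run_log <- function(run, path) {
  utils::write.table(run$stats, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
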