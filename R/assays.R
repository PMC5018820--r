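#' Behavioral assay configuration
#'
#' The standardized helping assay: the focal robot is placed 100
#' independent times at a random position with two food sources and one
#' stuck partner that cannot free itself, and tracked for 1000 steps per
#' trial.  The release hazard is the helped hazard
#' (`p_self_release * help_multiplier`) whenever the focal sits within
#' helping range, and zero otherwise.
#'
#' @param n_trials number of independent trials.
#' @param trial_steps steps per trial (censoring time).
#' @param partner_visible if `FALSE`, the partner contributes nothing to
#'   the focal's sensors while remaining physically present and releasable
#'   (the chance-level condition).
#' @param memory_clamp optional 0 or 1 clamping the focal's memory input
#'   for every step (mood assays); `NA` leaves the memory neuron dynamic.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(n_trials = 100L, trial_steps = 1000L,
                         partner_visible = TRUE, memory_clamp = NA_real_) {
  if (n_trials < 1L || trial_steps < 1L)
    stop("assay config: n_trials and trial_steps must be >= 1")
  if (!is.na(memory_clamp) && !memory_clamp %in% c(0, 1))
    stop("assay config: memory_clamp must be NA, 0 or 1")
  structure(list(n_trials = as.integer(n_trials),
                 trial_steps = as.integer(trial_steps),
                 partner_visible = isTRUE(partner_visible),
                 memory_clamp = as.numeric(memory_clamp)),
            class = "assay_config")
}

#' Helping assay
#'
#' Runs `n_trials` standardized trials and estimates the focal's helping
#' rate — its per-step probability of releasing a stuck partner — by
#' maximum likelihood under the censored-geometric model
#' (see [estimate_helping_rate()]).
#'
#' @param genome focal `genome`.
#' @param topology a [network_topology()] matching the genome.
#' @param config an [assay_config()].
#' @param arena an [arena_config()]; `p_stuck` is ignored (the focal never
#'   sticks during an assay).
#' @param partner_genome genome used for the stuck partner's body; it
#'   never moves, so only its presence matters.  Defaults to the focal.
#' @return An object of class `assay_result` with fields `released`,
#'   `release_times`, `n_trials`, `trial_steps` and `helping_rate`.
#' @export
helping_assay <- function(genome, topology = network_topology(),
                          config = assay_config(),
                          arena = arena_config(),
                          partner_genome = genome) {
  w <- genome_weights(genome, topology)
  wp <- genome_weights(partner_genome, topology)
  times <- integer(0)
  for (i in seq_len(config$n_trials)) {
    res <- sim_run(w, wp, topology$has_memory, unclass(arena),
                   config$trial_steps, 1L, config$memory_clamp, NA_real_,
                   !config$partner_visible, FALSE, NULL)
    if (!is.na(res$release_step)) times <- c(times, res$release_step)
  }
  new_assay_result(times, config)
}

new_assay_result <- function(release_times, config) {
  r <- structure(list(released = length(release_times),
                      release_times = as.integer(release_times),
                      n_trials = config$n_trials,
                      trial_steps = config$trial_steps,
                      helping_rate = NA_real_),
                 class = "assay_result")
  r$helping_rate <- estimate_helping_rate(r)
  r
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("Assay: %d/%d trials released; helping rate %.4g per step\n",
              x$released, x$n_trials, x$helping_rate))
  invisible(x)
}

#' Chance-level helping assay
#'
#' Identical to [helping_assay()] except the partner is invisible to every
#' sensory channel, so releases occur only when the focal happens to pass
#' within helping range by chance.
#'
#' @inheritParams helping_assay
#' @export
chance_level_assay <- function(genome, topology = network_topology(),
                               config = assay_config(),
                               arena = arena_config(),
                               partner_genome = genome) {
  config$partner_visible <- FALSE
  helping_assay(genome, topology, config, arena, partner_genome)
}

#' Mood-clamped helping assay
#'
#' Helping assay with the focal's memory input held at `clamp` for every
#' step: clamp 1 is "help in a good mood" (partner has always helped),
#' clamp 0 "help in a bad mood".
#'
#' @inheritParams helping_assay
#' @param clamp 0 or 1.
#' @export
mood_assay <- function(genome, clamp, topology = network_topology(TRUE),
                       config = assay_config(), arena = arena_config(),
                       partner_genome = genome) {
  if (!topology$has_memory)
    stop("topology error: mood assay requires a memory topology")
  if (!clamp %in% c(0, 1)) stop("clamp must be 0 or 1")
  config$memory_clamp <- as.numeric(clamp)
  helping_assay(genome, topology, config, arena, partner_genome)
}

#' Maximum-likelihood helping rate
#'
#' Model: in each trial the focal releases its partner at step `t` with
#' probability `(1 - h)^(t-1) h`, or the trial is censored at
#' `trial_steps`.  The released proportion and the release times are the
#' sufficient statistics, and the MLE has the closed form
#' `h = k / (sum(t) + (n - k) * T)` with `k` releases out of `n` trials
#' censored at `T`.
#'
#' @param result an `assay_result` (or a list with fields
#'   `release_times`, `n_trials`, `trial_steps`).
#' @return The estimated helping rate (probability per step).
#' @export
estimate_helping_rate <- function(result) {
  k <- length(result$release_times)
  n <- result$n_trials
  if (n < 1L) stop("undefined estimate: no trials")
  if (k == 0L) return(0)
  denom <- sum(result$release_times) + (n - k) * result$trial_steps
  k / denom
}

#' Censored-geometric log-likelihood of a helping rate
#'
#' @param h helping rate(s) in `(0, 1)`.
#' @param result as in [estimate_helping_rate()].
#' @return Log-likelihood value(s).
#' @export
helping_rate_loglik <- function(h, result) {
  k <- length(result$release_times)
  n <- result$n_trials
  st <- sum(result$release_times)
  m <- st - k + (n - k) * result$trial_steps
  # 0 * log(0) terms are exact zeros (degenerate all-released / none data)
  t1 <- if (k == 0L) 0 else k * log(h)
  t2 <- if (m == 0) 0 else m * log1p(-h)
  t1 + t2
}

#' Profile-likelihood confidence interval for the helping rate
#'
#' Inverts the likelihood-ratio statistic at the chi-squared(1) cutoff.
#'
#' @param result assay result as in [estimate_helping_rate()].
#' @param level confidence level.
#' @return Length-2 vector (lower, upper).
#' @export
helping_rate_ci <- function(result, level = 0.95) {
  hhat <- estimate_helping_rate(result)
  cut <- stats::qchisq(level, df = 1) / 2
  k <- length(result$release_times)
  if (k == 0L) {
    # all censored: L(h) = (1-h)^(nT); lower bound 0
    nT <- result$n_trials * result$trial_steps
    return(c(0, 1 - exp(-cut / nT)))
  }
  llmax <- helping_rate_loglik(hhat, result)
  f <- function(h) helping_rate_loglik(h, result) - llmax + cut
  eps <- 1e-14
  lo <- if (f(eps) > 0) 0 else
    stats::uniroot(f, c(eps, hhat), tol = 1e-14)$root
  hi_end <- 1 - eps
  hi <- if (f(hi_end) > 0) 1 else
    stats::uniroot(f, c(hhat, hi_end), tol = 1e-14)$root
  c(lo, hi)
}

#' Simulate censored-geometric assay data
#'
#' Draws release outcomes directly from the assay's statistical model
#' (not through the arena) — used for estimator-recovery checks.
#'
#' @param h true helping rate.
#' @param config an [assay_config()].
#' @return An `assay_result`.
#' @export
simulate_assay_data <- function(h, config = assay_config()) {
  t <- stats::rgeom(config$n_trials, h) + 1L
  new_assay_result(t[t <= config$trial_steps], config)
}

#' Mean payoff of one genotype against another
#'
#' Simulates `n_interactions` full evaluations of the ordered pair and
#' returns the mean food count of the row (first) robot, the measurement
#' behind entries of the strategy payoff matrix.
#'
#' @param genome_row,genome_col `genome` objects.
#' @param n_interactions number of evaluations.
#' @param topology a [network_topology()].
#' @param arena an [arena_config()].
#' @return List with `mean`, `se` and the per-interaction `payoffs`.
#' @export
measure_payoff <- function(genome_row, genome_col, n_interactions = 1000L,
                           topology = network_topology(),
                           arena = arena_config()) {
  wr <- genome_weights(genome_row, topology)
  wc <- genome_weights(genome_col, topology)
  payoffs <- vapply(seq_len(n_interactions), function(i) {
    res <- sim_run(wr, wc, topology$has_memory, unclass(arena),
                   arena$eval_steps, 0L, NA_real_, NA_real_, FALSE, FALSE,
                   NULL)
    as.numeric(res$food_counts[1L])
  }, numeric(1))
  list(mean = mean(payoffs),
       se = stats::sd(payoffs) / sqrt(n_interactions),
       payoffs = payoffs)
}

#' Assemble a payoff matrix from genotypes
#'
#' Measures every ordered pair among the named genotypes with
#' [measure_payoff()] and returns a [payoff_matrix()].
#'
#' @param genomes named list of `genome` objects.
#' @inheritParams measure_payoff
#' @export
measure_payoff_matrix <- function(genomes, n_interactions = 1000L,
                                  topology = network_topology(),
                                  arena = arena_config()) {
  nm <- names(genomes)
  if (is.null(nm) || any(nm == "")) stop("genomes must be a named list")
  n <- length(genomes)
  p <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  se <- p
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m <- measure_payoff(genomes[[i]], genomes[[j]], n_interactions,
                        topology, arena)
    p[i, j] <- m$mean; se[i, j] <- m$se
  }
  payoff_matrix(p, standard_errors = se)
}

#' Write an assay report as TSV
#'
#' One row per trial (trial, released, release_step) with a trailing
#' comment line giving the ML helping rate and its profile CI.
#'
#' @param result an `assay_result`.
#' @param path output path.
#' @export
write_assay_report <- function(result, path) {
  released <- logical(result$n_trials)
  released[seq_along(result$release_times)] <- TRUE
  steps <- rep(NA_integer_, result$n_trials)
  steps[seq_along(result$release_times)] <- result$release_times
  df <- data.frame(trial = seq_len(result$n_trials),
                   released = as.integer(released), release_step = steps)
  ci <- helping_rate_ci(result)
  con <- file(path, "w"); on.exit(close(con))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(sprintf("# helping_rate=%.10g ci95=[%.10g, %.10g]",
                     result$helping_rate, ci[1], ci[2]), con)
  invisible(path)
}
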