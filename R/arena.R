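#' Arena configuration
#'
#' Physical and stochastic parameters of the 1 m x 1 m toroidal world.
#' Defaults are the experimental conditions of the foraging/helping task:
#' two 7 cm robots, two 5.4 cm food sources, 100 ms update steps, wheel
#' speeds up to 8.2 cm/s, stuck onset and self-release at 5e-4 per step,
#' a five-fold release speed-up while the partner stays within 1 cm
#' (edge-to-edge), and 20,000-step evaluations.
#'
#' @param arena_side arena side length (m); the world wraps toroidally.
#' @param robot_diameter,food_diameter body diameters (m).
#' @param n_food number of food sources kept in the arena.
#' @param dt step duration (s).
#' @param wheel_vmax wheel speed bound (cm/s).
#' @param p_stuck per-step probability that a mobile robot becomes stuck.
#' @param p_self_release per-step probability that a stuck robot frees
#'   itself.
#' @param help_multiplier release-hazard multiplier while the partner is
#'   within `help_gap`.
#' @param help_gap edge-to-edge helping distance (m).
#' @param prox_range proximity-sensor range beyond the body (m), with
#'   linear activation falloff.
#' @param eval_steps steps per evaluation.
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(arena_side = 1.0, robot_diameter = 0.07,
                         food_diameter = 0.054, n_food = 2L, dt = 0.1,
                         wheel_vmax = 8.2, p_stuck = 5e-4,
                         p_self_release = 5e-4, help_multiplier = 5,
                         help_gap = 0.01, prox_range = 0.05,
                         eval_steps = 20000L) {
  cfg <- list(arena_side = arena_side, robot_diameter = robot_diameter,
              food_diameter = food_diameter, n_food = as.integer(n_food),
              dt = dt, wheel_vmax = wheel_vmax, p_stuck = p_stuck,
              p_self_release = p_self_release,
              help_multiplier = help_multiplier, help_gap = help_gap,
              prox_range = prox_range, eval_steps = as.integer(eval_steps))
  validate_arena_config(cfg)
  structure(cfg, class = "arena_config")
}

validate_arena_config <- function(cfg) {
  lens <- c("arena_side", "robot_diameter", "food_diameter", "dt",
            "wheel_vmax", "help_gap", "prox_range")
  for (f in lens)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("arena config: ", f, " must be positive")
  for (f in c("p_stuck", "p_self_release"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("arena config: ", f, " must be a probability in [0, 1]")
  if (cfg$help_multiplier * cfg$p_self_release > 1)
    stop("arena config: helped release hazard exceeds 1")
  if (cfg$n_food < 1L || cfg$eval_steps < 0L)
    stop("arena config: n_food must be >= 1 and eval_steps >= 0")
  invisible(cfg)
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf(
    "Arena: %.2g m torus, %d food, dt=%.3g s, p_stuck=%g, p_release=%g (x%g helped), %d steps/eval\n",
    x$arena_side, x$n_food, x$dt, x$p_stuck, x$p_self_release,
    x$help_multiplier, x$eval_steps))
  invisible(x)
}

genome_weights <- function(genome, topology) {
  # a plain numeric weight vector is accepted wherever a genome is: useful
  # for probing the controller with weights (e.g. exact zeros) that do not
  # lie on the 8-bit decoding grid
  if (is.numeric(genome) && !inherits(genome, "genome")) {
    if (length(genome) != topology$n_weights)
      stop("weight vector length does not match topology")
    return(as.numeric(genome))
  }
  spec <- attr(genome, "spec")
  if (spec$has_memory != topology$has_memory)
    stop("genome decoding spec and topology disagree on the memory neuron")
  w <- decode_genome(genome)
  if (length(w) != topology$n_weights)
    stop("decoded weight count does not match topology")
  w
}

#' Run one evaluation of a pair of robots
#'
#' Places the two robots at random non-overlapping positions and headings,
#' the food at random positions clear of the robots, then iterates
#' sense -> activate -> move -> collide -> eat -> stuck/release for
#' `eval_steps` steps.  Memory neurons start at their maximum (no completed
#' episodes).  Fully reproducible for a fixed RNG state.
#'
#' @param genome_a,genome_b `genome` objects for the two robots (pass the
#'   same object for clone pairing).
#' @param topology a [network_topology()] matching the genomes.
#' @param config an [arena_config()].
#' @param memory_clamp length-2 numeric; a non-`NA` entry clamps that
#'   robot's memory input to the value for the whole evaluation (used by
#'   the artificial-selection regimes and mood assays).
#' @param log_trajectory if `TRUE`, return a per-step trajectory matrix
#'   (step, x/y/heading/stuck per robot, memory activations).
#' @param init_state optional numeric vector
#'   `c(x0, y0, th0, x1, y1, th1, food1x, food1y, ...)` to start from a
#'   fixed world state instead of random placement (testing/inspection).
#' @return An object of class `eval_result`: per-robot `food_counts`,
#'   `stuck_episodes` data frames (start, end, helped), `helping_given`
#'   counts, and final memory counters.
#' @export
run_evaluation <- function(genome_a, genome_b, topology = network_topology(),
                           config = arena_config(),
                           memory_clamp = c(NA_real_, NA_real_),
                           log_trajectory = FALSE, init_state = NULL) {
  wa <- genome_weights(genome_a, topology)
  wb <- genome_weights(genome_b, topology)
  res <- sim_run(wa, wb, topology$has_memory, unclass(config),
                 config$eval_steps, 0L, memory_clamp[1L], memory_clamp[2L],
                 FALSE, log_trajectory, init_state)
  structure(res, class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Evaluation: %d steps, food %d/%d, helping given %d/%d\n",
              x$steps_run, x$food_counts[1], x$food_counts[2],
              x$helping_given[1], x$helping_given[2]))
  invisible(x)
}

#' Sensor activations on a frozen world state
#'
#' Computes the 8 proximity and 9 camera activations a robot would read in
#' the given state, without advancing the world.  Proximity sensor `k`
#' (1-based) faces `heading + (k-1) * 45` degrees and responds linearly in
#' the edge-to-edge distance to the other robot within `prox_range`.
#' Camera neurons cover a forward 60 degree cone in three 20 degree
#' sectors, ordered red/green/blue by sector (from -30 to +30 degrees);
#' food renders red, a mobile partner green, a stuck partner blue, and the
#' nearest object occludes.
#'
#' @param state numeric `c(x0, y0, th0, x1, y1, th1, food x/y pairs...)`.
#' @param robot_index 1 or 2.
#' @param stuck logical length-2: stuck status of each robot.
#' @param config an [arena_config()].
#' @param partner_invisible if `TRUE` the other robot contributes nothing
#'   to the sensors (the chance-level assay condition).
#' @return Named numeric vector of 17 activations in `[0, 1]`.
#' @export
sense_world <- function(state, robot_index, stuck = c(FALSE, FALSE),
                        config = arena_config(),
                        partner_invisible = FALSE) {
  stopifnot(robot_index %in% c(1L, 2L))
  out <- sim_sense(unclass(config), as.numeric(state), as.logical(stuck),
                   as.integer(robot_index) - 1L, partner_invisible)
  names(out) <- c(paste0("prox", 1:8),
                  paste0(rep(c("red", "green", "blue"), each = 3),
                         rep(1:3, 3)))
  out
}

#' @rdname sense_world
#' @export
sense_proximity <- function(state, robot_index, stuck = c(FALSE, FALSE),
                            config = arena_config(),
                            partner_invisible = FALSE) {
  sense_world(state, robot_index, stuck, config, partner_invisible)[1:8]
}

#' @rdname sense_world
#' @export
sense_camera <- function(state, robot_index, stuck = c(FALSE, FALSE),
                         config = arena_config(),
                         partner_invisible = FALSE) {
  sense_world(state, robot_index, stuck, config, partner_invisible)[9:17]
}

#' Monte-Carlo stuck-episode durations
#'
#' Samples episode durations with the same per-step Bernoulli release
#' hazard the world step uses: `p_self_release` alone, or multiplied by
#' `help_multiplier` when the partner sits continuously within helping
#' range.  Used to check the five-fold helped release speed-up
#' (mean 2000 steps unhelped vs 400 helped at the default rates).
#'
#' @param n number of episodes.
#' @param config an [arena_config()].
#' @param helped logical; partner continuously within helping range?
#' @param max_steps censoring bound per episode.
#' @return Integer vector of `n` durations (steps).
#' @export
stuck_episode_durations <- function(n, config = arena_config(),
                                    helped = FALSE, max_steps = 1000000L) {
  sim_stuck_durations(as.integer(n), config$p_self_release,
                      config$help_multiplier, helped,
                      as.integer(max_steps))
}

#' Write a trajectory log as TSV
#'
#' @param result an `eval_result` produced with `log_trajectory = TRUE`.
#' @param path output path.
#' @export
write_trajectory <- function(result, path) {
  if (is.null(result$trajectory))
    stop("evaluation was run without log_trajectory = TRUE")
  df <- as.data.frame(result$trajectory)
  names(df) <- c("step", "x1", "y1", "heading1", "stuck1",
                 "x2", "y2", "heading2", "stuck2", "memory1", "memory2",
                 "food1", "food2")
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
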