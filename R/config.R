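#' Default experiment configuration
#'
#' The full default configuration of the platform as a nested list:
#' `arena` (rates, geometry, evaluation length), `evolution` (population
#' size, pairing, generations, mutation, injection), `assay` (trials,
#' trial length).  These are the reference experimental conditions
#' (p_stuck 5e-4, N = 100, 20,000-step evaluations, 1e-2 per-bit
#' mutation).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    arena = unclass(arena_config()),
    evolution = list(population_size = 100L, evaluations_per_robot = 5L,
                     pairing = "unrelated", has_memory = FALSE,
                     generations = 500L, per_bit_mutation = 1e-2,
                     injection_genotype = NULL, injection_prob = 1e-2,
                     assay_every = 25L, assay_sample = 10L),
    assay = list(n_trials = 100L, trial_steps = 1000L,
                 partner_visible = TRUE, memory_clamp = NA_real_),
    seed = 1L)
}

#' Load and validate a structured text configuration file
#'
#' Reads a YAML configuration with the sections of [default_config()];
#' absent keys take the default experimental values, unknown keys are
#' rejected, and every value is validated against its type invariants
#' (probabilities in `[0, 1]`, positive lengths and sizes, ...).
#'
#' @param path configuration file path.
#' @return Validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(default_config(), user, "")
}

merge_config <- function(defaults, user, prefix) {
  if (!is.list(user)) stop("config error: section '", prefix,
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config error: unknown key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.null(user[[k]])) next  # explicit null keeps the default
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(prefix, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  if (prefix == "") validate_config(defaults)
  defaults
}

validate_config <- function(cfg) {
  do.call(arena_config, cfg$arena)          # runs the arena invariants
  ev <- cfg$evolution
  if (ev$population_size < 2L)
    stop("config error: evolution.population_size must be >= 2")
  for (k in c("per_bit_mutation", "injection_prob"))
    if (ev[[k]] < 0 || ev[[k]] > 1)
      stop("config error: evolution.", k, " must be in [0, 1]")
  if (!ev$pairing %in% c("unrelated", "related", "half_related"))
    stop("config error: evolution.pairing invalid")
  if (cfg$assay$n_trials < 1L || cfg$assay$trial_steps < 1L)
    stop("config error: assay trials/steps must be >= 1")
  invisible(cfg)
}

#' Write a configuration back to YAML
#'
#' `load_config(dump_config(cfg, path))` reproduces `cfg` exactly
#' (normalization round-trip).
#'
#' @param cfg nested configuration list.
#' @param path output path.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build module configs from a nested configuration
#'
#' @param cfg validated nested configuration from [load_config()].
#' @return List with `arena`, `assay` and `evolution` config objects.
#' @export
config_objects <- function(cfg) {
  arena <- do.call(arena_config, cfg$arena)
  assay <- do.call(assay_config, cfg$assay)
  ev <- cfg$evolution
  evolution <- evolution_config(
    population_size = ev$population_size,
    evaluations_per_robot = ev$evaluations_per_robot,
    pairing = ev$pairing, has_memory = ev$has_memory,
    generations = ev$generations, per_bit_mutation = ev$per_bit_mutation,
    injection_genotype = ev$injection_genotype,
    injection_prob = ev$injection_prob, assay_every = ev$assay_every,
    assay_sample = ev$assay_sample, assay = assay, arena = arena)
  list(arena = arena, assay = assay, evolution = evolution)
}

#' Write a run manifest
#'
#' Structured JSON provenance record for a run: the command, the full
#' configuration echo, the seed, package version, start timestamp and the
#' list of output files (each of which must exist).
#'
#' @param path manifest output path.
#' @param command the command or function invoked.
#' @param config configuration echo (any JSON-serializable structure).
#' @param seed integer seed used.
#' @param outputs character vector of produced file paths.
#' @export
write_manifest <- function(path, command, config, seed, outputs) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest lists missing output file(s): ",
         paste(missing, collapse = ", "))
  manifest <- list(command = command, config = config, seed = seed,
                   package_version =
                     as.character(utils::packageVersion("reciprobot")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
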