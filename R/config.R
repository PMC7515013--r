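# Experiment configurations.

.make_config <- function(profile, world_width, world_height,
                         obstacle_fraction, spawn_distance, lifetime,
                         checkpoint_stride, population_size, generations,
                         replicates, fitness_mappings, tournament_size,
                         mutation, genome_length, n_nodes, gate_set,
                         samples_per_state) {
  cfg <- list(profile = profile, world_width = world_width,
              world_height = world_height,
              obstacle_fraction = obstacle_fraction,
              spawn_distance = spawn_distance, lifetime = lifetime,
              checkpoint_stride = checkpoint_stride,
              population_size = population_size, generations = generations,
              replicates = replicates, fitness_mappings = fitness_mappings,
              tournament_size = tournament_size, mutation = mutation,
              genome_length = genome_length, n_nodes = n_nodes,
              gate_set = gate_set, samples_per_state = samples_per_state)
  class(cfg) <- "experiment_config"
  cfg
}

#' Desk-scale experiment profile
#'
#' A scaled-down configuration that preserves the structure of the full
#' study at workstation cost: 16x16 world (spawn distance 8), lifetime 256,
#' population 50, 2000 generations, 10 replicates, fitness on 6 of the 24
#' mappings (all 24 are still used for final evaluation and the elite test).
#'
#' @param ... named overrides of individual fields.
#' @return an `experiment_config`.
#' @export
desk_profile <- function(...) {
  cfg <- .make_config(
    profile = "desk", world_width = 16L, world_height = 16L,
    obstacle_fraction = 0.05, spawn_distance = 8L, lifetime = 256L,
    checkpoint_stride = 25L, population_size = 50L, generations = 2000L,
    replicates = 10L, fitness_mappings = c(1L, 5L, 9L, 14L, 18L, 22L),
    tournament_size = 2L, mutation = mutation_rates(),
    genome_length = 5000L, n_nodes = 16L, gate_set = default_gate_set(),
    samples_per_state = 64L)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Full-scale experiment profile
#'
#' The published study conditions: 64x64 world, spawn distance 32, lifetime
#' 512, population 100, 200000 generations, 200 replicates, all 24 mappings
#' per evaluation. This is cluster-scale work; it is provided for
#' completeness and is not run by the test suite.
#'
#' @param ... named overrides of individual fields.
#' @return an `experiment_config`.
#' @export
paper_profile <- function(...) {
  cfg <- .make_config(
    profile = "paper", world_width = 64L, world_height = 64L,
    obstacle_fraction = 0.05, spawn_distance = 32L, lifetime = 512L,
    checkpoint_stride = 50L, population_size = 100L, generations = 200000L,
    replicates = 200L, fitness_mappings = 1:24, tournament_size = 2L,
    mutation = mutation_rates(), genome_length = 5000L, n_nodes = 16L,
    gate_set = default_gate_set(), samples_per_state = 64L)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Hash of a configuration (stamped into output artifacts)
#' @param config an `experiment_config`.
#' @return the hash as a double.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  cpp_genome_hash(utf8ToInt(as.character(json)) %% 256L)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %s: %dx%d world, pop %d, %d generations, lifetime %d\n",
    x$profile, x$world_width, x$world_height, x$population_size,
    x$generations, x$lifetime))
  invisible(x)
}
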