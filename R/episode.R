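# Episode execution: one lifetime of an animat in a world under one
# action-to-result mapping, plus the all-mappings evaluation that defines
# fitness.

#' Run one lifetime episode
#'
#' Loops sensor encoding -> brain update -> motor decoding -> agent step for
#' `lifetime` timesteps. The motor nodes are read as a 2-bit action (00 = A,
#' 01 = B, 10 = C, 11 = D; first motor node = high bit), which the mapping
#' translates into a movement result. The full brain state is recorded at
#' every timestep, and gate tables can be snapshot at checkpoints for the
#' per-time-point integration analysis.
#'
#' @param brain a `markov_brain` (reset it first if a naive start is
#'   intended).
#' @param world a `grid_world`.
#' @param mapping integer vector of 4 result codes (a row of
#'   [action_mappings()]).
#' @param lifetime number of timesteps (default 512).
#' @param checkpoints increasing integer timesteps (0 = birth) at which gate
#'   tables are snapshot; empty for none.
#' @param record_trace record the state trace (integer state codes, node 1 =
#'   least-significant bit)?
#' @return an `episode_result`: `goals_reached`, `action_counts` (named by
#'   result type), `state_trace` (length `lifetime + 1`), `snapshots` (one
#'   list of per-gate tables per checkpoint), and the final `brain`.
#' @export
run_episode <- function(brain, world, mapping, lifetime = 512L,
                        checkpoints = integer(0), record_trace = TRUE) {
  stopifnot(inherits(brain, "markov_brain"), inherits(world, "grid_world"),
            length(mapping) == 4)
  out <- cpp_run_episode(brain, world, as.integer(mapping),
                         as.integer(lifetime), as.integer(checkpoints),
                         isTRUE(record_trace))
  res <- list(goals_reached = out$goals,
              action_counts = setNames(out$result_counts,
                                       names(result_codes())),
              state_trace = out$trace,
              actions = out$actions, cells = out$cells,
              orientations = out$orients, goal_events = out$goal_events,
              snapshots = out$snapshots,
              checkpoints = as.integer(checkpoints),
              lifetime = as.integer(lifetime),
              brain = structure(out$brain, class = "markov_brain"))
  res$brain$gates <- lapply(res$brain$gates,
                            function(g) { class(g) <- "gate"; g })
  res$brain$learning_enabled <- brain$learning_enabled
  class(res) <- "episode_result"
  res
}

#' @export
print.episode_result <- function(x, ...) {
  cat(sprintf("<episode_result> %d goals in %d timesteps\n",
              x$goals_reached, x$lifetime))
  cat("  actions:", paste(sprintf("%s=%d", names(x$action_counts),
                                  x$action_counts), collapse = " "), "\n")
  invisible(x)
}

#' Unpack integer state codes into a bit matrix
#' @param trace integer state codes (node 1 = least-significant bit).
#' @param n_nodes number of nodes.
#' @return 0/1 matrix, one row per timestep, one column per node.
#' @export
decode_states <- function(trace, n_nodes) {
  m <- vapply(seq_len(n_nodes),
              function(k) bitwAnd(bitwShiftR(trace, k - 1L), 1L),
              integer(length(trace)))
  matrix(m, nrow = length(trace), ncol = n_nodes)
}

#' Evaluate a genome on a set of action-to-result mappings
#'
#' Decodes the genome once; for each mapping (fixed enumeration order) the
#' brain is fully reset (states and learned tables) so every variant is
#' learned from a naive state, then one episode is run. `Gtotal` is the sum
#' of goals over the mappings.
#'
#' @param genome integer genome.
#' @param world a `grid_world`.
#' @param mappings matrix of mapping rows (default: all 24).
#' @param lifetime episode length.
#' @param learning_enabled allow feedback learning during the episodes?
#' @param n_nodes,gate_set decoding parameters.
#' @return list with `g_total` and `per_mapping` goal counts.
#' @export
evaluate_all_mappings <- function(genome, world, mappings = action_mappings(),
                                  lifetime = 512L, learning_enabled = TRUE,
                                  n_nodes = 16L,
                                  gate_set = default_gate_set()) {
  out <- cpp_evaluate_genome(as.integer(genome), world,
                             as.matrix(mappings), as.integer(lifetime),
                             as.integer(n_nodes),
                             .enabled_type_ids(gate_set),
                             isTRUE(learning_enabled))
  list(g_total = out$g_total, per_mapping = as.integer(out$per_mapping))
}

#' Build an oracle brain for a known mapping
#'
#' A single deterministic 4-in/2-out gate that reads the sensor one-hot and
#' emits the motor pattern whose action maps to the indicated result --
#' i.e. a policy that always follows the arrows, given the true mapping.
#' Useful as a navigation upper-bound fixture.
#'
#' @param mapping integer vector of 4 result codes.
#' @return a `markov_brain` (16 nodes).
#' @export
oracle_brain <- function(mapping) {
  inv <- integer(4)
  inv[mapping + 1] <- 0:3  # result -> action
  outs <- integer(16)
  for (p in 0:15) {
    bits <- bitwAnd(bitwShiftR(p, 3:0), 1L) # sensors 1..4, node 1 = MSB here
    result <- if (sum(bits) == 1) {
      # sensor 1 idle, 2 right, 3 forward, 4 left
      c(result_codes()["idle"], result_codes()["right"],
        result_codes()["forward"], result_codes()["left"])[which(bits == 1)]
    } else {
      result_codes()["idle"]
    }
    outs[p + 1] <- inv[result + 1]
  }
  g <- deterministic_gate(1:4, 5:6, outs)
  build_brain(list(g), n_nodes = 16L)
}
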