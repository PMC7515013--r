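# Serialisation of episode traces, TPMs and phi results.

#' Write an episode trace as CSV
#'
#' One row per timestep: the timestep, every node bit, the action taken
#' (0--3 for A--D), the agent's row/column and heading before the move
#' resolved, and whether the step reached the goal. Requires an episode run
#' with `record_trace = TRUE`.
#'
#' @param episode an `episode_result`.
#' @param world the `grid_world` the episode ran in (for coordinates).
#' @param path output file.
#' @export
write_episode_csv <- function(episode, world, path) {
  if (length(episode$actions) == 0) {
    stop("episode was run without record_trace = TRUE")
  }
  n <- episode$brain$n_nodes
  bits <- decode_states(episode$state_trace[seq_along(episode$actions)], n)
  colnames(bits) <- paste0("node", seq_len(n))
  df <- data.frame(timestep = seq_along(episode$actions) - 1L, bits,
                   action = episode$actions,
                   row = episode$cells %/% world$ncol + 1L,
                   col = episode$cells %% world$ncol + 1L,
                   orientation = episode$orientations,
                   goal_event = episode$goal_events)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a transition probability matrix as CSV with a JSON sidecar
#'
#' Dense TPMs are written as a full matrix, sparse ones as (from, to, p)
#' triplets; the sidecar (`path` + `.json`) records the node count,
#' construction mode and sample count.
#'
#' @param tpm a `tpm`.
#' @param path output file.
#' @export
write_tpm <- function(tpm, path) {
  if (!is.null(tpm$probs)) {
    write.csv(tpm$probs, path, row.names = FALSE)
  } else {
    write.csv(tpm$triplets, path, row.names = FALSE)
  }
  meta <- list(n_nodes = tpm$n_nodes, construction = tpm$construction,
               samples = tpm$samples, sparse = is.null(tpm$probs))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a transition probability matrix written by [write_tpm()]
#' @param path file written by [write_tpm()].
#' @return a `tpm`.
#' @export
read_tpm <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  raw <- read.csv(path)
  if (isTRUE(meta$sparse)) {
    .new_tpm(meta$n_nodes, triplets = raw, construction = meta$construction,
             samples = if (is.null(meta$samples)) NA_integer_
                       else meta$samples)
  } else {
    .new_tpm(meta$n_nodes, probs = unname(as.matrix(raw)),
             construction = meta$construction,
             samples = if (is.null(meta$samples)) NA_integer_
                       else meta$samples)
  }
}

#' Serialise a phi result or trajectory to JSON
#' @param x a `phi_result` or `phi_trajectory`.
#' @param path output file.
#' @export
write_phi_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
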