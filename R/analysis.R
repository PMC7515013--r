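# Figure-analog analyses: action fractions, gate mutual-information change
# over a lifetime, and phi versus performance along the line of descent.

#' Fraction of actions per movement result
#'
#' Pools the action counts of one or more episodes and returns the fraction
#' of timesteps spent on each result type (left, right, idle, forward).
#'
#' @param episode_results an `episode_result` or a list of them.
#' @return named numeric vector of fractions summing to 1.
#' @export
action_fractions <- function(episode_results) {
  if (inherits(episode_results, "episode_result")) {
    episode_results <- list(episode_results)
  }
  counts <- Reduce(`+`, lapply(episode_results, `[[`, "action_counts"))
  counts / sum(counts)
}

#' Gate mutual information at birth and death of one lifetime
#'
#' Mean analytic mutual information over the brain's decomposable (and
#' decomposable feedback) gates before the episode and after it; learning
#' can only change feedback gates, so a static brain has a zero change.
#'
#' @param brain a `markov_brain` or an integer genome.
#' @param world a `grid_world`.
#' @param mapping integer vector of 4 result codes.
#' @param lifetime episode length.
#' @return list with `mi_birth`, `mi_death`, `delta_mi` (bits).
#' @export
gate_mi_lifetime <- function(brain, world, mapping, lifetime = 512L) {
  if (!inherits(brain, "markov_brain")) brain <- decode_genome(brain)
  brain <- reset_brain(brain, "both")
  keep <- vapply(brain$gates, function(g) {
    g$type %in% c("decomposable", "decomposable_feedback")
  }, logical(1))
  mean_mi <- function(b) {
    if (!any(keep)) return(NA_real_)
    mean(vapply(b$gates[keep], gate_mutual_information, numeric(1)))
  }
  mi_birth <- mean_mi(brain)
  ep <- run_episode(brain, world, mapping, lifetime, record_trace = FALSE)
  mi_death <- mean_mi(ep$brain)
  delta <- if (any(keep)) mi_death - mi_birth else 0
  list(mi_birth = mi_birth, mi_death = mi_death, delta_mi = delta)
}

#' Phi versus performance along a line of descent
#'
#' For every line-of-descent member whose genome was retained, evaluates
#' Gtotal over the given mappings and the trace-based atomic phi of its
#' episodes, once with learning enabled and once with the feedback mechanism
#' disabled. Transition pairs are pooled across the evaluated mappings
#' before the plug-in estimate.
#'
#' @param lod a `line_of_descent`.
#' @param world a `grid_world`.
#' @param config experiment configuration.
#' @param mappings mapping rows to evaluate (default: all 24).
#' @param every evaluate every `every`-th member (the chain can be long).
#' @return data frame with one row per evaluated member: generation, id,
#'   g_total, phi_learning, phi_frozen.
#' @export
phi_vs_performance <- function(lod, world, config = desk_profile(),
                               mappings = action_mappings(), every = 1L) {
  ids <- names(lod$genomes)[!vapply(lod$genomes, is.null, logical(1))]
  ids <- ids[seq(1, length(ids), by = every)]
  rows <- lapply(ids, function(id) {
    genome <- lod$genomes[[id]]
    member <- lod$members[lod$members$id == as.integer(id), ]
    phis <- vapply(c(TRUE, FALSE), function(learn) {
      brain <- decode_genome(genome, config$n_nodes, config$gate_set,
                             learning_enabled = learn)
      traces <- lapply(seq_len(nrow(mappings)), function(m) {
        b <- reset_brain(brain, "both")
        run_episode(b, world, mappings[m, ], config$lifetime)$state_trace
      })
      # pool transitions: drop the seam between concatenated traces
      pairs_s <- unlist(lapply(traces, function(tr) tr[-length(tr)]))
      pairs_t <- unlist(lapply(traces, function(tr) tr[-1]))
      phi_atomic_from_trace_pairs(pairs_s, pairs_t, config$n_nodes)$phi_atomic
    }, numeric(1))
    ev <- evaluate_all_mappings(genome, world, mappings, config$lifetime,
                                TRUE, config$n_nodes, config$gate_set)
    data.frame(generation = member$generation, id = member$id,
               g_total = ev$g_total, phi_learning = phis[1],
               phi_frozen = phis[2])
  })
  do.call(rbind, rows)
}

#' Atomic phi from explicit transition pairs
#'
#' Plug-in estimate over given (state-at-t, state-at-t+1) pairs; used to
#' pool transitions from several episodes.
#'
#' @param s,t integer state codes of equal length.
#' @param n_nodes number of nodes encoded.
#' @return a `phi_result`.
#' @export
phi_atomic_from_trace_pairs <- function(s, t, n_nodes) {
  stopifnot(length(s) == length(t), length(s) >= 1)
  key <- paste(s, t)
  agg <- rowsum(rep(1, length(key)), key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  joint <- data.frame(
    s = as.integer(vapply(parts, `[`, character(1), 1)),
    t = as.integer(vapply(parts, `[`, character(1), 2)),
    p = agg[, 1] / length(s))
  .phi_from_joint(joint, n_nodes, "eq5")
}

#' Long-format analysis table from an evolution archive
#'
#' Per-generation summaries (mean and best fitness) in long format, stamped
#' with the configuration hash so every row is traceable to its run.
#'
#' @param archive an `evolution_archive`.
#' @return data frame with columns generation, metric, value, config_hash.
#' @export
analysis_table <- function(archive) {
  a <- archive$archive
  mean_fit <- aggregate(fitness ~ generation, a, mean)
  best_fit <- aggregate(fitness ~ generation, a, max)
  out <- rbind(
    data.frame(generation = mean_fit$generation, metric = "mean_fitness",
               value = mean_fit$fitness),
    data.frame(generation = best_fit$generation, metric = "best_fitness",
               value = best_fit$fitness))
  out$config_hash <- config_hash(archive$config)
  out[order(out$generation, out$metric), ]
}
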