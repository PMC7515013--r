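# Integrated information.
#
# Atomic phi compares the information the whole system carries across one
# time step with the sum carried by its nodes individually. Two algebraically
# identical assemblies are implemented as independent code paths and used as
# a permanent cross-check:
#   (mutual-information form)   phi = I(Xt : Xt+1) - sum_i I(Xt_i : Xt+1_i)
#                                     + [sum_i H(Xt_i) - H(Xt)]
#   (conditional-entropy form)  phi = sum_i H(Xt_i | Xt+1_i) - H(Xt | Xt+1)
# The per-time-point variant ("max-entropy phi") evaluates the
# conditional-entropy form on the brain's transition probability matrix at
# one lifetime instant, taking the current state to be uniform over all 2^n
# states, so integration can be measured before, during and after learning
# without observing the animat in its environment.

#' Shannon entropy (base 2) of a probability table
#'
#' `0 log 0` is taken as 0. The input need not be normalised exactly;
#' entries are used as-is.
#' @param p numeric vector/matrix of probabilities.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# ---------------------------------------------------------------------------
# TPM construction
# ---------------------------------------------------------------------------

.tpm_exact_ok <- function(brain, max_nodes = 12L, max_output_bits = 20L) {
  out_bits <- sum(vapply(brain$gates, function(g) g$n_outputs, integer(1)))
  brain$n_nodes <= max_nodes && out_bits <= max_output_bits
}

.new_tpm <- function(n_nodes, probs = NULL, triplets = NULL,
                     construction = "analytic", samples = NA_integer_) {
  t <- list(n_nodes = as.integer(n_nodes), probs = probs,
            triplets = triplets, construction = construction,
            samples = samples)
  class(t) <- "tpm"
  t
}

#' Exact state-to-state transition probability matrix of a brain
#'
#' Enumerates, for each of the `2^n` start states, the joint outcome space
#' of all gates (gates fire independently; writes OR; unwritten nodes 0)
#' and accumulates the exact next-state distribution. Limited to small
#' systems; above the threshold the caller is directed to [sampled_tpm()].
#'
#' @param brain a `markov_brain`.
#' @param max_nodes,max_output_bits exact-mode thresholds.
#' @return a `tpm` with a dense `2^n x 2^n` row-stochastic matrix. State
#'   index: node 1 = least-significant bit; row = state at t.
#' @export
analytic_tpm <- function(brain, max_nodes = 12L, max_output_bits = 20L) {
  if (!.tpm_exact_ok(brain, max_nodes, max_output_bits)) {
    stop("system too large for the exact TPM; use sampled_tpm()")
  }
  probs <- cpp_analytic_tpm(brain)
  .new_tpm(brain$n_nodes, probs = probs, construction = "analytic")
}

#' Monte-Carlo estimate of the transition probability matrix
#'
#' For every start state the one-step update is run `samples_per_state`
#' times with learning disabled during measurement, and arrival states are
#' counted. The estimator converges to [analytic_tpm()] at the usual
#' `1/sqrt(k)` Monte-Carlo rate.
#'
#' @param brain a `markov_brain`.
#' @param samples_per_state draws per start state (default 64).
#' @param dense return a dense matrix (only for <= 12 nodes)? Otherwise the
#'   TPM is kept as sparse (from, to, probability) triplets.
#' @return a `tpm`.
#' @export
sampled_tpm <- function(brain, samples_per_state = 64L,
                        dense = brain$n_nodes <= 12L) {
  stopifnot(samples_per_state >= 1)
  cnt <- cpp_sample_transitions(brain, as.integer(samples_per_state))
  tri <- data.frame(from = cnt[, 1], to = cnt[, 2],
                    p = cnt[, 3] / samples_per_state)
  if (dense) {
    S <- 2^brain$n_nodes
    probs <- matrix(0, S, S)
    probs[cbind(tri$from + 1L, tri$to + 1L)] <- tri$p
    .new_tpm(brain$n_nodes, probs = probs, construction = "sampled",
             samples = samples_per_state)
  } else {
    .new_tpm(brain$n_nodes, triplets = tri, construction = "sampled",
             samples = samples_per_state)
  }
}

#' @export
print.tpm <- function(x, ...) {
  cat(sprintf("<tpm> %d nodes (%d states), %s%s\n", x$n_nodes, 2^x$n_nodes,
              x$construction,
              if (!is.na(x$samples)) sprintf(", %d samples/state", x$samples)
              else ""))
  invisible(x)
}

# joint triplets (s, t, p) for p(x_t = s, x_{t+1} = t) under input_dist
.joint_triplets <- function(tpm, input_dist = NULL) {
  S <- 2^tpm$n_nodes
  if (is.null(input_dist)) {
    input_dist <- rep(1 / S, S)
  }
  stopifnot(length(input_dist) == S, abs(sum(input_dist) - 1) < 1e-6)
  if (!is.null(tpm$probs)) {
    joint <- tpm$probs * input_dist
    nz <- which(joint > 0, arr.ind = TRUE)
    data.frame(s = nz[, 1] - 1L, t = nz[, 2] - 1L, p = joint[nz])
  } else {
    tri <- tpm$triplets
    data.frame(s = tri$from, t = tri$to, p = tri$p * input_dist[tri$from + 1L])
  }
}

# All phi quantities from a sparse joint distribution over (x_t, x_{t+1}).
# `method` only selects which assembly fills the phi_atomic field.
.phi_from_joint <- function(joint, n_nodes, method = c("eq5", "eq3")) {
  method <- match.arg(method)
  p <- joint$p / sum(joint$p)
  s <- joint$s
  t <- joint$t

  p_s <- rowsum(p, s)      # p(x_t), labelled by state
  p_t <- rowsum(p, t)
  H_s <- shannon_entropy(p_s)
  H_t <- shannon_entropy(p_t)
  H_joint <- shannon_entropy(p)
  H_cond <- H_joint - H_t          # H(Xt | Xt+1)
  I_sys <- H_s + H_t - H_joint     # I(Xt : Xt+1)

  per_node_I <- numeric(n_nodes)
  per_node_cond_H <- numeric(n_nodes)
  per_node_H_s <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {
    bs <- bitwAnd(bitwShiftR(s, i - 1L), 1L)
    bt <- bitwAnd(bitwShiftR(t, i - 1L), 1L)
    j2 <- rowsum(p, bs * 2L + bt)   # 2x2 joint of node i across the step
    Hi_joint <- shannon_entropy(j2)
    Hi_s <- shannon_entropy(rowsum(p, bs))
    Hi_t <- shannon_entropy(rowsum(p, bt))
    per_node_I[i] <- Hi_s + Hi_t - Hi_joint
    per_node_cond_H[i] <- Hi_joint - Hi_t
    per_node_H_s[i] <- Hi_s
  }
  nonindependence <- sum(per_node_H_s) - H_s

  phi <- if (method == "eq5") {
    sum(per_node_cond_H) - H_cond
  } else {
    I_sys - sum(per_node_I) + nonindependence
  }
  res <- list(phi_atomic = phi, I_sys = I_sys, per_node_I = per_node_I,
              nonindependence = nonindependence,
              per_node_cond_H = per_node_cond_H, joint_cond_H = H_cond,
              n_nodes = n_nodes, method = method)
  class(res) <- "phi_result"
  res
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("<phi_result> phi_atomic = %.6f bits (%s assembly)\n",
              x$phi_atomic, x$method))
  cat(sprintf("  I(Xt:Xt+1) = %.6f, sum_i I_i = %.6f, nonindependence = %.6f\n",
              x$I_sys, sum(x$per_node_I), x$nonindependence))
  invisible(x)
}

#' Atomic phi from a transition probability matrix
#'
#' Conditional-entropy assembly: the per-node conditional entropies across
#' the step, summed, minus the whole-system conditional entropy. The joint
#' distribution is `input_dist(x_t) * tpm(x_t+1 | x_t)`; the default input
#' distribution is uniform, which is exactly the max-entropy per-time-point
#' construction.
#'
#' @param tpm a `tpm`.
#' @param input_dist probability vector over the `2^n` states at time t
#'   (default uniform).
#' @return a `phi_result` (all entropy components populated).
#' @export
phi_atomic_from_tpm <- function(tpm, input_dist = NULL) {
  .phi_from_joint(.joint_triplets(tpm, input_dist), tpm$n_nodes, "eq5")
}

#' Atomic phi via the mutual-information assembly
#'
#' Assembles phi from the system mutual information, the per-node mutual
#' informations, and the nonindependence of the node variables. Algebraically
#' identical to [phi_atomic_from_tpm()]; kept as an independent code path
#' and used as a permanent cross-check.
#'
#' @inheritParams phi_atomic_from_tpm
#' @return a `phi_result`.
#' @export
phi_atomic_eq3 <- function(tpm, input_dist = NULL) {
  .phi_from_joint(.joint_triplets(tpm, input_dist), tpm$n_nodes, "eq3")
}

#' Atomic phi from an observed state trace
#'
#' Plug-in (maximum-likelihood) estimate: the joint distribution over
#' consecutive state pairs is the empirical frequency of observed
#' transitions. No bias correction is applied; short traces underestimate
#' entropies.
#'
#' @param state_trace integer state codes (node 1 = least-significant bit),
#'   e.g. the `state_trace` of an [run_episode()] result.
#' @param n_nodes number of nodes encoded in the trace.
#' @return a `phi_result`.
#' @export
phi_atomic_from_trace <- function(state_trace, n_nodes) {
  if (length(state_trace) < 2) stop("trace must contain at least 2 states")
  s <- state_trace[-length(state_trace)]
  t <- state_trace[-1]
  key <- paste(s, t)
  agg <- rowsum(rep(1, length(key)), key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  joint <- data.frame(
    s = as.integer(vapply(parts, `[`, character(1), 1)),
    t = as.integer(vapply(parts, `[`, character(1), 2)),
    p = agg[, 1] / length(s))
  .phi_from_joint(joint, n_nodes, "eq5")
}

#' Max-entropy phi of a brain at its current tables
#'
#' Atomic phi of the brain's transition probability matrix under the uniform
#' current-state distribution: exact when the system is small enough,
#' otherwise Monte-Carlo sampled.
#'
#' @param brain a `markov_brain`.
#' @param samples_per_state draws per start state in sampled mode.
#' @param max_nodes,max_output_bits exact-mode thresholds.
#' @return a `phi_result`.
#' @export
phi_max_h <- function(brain, samples_per_state = 64L, max_nodes = 12L,
                      max_output_bits = 20L) {
  tpm <- if (.tpm_exact_ok(brain, max_nodes, max_output_bits)) {
    analytic_tpm(brain, max_nodes, max_output_bits)
  } else {
    sampled_tpm(brain, samples_per_state, dense = FALSE)
  }
  phi_atomic_from_tpm(tpm)
}

#' Lifetime trajectory of max-entropy phi
#'
#' Runs one learning episode, snapshotting the gate tables every `stride`
#' timesteps (checkpoints 0, stride, 2*stride, ...), computes the
#' max-entropy phi of the frozen brain at each checkpoint, and fits an
#' ordinary least-squares line whose slope summarises the lifetime change.
#' A brain without feedback gates has the same transition matrix at every
#' time point, so its trajectory is constant and the slope 0.
#'
#' @param brain a `markov_brain` (or an integer genome, decoded with
#'   defaults).
#' @param world a `grid_world`.
#' @param mapping integer vector of 4 result codes.
#' @param lifetime episode length.
#' @param stride checkpoint spacing (default 50).
#' @param samples_per_state,max_nodes,max_output_bits passed to
#'   [phi_max_h()].
#' @return a `phi_trajectory`: data frame of (checkpoint, phi), plus `slope`
#'   and `intercept` of the linear fit.
#' @export
phi_maxh_trajectory <- function(brain, world, mapping, lifetime = 512L,
                                stride = 50L, samples_per_state = 64L,
                                max_nodes = 12L, max_output_bits = 20L) {
  if (!inherits(brain, "markov_brain")) {
    brain <- decode_genome(brain)
  }
  brain <- reset_brain(brain, "both")
  stride <- as.integer(stride)
  lifetime <- as.integer(lifetime)
  cps <- as.integer(seq(0L, stride * (lifetime %/% stride), by = stride))
  ep <- run_episode(brain, world, mapping, lifetime, checkpoints = cps,
                    record_trace = FALSE)
  phis <- vapply(ep$snapshots, function(snap) {
    b <- brain
    for (j in seq_along(b$gates)) b$gates[[j]]$table <- snap[[j]]
    phi_max_h(b, samples_per_state, max_nodes, max_output_bits)$phi_atomic
  }, numeric(1))
  df <- data.frame(checkpoint = cps, phi = phis)
  fit <- coef(lm(phi ~ checkpoint, data = df))
  traj <- list(trajectory = df, slope = unname(fit[2]),
               intercept = unname(fit[1]), lifetime = lifetime,
               stride = stride)
  class(traj) <- "phi_trajectory"
  traj
}

#' @export
print.phi_trajectory <- function(x, ...) {
  cat(sprintf("<phi_trajectory> %d checkpoints (stride %d), slope %.3e bits/step\n",
              nrow(x$trajectory), x$stride, x$slope))
  invisible(x)
}
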