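# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: everything is explicit loops over enumerated
# states, so they can serve as ground truth for the fast implementations.

# Shannon entropy of a vector of probabilities, longhand
entropy_longhand <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log2(v)
  h
}

# Atomic phi (conditional-entropy form) from a dense TPM by exhaustive
# enumeration of the joint distribution and per-node marginals.
phi_bruteforce <- function(tpm_matrix, input_dist = NULL) {
  S <- nrow(tpm_matrix)
  n <- as.integer(round(log2(S)))
  if (is.null(input_dist)) input_dist <- rep(1 / S, S)
  joint <- matrix(0, S, S)
  for (s in 1:S) {
    for (t in 1:S) joint[s, t] <- input_dist[s] * tpm_matrix[s, t]
  }
  p_t <- numeric(S)
  for (t in 1:S) p_t[t] <- sum(joint[, t])
  H_joint <- entropy_longhand(as.vector(joint))
  H_cond <- H_joint - entropy_longhand(p_t)
  sum_node_cond <- 0
  for (i in 1:n) {
    j2 <- matrix(0, 2, 2) # node i's (value at t, value at t+1) joint
    for (s in 1:S) {
      for (t in 1:S) {
        bs <- bitwAnd(bitwShiftR(s - 1L, i - 1L), 1L)
        bt <- bitwAnd(bitwShiftR(t - 1L, i - 1L), 1L)
        j2[bs + 1, bt + 1] <- j2[bs + 1, bt + 1] + joint[s, t]
      }
    }
    Hi_joint <- entropy_longhand(as.vector(j2))
    Hi_t <- entropy_longhand(c(j2[1, 1] + j2[2, 1], j2[1, 2] + j2[2, 2]))
    sum_node_cond <- sum_node_cond + (Hi_joint - Hi_t)
  }
  sum_node_cond - H_cond
}

# Gate mutual information by enumerating the full (input, output) joint
gate_mi_bruteforce <- function(gate) {
  ni <- gate$n_inputs
  no <- gate$n_outputs
  joint <- matrix(0, 2^ni, 2^no)
  for (r in 1:(2^ni)) {
    for (c in 1:(2^no)) joint[r, c] <- gate$table[r, c] / 2^ni
  }
  p_in <- numeric(2^ni)
  p_out <- numeric(2^no)
  for (r in 1:(2^ni)) p_in[r] <- sum(joint[r, ])
  for (c in 1:(2^no)) p_out[c] <- sum(joint[, c])
  entropy_longhand(p_in) + entropy_longhand(p_out) -
    entropy_longhand(as.vector(joint))
}

# random row-stochastic dense TPM over n nodes
random_tpm_matrix <- function(n) {
  S <- 2^n
  m <- matrix(runif(S * S), S, S)
  m / rowSums(m)
}

dense_tpm <- function(m) {
  structure(list(n_nodes = as.integer(round(log2(nrow(m)))), probs = m,
                 triplets = NULL, construction = "analytic",
                 samples = NA_integer_), class = "tpm")
}

# hand-assembled genome encoding a single gene; enabled types are the
# default set (deterministic = 0, decomposable = 1, decomposable_feedback
# = 2 in type-locus space)
single_gene_genome <- function(type_locus, ni, no, in_addrs, out_addrs,
                               payload, feedback = integer(0),
                               pad = 10L) {
  body <- c(type_locus, ni - 1L, no - 1L,
            c(in_addrs, rep(0L, 4 - length(in_addrs))),
            c(out_addrs, rep(0L, 4 - length(out_addrs))),
            payload, feedback)
  as.integer(c(rep(0L, pad), 42L, 213L, body, rep(0L, pad)))
}

# random decomposable feedback gate for closure sweeps
random_feedback_gate <- function() {
  ni <- sample(1:3, 1)
  no <- sample(1:3, 1)
  feedback_gate(sample(1:8, ni), sample(1:8, no),
                matrix(runif(2^ni * no), 2^ni, no),
                pos_node = sample(1:8, 1), neg_node = sample(1:8, 1),
                history_length = sample(0:3, 1),
                pos_deltas = runif(3, 0, 0.5), neg_deltas = runif(3, 0, 0.5))
}
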