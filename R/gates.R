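# Gate types and gate-level operations.
#
# A gate maps each of 2^i input patterns to a probability vector over 2^o
# output patterns (its "table"). Decomposable gates additionally carry, for
# each input pattern, o independent per-bit on-probabilities ("factors");
# the table row is the outer product of the per-bit Bernoulli distributions.
# Feedback-capable gates remember recent (input, output) decisions and shift
# probabilities toward (positive reinforcement) or away from (negative) the
# remembered decision.

.gate_types <- c("deterministic", "probabilistic", "decomposable",
                 "decomposable_feedback", "feedback")
# numeric ids used in the genome and the C++ engine
.gate_type_ids <- c(deterministic = 0L, probabilistic = 1L, decomposable = 2L,
                    decomposable_feedback = 3L, feedback = 4L)

#' Build a gate-table row from per-bit probabilities
#'
#' The probability of an output pattern is the product over output bits of
#' the bit's on-probability (if the bit is set) or its complement (if not).
#' The first factor corresponds to the most-significant pattern bit.
#'
#' @param factors numeric vector of per-bit on-probabilities in \[0, 1\].
#' @return numeric vector of length `2^length(factors)`, summing to 1.
#' @examples
#' row_from_factors(c(0.4, 0.4)) # 0.36 0.24 0.24 0.16
#' @export
row_from_factors <- function(factors) {
  if (any(factors < 0 | factors > 1)) {
    stop("factors must lie in [0, 1]")
  }
  o <- length(factors)
  patterns <- 0:(2^o - 1)
  row <- vapply(patterns, function(p) {
    bits <- bitwAnd(bitwShiftR(p, (o - 1):0), 1L)
    prod(ifelse(bits == 1L, factors, 1 - factors))
  }, numeric(1))
  row
}

#' Recover per-bit probabilities from a gate-table row
#'
#' Inverts [row_from_factors()]: computes per-bit marginal on-probabilities
#' and accepts them only if their outer product reconstructs the row within
#' `tol`. Rows whose bits are dependent (e.g. an XOR-correlated pair) have no
#' factorisation and yield `NULL`.
#'
#' @param row probability vector over `2^o` output patterns (sums to 1).
#' @param tol reconstruction tolerance.
#' @return numeric vector of `o` factors, or `NULL` if the row is not
#'   decomposable.
#' @examples
#' factors_from_row(c(0.36, 0.24, 0.24, 0.16)) # 0.4 0.4
#' factors_from_row(c(0.02, 0.48, 0.48, 0.02)) # NULL: bits are dependent
#' @export
factors_from_row <- function(row, tol = 1e-9) {
  s <- sum(row)
  if (abs(s - 1) > 1e-6) stop("row must sum to 1")
  o <- as.integer(round(log2(length(row))))
  if (2^o != length(row)) stop("row length must be a power of 2")
  patterns <- 0:(2^o - 1)
  factors <- vapply(seq_len(o), function(j) {
    on <- bitwAnd(bitwShiftR(patterns, o - j), 1L) == 1L
    sum(row[on])
  }, numeric(1))
  if (max(abs(row_from_factors(factors) - row)) > tol) {
    return(NULL)
  }
  factors
}

.validate_gate_table <- function(table, n_inputs, n_outputs,
                                 deterministic = FALSE) {
  stopifnot(is.matrix(table),
            nrow(table) == 2^n_inputs, ncol(table) == 2^n_outputs)
  if (any(table < 0 | table > 1)) stop("table entries must lie in [0, 1]")
  if (any(abs(rowSums(table) - 1) > 1e-9)) stop("table rows must sum to 1")
  if (deterministic && any(rowSums(table == 1) != 1)) {
    stop("deterministic gate needs exactly one 1.0 per row")
  }
  invisible(table)
}

.new_gate <- function(type, inputs, outputs, table, factors = NULL,
                      pos_node = NULL, neg_node = NULL, history_length = NULL,
                      pos_deltas = NULL, neg_deltas = NULL) {
  ni <- length(inputs); no <- length(outputs)
  if (ni < 1 || ni > 4 || no < 1 || no > 4) {
    stop("gates support 1-4 inputs and 1-4 outputs")
  }
  .validate_gate_table(table, ni, no, deterministic = type == "deterministic")
  g <- list(type = type, n_inputs = ni, n_outputs = no,
            inputs = as.integer(inputs), outputs = as.integer(outputs),
            table = table, table0 = table,
            factors = factors, factors0 = factors,
            pos_node = pos_node, neg_node = neg_node,
            history_length = history_length,
            pos_deltas = pos_deltas, neg_deltas = neg_deltas,
            history = NULL)
  class(g) <- "gate"
  g
}

#' Construct a deterministic logic gate
#'
#' @param inputs,outputs node addresses (1-based) read and written.
#' @param table either a full 0/1 row-stochastic matrix with one 1 per row,
#'   or an integer vector of length `2^length(inputs)` giving the 0-based
#'   output pattern for each input pattern.
#' @return a `gate` object.
#' @examples
#' # copy gate: node 1 -> node 2
#' deterministic_gate(1, 2, c(0L, 1L))
#' @export
deterministic_gate <- function(inputs, outputs, table) {
  no <- length(outputs)
  if (!is.matrix(table)) {
    out_pat <- as.integer(table)
    stopifnot(length(out_pat) == 2^length(inputs),
              all(out_pat >= 0 & out_pat < 2^no))
    m <- matrix(0, nrow = length(out_pat), ncol = 2^no)
    m[cbind(seq_along(out_pat), out_pat + 1L)] <- 1
    table <- m
  }
  .new_gate("deterministic", inputs, outputs, table)
}

#' Construct a decomposable probabilistic gate
#'
#' @param inputs,outputs node addresses (1-based).
#' @param factors matrix (`2^length(inputs)` rows, `length(outputs)` columns)
#'   of per-bit on-probabilities; row `r` serves input pattern `r - 1`.
#' @return a `gate` object whose table rows are outer products of the per-bit
#'   Bernoulli distributions.
#' @export
decomposable_gate <- function(inputs, outputs, factors) {
  factors <- as.matrix(factors)
  stopifnot(nrow(factors) == 2^length(inputs),
            ncol(factors) == length(outputs))
  table <- t(apply(factors, 1, row_from_factors))
  if (2^length(outputs) == 1) table <- matrix(table, ncol = 1)
  .new_gate("decomposable", inputs, outputs, table, factors = factors)
}

#' Construct a decomposable feedback gate
#'
#' A decomposable gate that learns: when the node wired for positive
#' (negative) reinforcement is on after an update, every remembered
#' (input, output) decision has its per-bit factors moved toward (away from)
#' the emitted bit values by the per-depth delta, clamped to
#' \[0.01, 0.99\], and the affected table row is rebuilt from the factors --
#' so rows stay decomposable by construction.
#'
#' @inheritParams decomposable_gate
#' @param pos_node,neg_node node addresses read for positive/negative
#'   reinforcement.
#' @param history_length how many recent decisions are remembered (0--3).
#' @param pos_deltas,neg_deltas per-depth probability increments in
#'   \[0, 0.5\]; scalars are recycled to length 3.
#' @return a `gate` object.
#' @export
feedback_gate <- function(inputs, outputs, factors, pos_node, neg_node,
                          history_length = 1L, pos_deltas = 0.1,
                          neg_deltas = 0.1) {
  g <- decomposable_gate(inputs, outputs, factors)
  stopifnot(history_length %in% 0:3,
            all(pos_deltas >= 0 & pos_deltas <= .delta_max),
            all(neg_deltas >= 0 & neg_deltas <= .delta_max))
  g$type <- "decomposable_feedback"
  g$pos_node <- as.integer(pos_node)
  g$neg_node <- as.integer(neg_node)
  g$history_length <- as.integer(history_length)
  g$pos_deltas <- rep_len(as.numeric(pos_deltas), 3)
  g$neg_deltas <- rep_len(as.numeric(neg_deltas), 3)
  g
}

#' Construct a legacy (non-decomposable) feedback gate
#'
#' Kept for comparison with the decomposable variant: reinforcement shifts
#' probability mass between the remembered table entry and one randomly
#' chosen other entry of the same row, then renormalises the row. Rows are
#' not guaranteed to stay factorisable, which invalidates
#' integrated-information analysis; the default gate set therefore excludes
#' this type.
#'
#' @inheritParams feedback_gate
#' @param table row-stochastic probability matrix.
#' @export
legacy_feedback_gate <- function(inputs, outputs, table, pos_node, neg_node,
                                 history_length = 1L, pos_deltas = 0.1,
                                 neg_deltas = 0.1) {
  g <- .new_gate("probabilistic", inputs, outputs, table)
  g$type <- "feedback"
  g$pos_node <- as.integer(pos_node)
  g$neg_node <- as.integer(neg_node)
  g$history_length <- as.integer(history_length)
  g$pos_deltas <- rep_len(as.numeric(pos_deltas), 3)
  g$neg_deltas <- rep_len(as.numeric(neg_deltas), 3)
  g
}

#' Fire a gate on one input pattern
#'
#' Samples an output pattern from the gate's current table row (deterministic
#' gates return their unique output without consuming randomness). For
#' feedback-capable gates the decision is pushed onto the gate's history.
#'
#' @param gate a `gate`.
#' @param input_pattern 0-based input pattern index, or a bit vector
#'   (first input = most significant bit).
#' @return list with `output` (0-based pattern) and the updated `gate`.
#' @export
gate_update <- function(gate, input_pattern) {
  if (length(input_pattern) > 1) {
    input_pattern <- sum(input_pattern * 2^((length(input_pattern) - 1):0))
  }
  stopifnot(input_pattern >= 0, input_pattern < 2^gate$n_inputs)
  row <- gate$table[input_pattern + 1, ]
  if (gate$type == "deterministic") {
    out <- which.max(row) - 1L
  } else {
    u <- runif(1)
    out <- as.integer(findInterval(u, cumsum(row))) # 0-based by construction
    out <- min(out, length(row) - 1L)
  }
  if (gate$type %in% c("decomposable_feedback", "feedback") &&
      gate$history_length > 0) {
    h <- rbind(c(input_pattern, out), gate$history)
    gate$history <- h[seq_len(min(nrow(h), gate$history_length)), ,
                      drop = FALSE]
  }
  list(output = out, gate = gate)
}

#' Apply reinforcement to a feedback-capable gate
#'
#' Applies the learning rule to every remembered decision (most recent first,
#' each depth with its own delta). A gate with an empty history is returned
#' unchanged with a message.
#'
#' @param gate a feedback-capable `gate`.
#' @param sign `"positive"` or `"negative"`.
#' @return the updated `gate`.
#' @export
apply_feedback <- function(gate, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (!gate$type %in% c("decomposable_feedback", "feedback")) {
    stop("gate has no feedback capability")
  }
  if (is.null(gate$history) || nrow(gate$history) == 0) {
    message("feedback on a gate with empty history: no-op")
    return(gate)
  }
  out <- cpp_apply_feedback(gate, sign == "positive")
  out$history <- gate$history
  class(out) <- "gate"
  out
}

#' Mutual information conveyed by a gate
#'
#' Analytic mutual information, in bits, between the input pattern (uniform
#' over the `2^i` patterns unless `input_dist` is given) and the output
#' pattern induced by the gate's current table.
#'
#' @param gate a `gate`.
#' @param input_dist optional probability vector over input patterns.
#' @return MI in bits, between 0 and `min(i, o)`.
#' @export
gate_mutual_information <- function(gate, input_dist = NULL) {
  p_in <- if (is.null(input_dist)) {
    rep(1 / nrow(gate$table), nrow(gate$table))
  } else {
    stopifnot(length(input_dist) == nrow(gate$table))
    input_dist / sum(input_dist)
  }
  joint <- gate$table * p_in   # p(in, out)
  p_out <- colSums(joint)
  shannon_entropy(p_in) + shannon_entropy(p_out) - shannon_entropy(joint)
}

#' @export
print.gate <- function(x, ...) {
  cat(sprintf("<%s gate> %d-in -> %d-out; reads %s writes %s\n",
              x$type, x$n_inputs, x$n_outputs,
              paste(x$inputs, collapse = ","),
              paste(x$outputs, collapse = ",")))
  if (x$type %in% c("decomposable_feedback", "feedback")) {
    cat(sprintf("  feedback: +node %d, -node %d, history %d\n",
                x$pos_node, x$neg_node, x$history_length))
  }
  invisible(x)
}

#' Serialize a gate to JSON
#'
#' Round-trip stable with [gate_from_json()].
#' @param gate a `gate`.
#' @return a JSON string.
#' @export
gate_to_json <- function(gate) {
  rec <- list(type = gate$type, inputs = gate$inputs, outputs = gate$outputs,
              table = gate$table, factors = gate$factors,
              pos_node = gate$pos_node, neg_node = gate$neg_node,
              history_length = gate$history_length,
              pos_deltas = gate$pos_deltas, neg_deltas = gate$neg_deltas)
  jsonlite::toJSON(rec[!vapply(rec, is.null, logical(1))],
                   digits = NA, auto_unbox = TRUE)
}

#' Deserialize a gate from JSON
#' @param json a string produced by [gate_to_json()].
#' @return a `gate`.
#' @export
gate_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  tb <- matrix(rec$table, nrow = 2^length(rec$inputs))
  switch(rec$type,
    deterministic = deterministic_gate(rec$inputs, rec$outputs, tb),
    decomposable = decomposable_gate(rec$inputs, rec$outputs,
                                     matrix(rec$factors,
                                            nrow = 2^length(rec$inputs))),
    decomposable_feedback = feedback_gate(
      rec$inputs, rec$outputs,
      matrix(rec$factors, nrow = 2^length(rec$inputs)),
      rec$pos_node, rec$neg_node, rec$history_length,
      rec$pos_deltas, rec$neg_deltas),
    feedback = legacy_feedback_gate(rec$inputs, rec$outputs, tb,
                                    rec$pos_node, rec$neg_node,
                                    rec$history_length,
                                    rec$pos_deltas, rec$neg_deltas),
    probabilistic = .new_gate("probabilistic", rec$inputs, rec$outputs, tb),
    stop("unknown gate type in JSON"))
}
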