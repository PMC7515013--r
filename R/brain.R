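# Markov Brain construction and update semantics.

#' Assemble a Markov Brain from gates
#'
#' The standard animat has 16 nodes: sensors 1--4 (written by the
#' environment), motors 5--6 (read as the action), hidden 7--16. Smaller node
#' counts are allowed for hand-built test systems. All nodes update
#' synchronously: every gate reads the time-t state, writes are combined by
#' OR, and nodes written by no gate fall back to 0.
#'
#' @param gates list of `gate` objects.
#' @param n_nodes,n_sensors,n_motors node layout.
#' @param learning_enabled if `FALSE`, feedback gates never update their
#'   tables: the brain stays static through its whole life.
#' @return a `markov_brain`.
#' @export
build_brain <- function(gates, n_nodes = 16L, n_sensors = 4L, n_motors = 2L,
                        learning_enabled = TRUE) {
  gates <- lapply(gates, function(g) {
    stopifnot(inherits(g, "gate"))
    addr <- c(g$inputs, g$outputs, g$pos_node, g$neg_node)
    if (any(addr < 1 | addr > n_nodes)) stop("gate address out of range")
    g
  })
  b <- list(n_nodes = as.integer(n_nodes), n_sensors = as.integer(n_sensors),
            n_motors = as.integer(n_motors),
            state = integer(n_nodes), gates = gates,
            learning_enabled = isTRUE(learning_enabled))
  class(b) <- "markov_brain"
  b
}

#' One synchronous brain update
#'
#' Writes the sensor bits into the sensor nodes, fires every gate on the
#' time-t state, OR-combines writes into the time-(t+1) state (unwritten
#' nodes reset to 0), and -- when learning is enabled -- applies feedback to
#' each feedback-capable gate whose positive/negative reinforcement node is
#' on in the NEW state (positive before negative).
#'
#' @param brain a `markov_brain`.
#' @param sensor_bits integer vector of sensor values (0/1), length
#'   `n_sensors`.
#' @return list with the updated `brain` and `motors`, the motor node values.
#' @export
brain_step <- function(brain, sensor_bits) {
  stopifnot(length(sensor_bits) == brain$n_sensors)
  out <- cpp_brain_step(brain, as.integer(sensor_bits))
  out$brain$learning_enabled <- brain$learning_enabled
  out
}

#' Reset a brain's runtime state and/or learned tables
#'
#' @param brain a `markov_brain`.
#' @param scope `"states"` zeroes all node states and clears feedback
#'   histories; `"learning"` restores every gate table to its genome-encoded
#'   (birth) values; `"both"` does both.
#' @return the reset `markov_brain`.
#' @export
reset_brain <- function(brain, scope = c("both", "states", "learning")) {
  scope <- match.arg(scope)
  if (scope %in% c("states", "both")) {
    brain$state <- integer(brain$n_nodes)
    brain$gates <- lapply(brain$gates, function(g) {
      g$history <- NULL
      g
    })
  }
  if (scope %in% c("learning", "both")) {
    brain$gates <- lapply(brain$gates, function(g) {
      g$table <- g$table0
      g$factors <- g$factors0
      g$history <- NULL
      g
    })
  }
  brain
}

#' @export
print.markov_brain <- function(x, ...) {
  types <- vapply(x$gates, function(g) g$type, character(1))
  cat(sprintf("<markov_brain> %d nodes (%d sensors, %d motors), %d gates%s\n",
              x$n_nodes, x$n_sensors, x$n_motors, length(x$gates),
              if (x$learning_enabled) "" else " [learning disabled]"))
  if (length(types)) {
    tt <- table(types)
    cat("  gates:", paste(sprintf("%s x%d", names(tt), tt), collapse = ", "),
        "\n")
  }
  invisible(x)
}
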