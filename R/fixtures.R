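# Deterministic fixtures with closed-form properties, used throughout the
# test suite and handy for exploring the measures.

#' Construct a named fixture brain or world
#'
#' Available fixtures:
#' \describe{
#'   \item{`copy_brain`}{2 nodes, each copied to itself. The system
#'     factorises over nodes, so atomic phi is exactly 0.}
#'   \item{`swap_brain`}{2 nodes exchanged each step: each node's next value
#'     carries no information about its own past, so atomic phi is 2 bits
#'     under the uniform input distribution.}
#'   \item{`xor_brain`}{both next nodes equal the XOR of the two current
#'     nodes; atomic phi is 1 bit under the uniform input distribution.}
#'   \item{`coin_brain`}{1 node rewritten by a fair coin each step.}
#'   \item{`feedback_probe_brain`}{8 nodes; one decomposable feedback gate
#'     (node 7 -> node 8, a cross-node channel so its sharpening changes
#'     phi; factors 0.5, history 1, deltas 0.1) whose positive and negative
#'     reinforcement nodes (5 and 6) receive copies of sensors 1 and 2.
#'     Reinforcement nodes are read from the post-update state, so setting
#'     sensor 1 (or 2) on a step injects positive (negative) feedback into
#'     that same step's decision.}
#'   \item{`corridor_world`}{a 3-row corridor of length 33 with every arrow
#'     pointing at the goal, spawn distance 32, respawning agents face the
#'     arrow: an oracle policy walks forward every step and scores
#'     lifetime / 32 goals.}
#'   \item{`open_world_5x5`}{5x5 world (3x3 open interior), goal at the
#'     centre, no obstacles, spawn distance 2.}
#' }
#'
#' @param name fixture name.
#' @return a `markov_brain` or `grid_world`.
#' @export
make_fixture <- function(name = c("copy_brain", "swap_brain", "xor_brain",
                                  "coin_brain", "feedback_probe_brain",
                                  "corridor_world", "open_world_5x5")) {
  name <- match.arg(name)
  switch(name,
    copy_brain = build_brain(list(
      deterministic_gate(1, 1, c(0L, 1L)),
      deterministic_gate(2, 2, c(0L, 1L))),
      n_nodes = 2L, n_sensors = 0L, n_motors = 0L),
    swap_brain = build_brain(list(
      deterministic_gate(1, 2, c(0L, 1L)),
      deterministic_gate(2, 1, c(0L, 1L))),
      n_nodes = 2L, n_sensors = 0L, n_motors = 0L),
    xor_brain = build_brain(list(
      # inputs (1,2); output pattern 11 when exactly one input is on
      deterministic_gate(c(1, 2), c(1, 2), c(0L, 3L, 3L, 0L))),
      n_nodes = 2L, n_sensors = 0L, n_motors = 0L),
    coin_brain = build_brain(list(
      decomposable_gate(1, 1, matrix(0.5, 2, 1))),
      n_nodes = 1L, n_sensors = 0L, n_motors = 0L),
    feedback_probe_brain = build_brain(list(
      deterministic_gate(1, 5, c(0L, 1L)),  # sensor 1 -> reinforcement node
      deterministic_gate(2, 6, c(0L, 1L)),  # sensor 2 -> punishment node
      feedback_gate(7, 8, matrix(0.5, 2, 1), pos_node = 5, neg_node = 6,
                    history_length = 1L, pos_deltas = 0.1,
                    neg_deltas = 0.1)),
      n_nodes = 8L, n_sensors = 4L, n_motors = 2L),
    corridor_world = .corridor_world(),
    open_world_5x5 = .open_world_5x5())
}

# 5 x 5 world, 3 x 3 open interior, goal fixed at the centre (3, 3)
.open_world_5x5 <- function() {
  wall <- matrix(FALSE, 5L, 5L)
  wall[c(1, 5), ] <- TRUE
  wall[, c(1, 5)] <- TRUE
  goal <- (3L - 1L) * 5L + 3L # column-major linear index of (3, 3)
  .finish_world(wall, goal, 5L, 5L, spawn_distance = 2L,
                respawn_facing_arrow = FALSE)
}

# 3 x 35 corridor: open row 2, goal at (2,2), arrows all west, spawn cells
# at distance 32 (i.e. column 34)
.corridor_world <- function() {
  height <- 3L
  width <- 35L
  wall <- matrix(TRUE, height, width)
  wall[2, 2:(width - 1)] <- FALSE
  goal <- (2L - 1L) * height + 2L # column-major linear index of (2, 2)
  .finish_world(wall, goal, width, height, spawn_distance = 32L,
                respawn_facing_arrow = TRUE)
}
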