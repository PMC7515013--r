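# The lattice navigation world.
#
# Cells are indexed (row, col), 1-based, origin top-left. Directions are
# coded 0 = N (row decreases), 1 = E, 2 = S, 3 = W; turning right adds 1
# mod 4. The exterior ring is wall; a configurable fraction of interior
# cells are obstacles. Every cell that can reach the goal carries its
# shortest-path distance and an arrow pointing at the next cell of a
# shortest path (neighbour tie-break in fixed N, E, S, W order).

.dir_offsets <- matrix(c(-1L, 0L, 0L, 1L, 1L, 0L, 0L, -1L), ncol = 2,
                       byrow = TRUE) # N, E, S, W as (drow, dcol)

#' Result codes of the navigation task
#'
#' The four movement results, in their fixed enumeration order:
#' 0 = turn left 90 degrees, 1 = turn right 90 degrees, 2 = idle,
#' 3 = move forward.
#' @return named integer vector.
#' @export
result_codes <- function() {
  c(left = 0L, right = 1L, idle = 2L, forward = 3L)
}

#' Enumerate the 24 action-to-result mappings
#'
#' Each of the four actions (A, B, C, D, i.e. the four motor patterns
#' 00, 01, 10, 11) is assigned a distinct result; the 24 bijections are
#' enumerated as the lexicographic permutations of (left, right, idle,
#' forward).
#'
#' @return a 24 x 4 integer matrix of result codes; row `i` is mapping `i`,
#'   columns are actions A--D.
#' @export
action_mappings <- function() {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perms(v[-i]))
    }))
  }
  m <- perms(0:3)
  dimnames(m) <- list(NULL, c("A", "B", "C", "D"))
  m
}

.cell_index0 <- function(row, col, ncol) (row - 1L) * ncol + (col - 1L)

#' Build a grid world
#'
#' Samples interior obstacles, picks the goal uniformly among non-wall
#' cells, computes shortest-path distances to the goal on the 4-neighbour
#' lattice (unit edge weights, via igraph), and derives the per-cell arrow.
#' Worlds without any cell at exactly `spawn_distance` from the goal are
#' redrawn (bounded retries).
#'
#' @param width,height grid size in cells (>= 5).
#' @param obstacle_fraction fraction of interior cells turned into walls.
#' @param spawn_distance agents (re)spawn at cells exactly this far from the
#'   goal.
#' @param respawn_facing_arrow if `TRUE` the agent spawns facing the cell's
#'   arrow (used by oracle fixtures); default is a uniform random heading.
#' @param max_tries rebuild attempts before giving up.
#' @return a `grid_world`.
#' @export
build_world <- function(width = 64L, height = 64L, obstacle_fraction = 0.05,
                        spawn_distance = 32L, respawn_facing_arrow = FALSE,
                        max_tries = 20L) {
  stopifnot(width >= 5, height >= 5)
  for (try in seq_len(max_tries)) {
    wall <- matrix(FALSE, height, width)
    wall[c(1, height), ] <- TRUE
    wall[, c(1, width)] <- TRUE
    interior <- which(!wall)
    n_obs <- round(obstacle_fraction * length(interior))
    if (n_obs > 0) wall[sample(interior, n_obs)] <- TRUE
    open <- which(!wall)
    if (length(open) < 2) next
    goal <- open[sample.int(length(open), 1)]
    w <- .finish_world(wall, goal, width, height, spawn_distance,
                       respawn_facing_arrow)
    if (length(w$spawn0) > 0) return(w)
  }
  stop("no cell at spawn distance ", spawn_distance,
       " after ", max_tries, " world draws")
}

# distance/arrow fields + engine-facing flat vectors, given walls and goal
.finish_world <- function(wall, goal, width, height, spawn_distance,
                          respawn_facing_arrow) {
  width <- as.integer(width)
  height <- as.integer(height)
  open <- which(!wall)
  idx_of <- match(seq_len(height * width), open) # matrix idx -> vertex id
  edges <- NULL
  gr <- arrayInd(open, c(height, width))
  # edges to E and S neighbours between open cells
  for (d in list(c(0L, 1L), c(1L, 0L))) {
    nr <- gr[, 1] + d[1]; nc <- gr[, 2] + d[2]
    ok <- nr >= 1 & nr <= height & nc >= 1 & nc <= width
    nidx <- (nc - 1L) * height + nr
    ok[ok] <- !wall[nidx[ok]]
    edges <- rbind(edges, cbind(idx_of[open[ok]], idx_of[nidx[ok]]))
  }
  g <- igraph::make_empty_graph(n = length(open), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  dvec <- suppressWarnings(
    igraph::distances(g, v = idx_of[goal], algorithm = "unweighted"))[1, ]
  dist <- matrix(NA_integer_, height, width)
  dfin <- rep(NA_integer_, length(dvec))
  dfin[is.finite(dvec)] <- as.integer(dvec[is.finite(dvec)])
  dist[open] <- dfin

  arrow <- matrix(NA_integer_, height, width)
  reach <- which(!is.na(dist) & dist > 0)
  rc <- arrayInd(reach, c(height, width))
  for (k in seq_along(reach)) {
    r <- rc[k, 1]; cc <- rc[k, 2]
    for (dir in 0:3) { # fixed N,E,S,W tie-break
      nr <- r + .dir_offsets[dir + 1, 1]
      nc <- cc + .dir_offsets[dir + 1, 2]
      if (nr < 1 || nr > height || nc < 1 || nc > width) next
      nd <- dist[nr, nc]
      if (!is.na(nd) && nd == dist[r, cc] - 1L) {
        arrow[r, cc] <- dir
        break
      }
    }
  }

  grc <- arrayInd(goal, c(height, width))
  spawn <- which(!is.na(dist) & dist == spawn_distance)
  sp_rc <- arrayInd(spawn, c(height, width))
  w <- list(nrow = height, ncol = width,
            wall = wall, dist = dist, arrow = arrow,
            goal = c(row = grc[1], col = grc[2]),
            spawn_distance = as.integer(spawn_distance),
            respawn_facing_arrow = isTRUE(respawn_facing_arrow),
            # flat 0-based fields for the engine (row-major)
            wall0 = as.integer(t(wall)),
            dist0 = { d <- t(dist); d[is.na(d)] <- -1L; as.integer(d) },
            arrow0 = { a <- t(arrow); a[is.na(a)] <- -1L; as.integer(a) },
            goal0 = as.integer(.cell_index0(grc[1], grc[2], width)),
            spawn0 = as.integer(.cell_index0(sp_rc[, 1], sp_rc[, 2], width)))
  class(w) <- "grid_world"
  w
}

#' @export
print.grid_world <- function(x, ...) {
  cat(sprintf(
    "<grid_world> %dx%d, goal (%d,%d), %d walls, %d spawn cells at d=%d\n",
    x$nrow, x$ncol, x$goal["row"], x$goal["col"], sum(x$wall),
    length(x$spawn0), x$spawn_distance))
  invisible(x)
}

#' Encode the relative arrow direction as the 4-bit sensor pattern
#'
#' Sensor 1 fires for the idle signal (the cell's arrow is undefined),
#' sensor 2 for a required right turn (90 or 180 degrees), sensor 3 when the
#' agent already faces the arrow (go forward), sensor 4 for a required left
#' turn.
#'
#' @param arrow_dir the cell's arrow direction (0--3) or `NA`.
#' @param orientation the agent's heading (0--3).
#' @return integer vector of 4 bits, exactly one set.
#' @export
sensor_encoding <- function(arrow_dir, orientation) {
  s <- integer(4)
  if (is.na(arrow_dir)) {
    s[1] <- 1L
    return(s)
  }
  rel <- (arrow_dir - orientation) %% 4
  if (rel == 0) s[3] <- 1L
  else if (rel == 3) s[4] <- 1L
  else s[2] <- 1L
  s
}

#' Advance an agent by one action
#'
#' Looks the action up in the mapping; turns change the heading only,
#' forward moves one cell unless the target is a wall (then nothing
#' happens), idle changes nothing. Reaching the goal respawns the agent at a
#' uniformly random spawn cell with a fresh heading.
#'
#' @param world a `grid_world`.
#' @param agent list with `cell = c(row, col)`, `orientation`, `timestep`.
#' @param action action index 0--3 (A--D).
#' @param mapping integer vector of 4 result codes (one mapping row).
#' @return list with the updated `agent` and logical `goal_event`.
#' @export
step_agent <- function(world, agent, action, mapping) {
  stopifnot(action %in% 0:3)
  result <- mapping[action + 1]
  if (result == result_codes()["left"]) {
    agent$orientation <- (agent$orientation + 3L) %% 4L
  } else if (result == result_codes()["right"]) {
    agent$orientation <- (agent$orientation + 1L) %% 4L
  } else if (result == result_codes()["forward"]) {
    tgt <- agent$cell + .dir_offsets[agent$orientation + 1, ]
    if (tgt[1] >= 1 && tgt[1] <= world$nrow && tgt[2] >= 1 &&
        tgt[2] <= world$ncol && !world$wall[tgt[1], tgt[2]]) {
      agent$cell <- tgt
    }
  }
  agent$timestep <- agent$timestep + 1L
  goal_event <- all(agent$cell == world$goal)
  if (goal_event) {
    agent <- spawn_agent(world, agent$timestep)
  }
  list(agent = agent, goal_event = goal_event)
}

#' Place an agent at a random spawn cell
#' @param world a `grid_world`.
#' @param timestep starting timestep counter.
#' @return an agent list.
#' @export
spawn_agent <- function(world, timestep = 0L) {
  cell0 <- world$spawn0[sample.int(length(world$spawn0), 1)]
  row <- cell0 %/% world$ncol + 1L
  col <- cell0 %% world$ncol + 1L
  orient <- if (world$respawn_facing_arrow && !is.na(world$arrow[row, col])) {
    world$arrow[row, col]
  } else {
    sample(0:3, 1)
  }
  list(cell = c(row, col), orientation = orient, timestep = timestep)
}

#' Write a world as plain text
#'
#' Grid characters: `#` wall, `G` goal, `^ > v <` arrows, `.` open cell
#' without arrow; a JSON sidecar (same path + `.json`) stores the metadata.
#' @param world a `grid_world`.
#' @param path output file.
#' @export
write_world <- function(world, path) {
  chars <- matrix(".", world$nrow, world$ncol)
  chars[!is.na(world$arrow)] <-
    c("^", ">", "v", "<")[world$arrow[!is.na(world$arrow)] + 1]
  chars[world$wall] <- "#"
  chars[world$goal["row"], world$goal["col"]] <- "G"
  writeLines(apply(chars, 1, paste, collapse = ""), path)
  meta <- list(nrow = world$nrow, ncol = world$ncol,
               goal = unname(world$goal),
               spawn_distance = world$spawn_distance,
               respawn_facing_arrow = world$respawn_facing_arrow)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
}

#' Read a world written by [write_world()]
#' @param path file written by [write_world()].
#' @return a `grid_world` (fields recomputed from walls + goal).
#' @export
read_world <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  chars <- do.call(rbind, strsplit(lines, ""))
  wall <- chars == "#"
  goal <- (meta$goal[2] - 1L) * nrow(chars) + meta$goal[1]
  .finish_world(wall, goal, ncol(chars), nrow(chars), meta$spawn_distance,
                meta$respawn_facing_arrow)
}
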