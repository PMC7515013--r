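# World construction, sensor encoding, agent stepping and episodes.

test_that("all 24 action-result bijections are enumerated exactly once", {
  m <- action_mappings()
  expect_identical(dim(m), c(24L, 4L))
  expect_identical(nrow(unique(m)), 24L)
  for (r in 1:24) expect_setequal(m[r, ], 0:3)
})

test_that("a 5x5 open world has hand-checkable shortest-path fields", {
  # goal-centred world built deterministically from the fixture
  w <- make_fixture("open_world_5x5")
  # centre of the 3x3 open interior
  expect_identical(unname(w$goal), c(3L, 3L))
  expect_identical(w$dist[3, 3], 0L)
  expect_identical(w$dist[2, 2], 2L) # corner-adjacent interior cell
  expect_identical(w$dist[2, 3], 1L)
  # cells adjacent to the goal point straight at it
  expect_identical(w$arrow[2, 3], 2L) # south
  expect_identical(w$arrow[4, 3], 0L) # north
  expect_identical(w$arrow[3, 2], 1L) # east
  expect_identical(w$arrow[3, 4], 3L) # west
  # every arrow target is exactly one step closer (direction-field law)
  off <- rbind(c(-1, 0), c(0, 1), c(1, 0), c(0, -1))
  for (r in 1:5) for (c in 1:5) {
    a <- w$arrow[r, c]
    if (is.na(a)) next
    tgt <- c(r, c) + off[a + 1, ]
    expect_identical(w$dist[tgt[1], tgt[2]], w$dist[r, c] - 1L)
  }
})

test_that("walled-off cells are excluded from spawn candidates", {
  wall <- matrix(FALSE, 7, 7)
  wall[c(1, 7), ] <- TRUE
  wall[, c(1, 7)] <- TRUE
  # isolate cell (3,5) completely
  wall[2, 5] <- wall[4, 5] <- wall[3, 4] <- wall[3, 6] <- TRUE
  w <- animats:::.finish_world(wall, goal = (2 - 1) * 7 + 3, # cell (3,2)
                               width = 7, height = 7, spawn_distance = 2,
                               respawn_facing_arrow = FALSE)
  expect_true(is.na(w$dist[3, 5]))
  isolated0 <- (3 - 1) * 7 + (5 - 1)
  expect_false(isolated0 %in% w$spawn0)
  expect_true(all(w$dist[cbind(w$spawn0 %/% 7 + 1, w$spawn0 %% 7 + 1)] == 2))
})

test_that("sensor encoding is one-hot over idle/right/forward/left", {
  expect_identical(sensor_encoding(3, 0), c(0L, 0L, 0L, 1L)) # left turn
  expect_identical(sensor_encoding(1, 1), c(0L, 0L, 1L, 0L)) # facing arrow
  expect_identical(sensor_encoding(2, 0), c(0L, 1L, 0L, 0L)) # 180: right
  expect_identical(sensor_encoding(0, 3), c(0L, 1L, 0L, 0L)) # 90 right
  expect_identical(sensor_encoding(NA, 2), c(1L, 0L, 0L, 0L)) # idle signal
  for (a in 0:3) for (o in 0:3) expect_identical(sum(sensor_encoding(a, o)), 1L)
})

test_that("agent stepping: turns, wall blocks, goal respawn", {
  w <- make_fixture("open_world_5x5")
  identity_map <- c(0L, 1L, 2L, 3L) # action k -> result k
  ag <- list(cell = c(2L, 2L), orientation = 0L, timestep = 0L)
  r <- step_agent(w, ag, 0L, identity_map) # left
  expect_identical(r$agent$orientation, 3L)
  expect_identical(r$agent$cell, c(2L, 2L))
  r <- step_agent(w, r$agent, 3L, identity_map) # forward into west wall
  expect_identical(r$agent$cell, c(2L, 2L))
  expect_false(r$goal_event)
  # idle changes nothing but the clock
  r2 <- step_agent(w, ag, 2L, identity_map)
  expect_identical(r2$agent$cell, ag$cell)
  expect_identical(r2$agent$orientation, ag$orientation)
  expect_identical(r2$agent$timestep, 1L)
  # stepping onto the goal respawns at spawn distance
  ag3 <- list(cell = c(2L, 3L), orientation = 2L, timestep = 0L) # above goal
  set.seed(91)
  r3 <- step_agent(w, ag3, 3L, identity_map)
  expect_true(r3$goal_event)
  expect_identical(w$dist[r3$agent$cell[1], r3$agent$cell[2]],
                   w$spawn_distance)
})

test_that("episodes account for every timestep and idle brains stay put", {
  w <- make_fixture("open_world_5x5")
  m <- action_mappings()
  # a brain with no gates always emits action A (motors 00); pick a mapping
  # whose action A is idle
  midle <- m[which(m[, 1] == result_codes()["idle"])[1], ]
  b <- build_brain(list())
  set.seed(101)
  ep <- run_episode(b, w, midle, lifetime = 100)
  expect_identical(ep$goals_reached, 0L)
  expect_identical(unname(ep$action_counts["idle"]), 100L)
  expect_identical(sum(ep$action_counts), 100L)
  expect_length(ep$state_trace, 101L)
})

test_that("the oracle policy on the corridor scores 16 per episode, 384 total", {
  w <- make_fixture("corridor_world")
  m <- action_mappings()
  set.seed(111)
  total <- 0L
  for (r in 1:24) {
    ep <- run_episode(oracle_brain(m[r, ]), w, m[r, ], lifetime = 512,
                      record_trace = FALSE)
    expect_identical(ep$goals_reached, 16L)
    total <- total + ep$goals_reached
  }
  expect_identical(total, 384L)
})

test_that("episodes are bit-reproducible under a fixed seed", {
  set.seed(121)
  w <- build_world(12, 12, obstacle_fraction = 0.05, spawn_distance = 5)
  g <- random_genome(4000)
  b <- decode_genome(g)
  m <- action_mappings()[3, ]
  set.seed(5)
  e1 <- run_episode(b, w, m, lifetime = 200)
  set.seed(5)
  e2 <- run_episode(b, w, m, lifetime = 200)
  expect_identical(e1$state_trace, e2$state_trace)
  expect_identical(e1$goals_reached, e2$goals_reached)
  expect_equal(e1$brain, e2$brain)
})

test_that("learning-disabled episodes leave gate tables untouched", {
  set.seed(131)
  w <- build_world(12, 12, spawn_distance = 5)
  b <- decode_genome(random_genome(5000), learning_enabled = FALSE)
  tables <- lapply(b$gates, `[[`, "table")
  ep <- run_episode(b, w, action_mappings()[2, ], lifetime = 200)
  expect_identical(lapply(ep$brain$gates, `[[`, "table"), tables)
})

test_that("evaluation resets the brain between the 24 mapping variants", {
  w <- make_fixture("corridor_world")
  set.seed(141)
  g <- random_genome(4000)
  ev <- evaluate_all_mappings(g, w, lifetime = 64)
  expect_length(ev$per_mapping, 24L)
  expect_identical(ev$g_total, sum(ev$per_mapping))
  # a gateless genome always emits action A: on the corridor it scores the
  # walking bound (64 / 32 = 2) exactly when the mapping sends A forward,
  # and nothing otherwise
  m <- action_mappings()
  ev0 <- evaluate_all_mappings(rep(0L, 1200), w, lifetime = 64)
  fwd <- m[, "A"] == result_codes()["forward"]
  expect_true(all(ev0$per_mapping[fwd] == 2L))
  expect_true(all(ev0$per_mapping[!fwd] == 0L))
})

test_that("world text serialisation round-trips the fields", {
  set.seed(151)
  w <- build_world(10, 8, obstacle_fraction = 0.1, spawn_distance = 3)
  path <- tempfile(fileext = ".txt")
  write_world(w, path)
  w2 <- read_world(path)
  expect_identical(w2$wall, w$wall)
  expect_identical(w2$dist, w$dist)
  expect_identical(w2$arrow, w$arrow)
  expect_identical(w2$goal, w$goal)
  expect_identical(w2$spawn0, w$spawn0)
})
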