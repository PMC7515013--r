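# Gate semantics: factor <-> row conversions, firing, feedback learning,
# and gate-level mutual information.

test_that("rows are outer products of per-bit probabilities", {
  expect_equal(row_from_factors(c(0.4, 0.4)), c(0.36, 0.24, 0.24, 0.16))
  expect_equal(row_from_factors(0), c(1, 0))
  expect_equal(row_from_factors(c(1, 1)), c(0, 0, 0, 1))
  expect_equal(sum(row_from_factors(c(0.13, 0.77, 0.5))), 1)
  expect_error(row_from_factors(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("factor recovery inverts row construction and flags dependence", {
  expect_equal(factors_from_row(c(0.36, 0.24, 0.24, 0.16)), c(0.4, 0.4))
  expect_equal(factors_from_row(c(1, 0, 0, 0)), c(0, 0))
  # XOR-correlated bits: marginals exist but no factorisation does
  expect_null(factors_from_row(c(0.02, 0.48, 0.48, 0.02)))
  expect_error(factors_from_row(c(0.3, 0.3)), "sum to 1")
})

test_that("factor round trip holds across the clamped range", {
  set.seed(11)
  for (rep in 1:50) {
    o <- sample(1:3, 1)
    f <- runif(o, 0.01, 0.99)
    expect_equal(factors_from_row(row_from_factors(f)), f, tolerance = 1e-12)
  }
})

test_that("deterministic gates fire their unique output, ignoring the RNG", {
  g <- deterministic_gate(c(1, 2), c(3, 4), c(2L, 2L, 2L, 2L))
  set.seed(1)
  r1 <- gate_update(g, 3)
  set.seed(99)
  r2 <- gate_update(g, 3)
  expect_identical(r1$output, 2L)
  expect_identical(r2$output, 2L)
})

test_that("probabilistic firing is seed-reproducible and unbiased", {
  g <- decomposable_gate(1, 2, matrix(0.5, 2, 1))
  set.seed(5)
  a <- replicate(20, gate_update(g, 0)$output)
  set.seed(5)
  b <- replicate(20, gate_update(g, 0)$output)
  expect_identical(a, b)
  set.seed(6)
  draws <- replicate(10000, gate_update(g, 1)$output)
  expect_lt(abs(mean(draws) - 0.5), 0.02)
})

test_that("feedback moves factors toward/away from the emitted bits", {
  g <- feedback_gate(1, 2, matrix(0.5, 2, 1), pos_node = 3, neg_node = 4,
                     history_length = 1L, pos_deltas = 0.1, neg_deltas = 0.1)
  set.seed(2)
  r <- gate_update(g, 0)
  g <- r$gate
  bit <- r$output
  gp <- apply_feedback(g, "positive")
  gn <- apply_feedback(g, "negative")
  expect_equal(gp$factors[1, 1], if (bit == 1) 0.6 else 0.4)
  expect_equal(gn$factors[1, 1], if (bit == 1) 0.4 else 0.6)
  # the rebuilt row matches the new factors
  expect_equal(gp$table[1, ], row_from_factors(gp$factors[1, ]))
  # the unfired input pattern's row is untouched
  expect_equal(gp$table[2, ], g$table[2, ])
})

test_that("feedback clamps factors away from 0 and 1", {
  g <- feedback_gate(1, 2, matrix(0.95, 2, 1), pos_node = 3, neg_node = 4,
                     history_length = 1L, pos_deltas = 0.1, neg_deltas = 0.1)
  g$history <- matrix(c(0L, 1L), 1) # emitted bit 1 on input pattern 0
  for (k in 1:5) g <- apply_feedback(g, "positive")
  expect_equal(g$factors[1, 1], 0.99)
  for (k in 1:30) g <- apply_feedback(g, "negative")
  expect_equal(g$factors[1, 1], 0.01)
})

test_that("feedback reaches all remembered decisions with per-depth deltas", {
  g <- feedback_gate(c(1, 2), 3, matrix(0.5, 4, 1), pos_node = 4,
                     neg_node = 5, history_length = 3L,
                     pos_deltas = c(0.1, 0.05, 0.02), neg_deltas = 0.1)
  # most recent first: (pattern 0, bit 1), (pattern 1, bit 1), (pattern 2, bit 0)
  g$history <- matrix(c(0L, 1L, 1L, 1L, 2L, 0L), ncol = 2, byrow = TRUE)
  g2 <- apply_feedback(g, "positive")
  expect_equal(g2$factors[1, 1], 0.6)   # depth-1 delta 0.1 toward 1
  expect_equal(g2$factors[2, 1], 0.55)  # depth-2 delta 0.05 toward 1
  expect_equal(g2$factors[3, 1], 0.48)  # depth-3 delta 0.02 toward 0
  expect_equal(g2$factors[4, 1], 0.5)   # never fired
})

test_that("feedback with empty history is a no-op", {
  g <- feedback_gate(1, 2, matrix(0.5, 2, 1), pos_node = 3, neg_node = 4)
  expect_message(g2 <- apply_feedback(g, "positive"), "no-op")
  expect_equal(g2$table, g$table)
})

test_that("repeated reinforcement sharpens a row until the clamp", {
  g <- feedback_gate(1, 1, matrix(0.5, 2, 1), pos_node = 2, neg_node = 3,
                     history_length = 1L, pos_deltas = 0.05)
  g$history <- matrix(c(0L, 1L), 1)
  ent <- entropy_longhand(g$table[1, ])
  for (k in 1:10) { # 0.5 -> 0.95 in steps, then clamped at 0.99
    g <- apply_feedback(g, "positive")
    e2 <- entropy_longhand(g$table[1, ])
    expect_lt(e2, ent)
    ent <- e2
  }
  g2 <- apply_feedback(g, "positive") # factor pinned at 0.99
  expect_equal(entropy_longhand(g2$table[1, ]), ent)
})

test_that("legacy feedback shifts row mass and renormalises", {
  g <- legacy_feedback_gate(1, c(2, 3), matrix(0.25, 2, 4),
                            pos_node = 4, neg_node = 5, history_length = 1L,
                            pos_deltas = 0.1, neg_deltas = 0.1)
  g$history <- matrix(c(0L, 2L), 1)
  set.seed(8)
  g2 <- apply_feedback(g, "positive")
  expect_equal(sum(g2$table[1, ]), 1, tolerance = 1e-9)
  expect_equal(g2$table[1, 3], 0.35)
  expect_equal(sum(g2$table[1, ] < 0.25), 1) # exactly one other entry paid
})

test_that("gate mutual information matches closed forms and the oracle", {
  bij <- deterministic_gate(c(1, 2), c(3, 4), c(0L, 1L, 2L, 3L))
  expect_equal(gate_mutual_information(bij), 2)
  flat <- decomposable_gate(c(1, 2), 3, matrix(0.3, 4, 1))
  expect_equal(gate_mutual_information(flat), 0)
  bsc <- legacy_feedback_gate(1, 2, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                                           byrow = TRUE),
                              pos_node = 3, neg_node = 4)
  hb <- -(0.9 * log2(0.9) + 0.1 * log2(0.1))
  expect_equal(gate_mutual_information(bsc), 1 - hb, tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:20) {
    ni <- sample(1:3, 1); no <- sample(1:3, 1)
    g <- decomposable_gate(sample(1:8, ni), sample(1:8, no),
                           matrix(runif(2^ni * no), 2^ni, no))
    mi <- gate_mutual_information(g)
    expect_equal(mi, gate_mi_bruteforce(g), tolerance = 1e-6)
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(ni, no) + 1e-12)
  }
})

test_that("gate JSON serialisation round-trips", {
  g <- feedback_gate(c(2, 7), c(5, 9), matrix(runif(8), 4, 2),
                     pos_node = 3, neg_node = 11, history_length = 2L,
                     pos_deltas = c(0.1, 0.2, 0.3), neg_deltas = 0.05)
  g2 <- gate_from_json(gate_to_json(g))
  expect_equal(g2$table, g$table, tolerance = 1e-15)
  expect_equal(g2$factors, g$factors, tolerance = 1e-15)
  expect_identical(g2$inputs, g$inputs)
  expect_identical(g2$pos_node, g$pos_node)
  expect_identical(g2$history_length, g$history_length)
  d <- deterministic_gate(1, 2, c(1L, 0L))
  expect_equal(gate_from_json(gate_to_json(d))$table, d$table)
})
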