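# Integrated-information measures: closed forms, the two assemblies,
# trace-based estimates, TPM construction and convergence.

test_that("closed-form systems match the brute-force oracle", {
  copy <- analytic_tpm(make_fixture("copy_brain"))
  swap <- analytic_tpm(make_fixture("swap_brain"))
  xorb <- analytic_tpm(make_fixture("xor_brain"))
  expect_equal(phi_atomic_from_tpm(copy)$phi_atomic, 0)
  expect_equal(phi_atomic_from_tpm(swap)$phi_atomic, 2)
  expect_equal(phi_atomic_from_tpm(xorb)$phi_atomic, 1)
  for (tp in list(copy, swap, xorb)) {
    expect_equal(phi_atomic_from_tpm(tp)$phi_atomic,
                 phi_bruteforce(tp$probs), tolerance = 1e-9)
  }
})

test_that("the two assemblies agree on random TPMs and inputs", {
  set.seed(201)
  for (rep in 1:100) {
    tp <- dense_tpm(random_tpm_matrix(3))
    d_unif <- abs(phi_atomic_eq3(tp)$phi_atomic -
                  phi_atomic_from_tpm(tp)$phi_atomic)
    expect_lt(d_unif, 1e-9)
    w <- runif(8)
    w <- w / sum(w)
    d_w <- abs(phi_atomic_eq3(tp, w)$phi_atomic -
               phi_atomic_from_tpm(tp, w)$phi_atomic)
    expect_lt(d_w, 1e-9)
  }
})

test_that("factorising systems carry exactly zero phi", {
  set.seed(211)
  # two independent biased coins: TPM factorises over nodes
  b <- build_brain(list(decomposable_gate(1, 1, matrix(0.4, 2, 1)),
                        decomposable_gate(2, 2, matrix(0.7, 2, 1))),
                   n_nodes = 2, n_sensors = 0, n_motors = 0)
  tp <- analytic_tpm(b)
  expect_equal(tp$probs[1, ], row_from_factors(c(0.7, 0.4)),
               tolerance = 1e-12) # node 2 is the high row bit
  res <- phi_atomic_eq3(tp)
  expect_equal(res$phi_atomic, 0, tolerance = 1e-12)
  expect_equal(res$I_sys, sum(res$per_node_I), tolerance = 1e-12)
  expect_equal(res$nonindependence, 0, tolerance = 1e-12)
})

test_that("phi components decompose as entropies should", {
  set.seed(221)
  tp <- dense_tpm(random_tpm_matrix(2))
  r <- phi_atomic_from_tpm(tp)
  # uniform input: H(Xt) = 2 bits, so I = H(Xt) - H(Xt|Xt+1)
  expect_equal(r$I_sys, 2 - r$joint_cond_H, tolerance = 1e-9)
  expect_equal(r$phi_atomic, sum(r$per_node_cond_H) - r$joint_cond_H,
               tolerance = 1e-12)
})

test_that("trace-based phi handles degenerate and sampled traces", {
  expect_error(phi_atomic_from_trace(3L, 2), "at least 2")
  # constant trace: all entropies vanish
  expect_equal(phi_atomic_from_trace(rep(5L, 40), 3)$phi_atomic, 0)
  # alternating 01 <-> 10: each node's next value is determined by its own
  # current value in this two-state orbit, so phi collapses to 0
  expect_equal(phi_atomic_from_trace(rep(c(1L, 2L), 30), 2)$phi_atomic, 0)
  # transitions of the swap system sampled at the uniform stationary
  # distribution (fresh uniform start each draw; a single trajectory would
  # stay on one two-state orbit) approach the TPM value of 2 bits
  set.seed(231)
  tpm <- analytic_tpm(make_fixture("swap_brain"))$probs
  s <- sample(0:3, 10000, replace = TRUE)
  t <- vapply(s, function(x) which(tpm[x + 1, ] == 1) - 1L, integer(1))
  expect_equal(phi_atomic_from_trace_pairs(s, t, 2)$phi_atomic, 2,
               tolerance = 0.05)
})

test_that("sampled TPMs converge to the analytic TPM at the MC rate", {
  set.seed(241)
  b <- build_brain(list(decomposable_gate(c(1, 2), c(2, 3),
                                          matrix(runif(8), 4, 2)),
                        deterministic_gate(3, 1, c(0L, 1L))),
                   n_nodes = 3, n_sensors = 0, n_motors = 0)
  exact <- analytic_tpm(b)$probs
  err_at <- function(k) {
    est <- sampled_tpm(b, k)$probs
    max(rowSums(abs(est - exact)))
  }
  e2 <- err_at(100L)
  e4 <- err_at(10000L)
  expect_lt(e4, e2) # more samples, smaller error
  # error should shrink roughly like 1/sqrt(k): a factor of 10 +/- slack
  expect_lt(e4, e2 / sqrt(100) * 4)
  expect_lt(e4, 0.05)
  # deterministic brains are recovered exactly from one sample
  det <- make_fixture("swap_brain")
  expect_equal(sampled_tpm(det, 1L)$probs, analytic_tpm(det)$probs)
  # same seed, same estimate
  set.seed(9)
  s1 <- sampled_tpm(b, 50L)$probs
  set.seed(9)
  s2 <- sampled_tpm(b, 50L)$probs
  expect_identical(s1, s2)
})

test_that("exact mode refuses oversized systems and points to sampling", {
  b <- decode_genome(random_genome(3000), n_nodes = 16)
  expect_error(analytic_tpm(b, max_nodes = 12), "sampled_tpm")
})

test_that("maximum-entropy phi is constant over the life of a static brain", {
  set.seed(251)
  # a brain from a genome restricted to non-learning gate types
  g <- random_genome(3000)
  b <- decode_genome(g, n_nodes = 8,
                     gate_set = c("deterministic", "decomposable"))
  w <- make_fixture("open_world_5x5")
  traj <- phi_maxh_trajectory(b, w, action_mappings()[4, ], lifetime = 200,
                              stride = 25)
  expect_identical(nrow(traj$trajectory), 200L %/% 25L + 1L)
  expect_lt(diff(range(traj$trajectory$phi)), 1e-12)
  expect_equal(traj$slope, 0, tolerance = 1e-12)
})

test_that("feedback learning moves the max-entropy phi trajectory", {
  # probe brain in a world that keeps its reinforcement sensor firing:
  # drive it by hand instead, snapshotting through an episode substitute
  set.seed(261)
  b <- make_fixture("feedback_probe_brain")
  phi0 <- phi_max_h(b)$phi_atomic
  for (k in 1:200) b <- brain_step(b, c(1, 0, 0, 0))$brain
  phi1 <- phi_max_h(b)$phi_atomic
  expect_false(isTRUE(all.equal(phi0, phi1)))
})

test_that("checkpoint schedule matches the stride arithmetic", {
  set.seed(271)
  b <- decode_genome(random_genome(2000), n_nodes = 8)
  w <- make_fixture("open_world_5x5")
  traj <- phi_maxh_trajectory(b, w, action_mappings()[1, ], lifetime = 512,
                              stride = 50)
  expect_identical(traj$trajectory$checkpoint, seq(0L, 500L, 50L))
  expect_identical(nrow(traj$trajectory), 11L)
})
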