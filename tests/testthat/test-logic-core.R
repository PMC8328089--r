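# Core engine: function evaluation, synchronous step, trajectory/cycle
# detection, canonicalization, packed-state encoding.

test_that("evaluate_function matches direct table lookup", {
  net <- and_gate()
  # constant function: any state -> the constant
  cn <- constant_net(2, value = 1L)
  expect_equal(evaluate_function(cn, "n1", c(n1 = 0L, n2 = 0L)), 1L)
  expect_equal(evaluate_function(cn, "n1", c(n1 = 1L, n2 = 1L)), 1L)
  # identity on one binary regulator
  idn <- logical_network(
    nodes = data.frame(name = c("X", "Y"), max_level = 1L,
                       role = c("input", "internal")),
    functions = list(Y = list(regulators = "X", table = c(0L, 1L))))
  expect_equal(evaluate_function(idn, "Y", c(X = 0L, Y = 1L)), 0L)
  # 2-regulator AND: checked against enumerating all four rows
  sts <- expand.grid(A = 0:1, B = 0:1)
  for (i in seq_len(nrow(sts))) {
    st <- c(A = sts$A[i], B = sts$B[i], C = 0L)
    expect_equal(evaluate_function(net, "C", st),
                 as.integer(sts$A[i] == 1 && sts$B[i] == 1))
  }
})

test_that("step is synchronous, holds inputs, and respects clamps", {
  # all-constant network reaches its constant vector in one step
  cn <- constant_net(3, value = 1L)
  expect_equal(unname(step(cn, c(0L, 0L, 0L))), c(1L, 1L, 1L))
  # hand-evaluated negation loop
  nl <- negation_loop()
  expect_equal(step(nl, c(A = 0L, B = 0L)), c(A = 1L, B = 0L))
  expect_equal(step(nl, c(A = 1L, B = 0L)), c(A = 1L, B = 1L))
  # clamp dominates the truth table
  s <- step(nl, c(A = 0L, B = 0L), clamp_set(A = 0))
  expect_equal(s[["A"]], 0L)
  # input nodes hold their value
  ag <- and_gate()
  s2 <- step(ag, c(A = 1L, B = 0L, C = 1L))
  expect_equal(s2[["A"]], 1L)
  expect_equal(s2[["B"]], 0L)
  expect_equal(s2[["C"]], 0L)
  # determinism: repeated calls agree exactly
  st <- c(A = 1L, B = 1L)
  expect_identical(step(nl, st), step(nl, st))
})

test_that("run_to_attractor finds cycles with correct transients", {
  cn <- constant_net(3)
  r <- run_to_attractor(cn, c(0L, 0L, 0L))
  expect_lte(r$transient, 1L)
  expect_equal(r$length, 1L)
  nl <- negation_loop()
  r2 <- run_to_attractor(nl, c(A = 0L, B = 0L))
  expect_equal(r2$transient, 0L)
  expect_equal(r2$length, 4L)
  # exhaustive 4-state check of the cycle order from (0,0)
  expect_equal(unname(r2$cycle),
               matrix(c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L), 4, 2, byrow = TRUE))
  # clamped trajectories keep the clamped level throughout the cycle
  r3 <- run_to_attractor(nl, c(A = 0L, B = 0L), clamp_set(A = 1))
  expect_true(all(r3$cycle[, "A"] == 1L))
  # max_steps exceeded errors loudly (cycle length 4 cannot fit in 2 steps)
  expect_error(run_to_attractor(nl, c(A = 0L, B = 0L), max_steps = 2L),
               "transient too long")
})

test_that("canonicalize rotates to the smallest packed state", {
  nl <- negation_loop()
  cyc <- run_to_attractor(nl, c(A = 1L, B = 1L))$cycle # entered mid-phase
  can <- canonicalize(nl, cyc)
  expect_equal(unname(can[1, ]), c(0L, 0L))
  # rotation invariance: canonicalize(rotate(cycle, r)) == canonicalize(cycle)
  for (r in 1:3) {
    rot <- cyc[c((r + 1):4, 1:r), , drop = FALSE]
    expect_equal(unname(canonicalize(nl, rot)), unname(can))
  }
  # length-1 cycle is its own canonical form
  cn <- constant_net(2)
  fp <- run_to_attractor(cn, c(1L, 1L))$cycle
  expect_equal(canonicalize(cn, fp)[1, ], fp[1, ])
  # a non-closed sequence is rejected
  expect_error(canonicalize(nl, matrix(c(0L, 0L, 1L, 1L), 2, 2, TRUE)),
               "not closed")
})

test_that("pack/unpack is an exact bijection on mixed radices", {
  net <- logical_network(
    nodes = data.frame(name = c("a", "b", "c"), max_level = c(3L, 1L, 2L)),
    functions = list(
      a = list(regulators = "a", table = c(0L, 1L, 2L, 3L)),
      b = list(regulators = "b", table = c(0L, 1L)),
      c = list(regulators = "c", table = c(0L, 1L, 2L))))
  S <- prod(net$nodes$max_level + 1)
  keys <- pack_states(net, unpack_states(net, 0:(S - 1)))
  expect_identical(keys, as.numeric(0:(S - 1)))
  # first node is the most significant digit
  expect_equal(pack_states(net, c(a = 1L, b = 0L, c = 0L)), 6)
  expect_equal(pack_states(net, c(a = 0L, b = 0L, c = 1L)), 1)
  # out-of-range levels are rejected
  expect_error(step(net, c(a = 4L, b = 0L, c = 0L)), "out of range")
})

test_that("trajectories are reproducible and clamp-invariant where expected", {
  set.seed(11)
  net <- random_network(8, k = 2, scheme = "uniform_random", seed = 7)
  sts <- all_states(net)[sample(256, 40), ]
  r1 <- vapply(seq_len(40), function(i)
    run_to_attractor(net, sts[i, ])$key, numeric(1))
  r2 <- vapply(seq_len(40), function(i)
    run_to_attractor(net, sts[i, ])$key, numeric(1))
  expect_identical(r1, r2)
})
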