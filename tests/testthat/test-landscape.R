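# Attractor discovery, classification into Spontaneous/Inducible/Negative,
# basin assignment; oracle equivalence against exhaustive enumeration.

test_that("full-coverage discovery equals the exhaustive oracle", {
  # attractor sets AND basin partitions must match the brute-force oracle
  # when every state is used as a restart (deterministic full coverage)
  for (seed in 1:20) {
    m <- random_network(8, max_levels = c(2, rep(1, 7)), k = c(1, 3),
                        scheme = "uniform_random", seed = seed)
    bf <- brute_force_landscape(m)
    sts <- all_states(m)
    cm <- acrodyn:::compile_model(m)
    tr <- acrodyn:::cpp_trajectories(cm, sts, integer(0), integer(0), 10000L)
    expect_setequal(unique(tr$key), bf$key)
    # identical partition: states sharing a basin under the oracle share keys
    expect_equal(tr$key, bf$key[bf$basin])
  }
})

test_that("sampled discovery converges to the oracle attractor set", {
  for (seed in c(2, 9)) {
    m <- random_network(7, k = 2, scheme = "uniform_random", seed = seed)
    bf <- brute_force_landscape(m)
    ls <- discover_attractors(m, n_samples = 5e4, n_confirm = 2000,
                              seed = seed, constraints = NULL)
    expect_true(ls$discovery$converged)
    expect_setequal(ls$key, bf$key)
  }
})

test_that("discovery is reproducible and flags non-convergence", {
  m <- random_network(8, k = 2, scheme = "uniform_random", seed = 4)
  a <- discover_attractors(m, n_samples = 500, n_confirm = 200, seed = 1,
                           constraints = NULL)
  b <- discover_attractors(m, n_samples = 500, n_confirm = 200, seed = 1,
                           constraints = NULL)
  expect_identical(a$key, b$key)
  expect_identical(a$discovery$n_drawn, b$discovery$n_drawn)
  tiny <- discover_attractors(m, n_samples = 3, n_confirm = 1e6, seed = 1,
                              constraints = NULL)
  expect_false(tiny$discovery$converged)
})

test_that("classification follows the progesterone-response rules", {
  toy <- pg_toy()
  # Pg = 0 attractor of the toy never fuses on its own but fuses after Pg
  ls <- discover_attractors(toy, clamp_set(Pg = 0), n_samples = 100,
                            n_confirm = 20, seed = 1, constraints = NULL)
  ls <- classify_landscape(toy, ls)
  expect_equal(unname(ls$classes), rep("Inducible", length(ls$classes)))
  # an attractor containing Fusion = 1 short-circuits to Spontaneous
  fused <- run_to_attractor(toy, c(Pg = 0L, Relay = 1L, Fusion = 1L))
  fused$cycle[, "Fusion"] <- 1L # synthetic fused cycle state
  cl <- classify_attractor(toy, fused)
  expect_equal(cl$class, "Spontaneous")
  expect_null(cl$targets)
  # attractors computed under Pg = 1 are rejected
  bad <- run_to_attractor(toy, c(Pg = 1L, Relay = 1L, Fusion = 1L))
  expect_error(classify_attractor(toy, bad), "Pg")
})

test_that("a toy without a fusion route is Negative", {
  m <- logical_network(
    nodes = data.frame(name = c("Pg", "Fusion"), max_level = 1L,
                       role = c("input", "reporter")),
    functions = list(Fusion = list(regulators = "Fusion",
                                   table = c(0L, 0L))))
  ls <- classify_landscape(m,
    discover_attractors(m, clamp_set(Pg = 0), 50, 10, seed = 1,
                        constraints = NULL))
  expect_equal(unname(ls$classes), rep("Negative", length(ls$classes)))
})

test_that("assign_basin partitions states and extends on novelty", {
  m <- random_network(7, k = 2, scheme = "uniform_random", seed = 12)
  bf <- brute_force_landscape(m)
  ls <- discover_attractors(m, n_samples = 2e4, n_confirm = 1000, seed = 3,
                            constraints = NULL)
  sts <- all_states(m)
  # attractor states belong to their own basin with transient 0
  a1 <- ls$attractors[[1]]
  r <- assign_basin(m, a1$cycle[1, ], ls)
  expect_equal(r$key, names(ls$attractors)[1])
  expect_equal(r$transient, 0L)
  # two states on the same trajectory share a basin
  s0 <- sts[17, ]
  s1 <- step(m, s0)
  expect_equal(assign_basin(m, s0, ls)$key, assign_basin(m, s1, ls)$key)
  # every state maps to exactly one oracle basin (partition property)
  cm <- acrodyn:::compile_model(m)
  tr <- acrodyn:::cpp_trajectories(cm, sts, integer(0), integer(0), 10000L)
  expect_equal(length(tr$key), nrow(sts))
  expect_setequal(unique(tr$key), bf$key)
})

test_that("attractors discovered under a clamp hold the clamped level", {
  ar <- ar_network()
  ls <- discover_attractors(ar, ar_protocol(0, pH_a = 0L),
                            n_samples = 5e3, n_confirm = 1e3, seed = 2)
  for (a in ls$attractors) expect_true(all(a$cycle[, "pH_a"] == 0L))
})

test_that("classification is invariant under node reordering", {
  m <- pg_toy()
  perm <- c(3, 1, 2)
  m2 <- logical_network(
    nodes = m$nodes[perm, ],
    functions = m$functions,
    name = "pg_toy_permuted")
  for (st in list(c(Pg = 0L, Relay = 0L, Fusion = 0L),
                  c(Pg = 0L, Relay = 1L, Fusion = 0L))) {
    c1 <- classify_attractor(m, run_to_attractor(m, st))
    c2 <- classify_attractor(m2, run_to_attractor(m2, st[names(st)]))
    expect_equal(c1$class, c2$class)
  }
})
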