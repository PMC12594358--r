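test_that("random system generation respects edge probability limits and is reproducible", {
  full <- generate_random_system(5, edge_prob = 1.0, seed = 42)
  expect_equal(nrow(full$edges), 10L)
  empty <- generate_random_system(5, edge_prob = 0.0, seed = 42)
  expect_equal(nrow(empty$edges), 0L)

  a <- generate_random_system(6, seed = 7)
  b <- generate_random_system(6, seed = 7)
  expect_identical(a, b)
  expect_true(all(abs(a$state) == 1))
  expect_gt(a$temperature, 0.1 - 1e-12)
  expect_lt(a$temperature, 3.0 + 1e-12)
  expect_true(all(a$edges[, 1L] < a$edges[, 2L]))
})

test_that("spec construction rejects invalid inputs", {
  expect_error(generate_random_system(1, seed = 1), "n must be")
  expect_error(generate_random_system(5, edge_prob = 1.5, seed = 1), "edge_prob")
  expect_error(generate_random_system(5, t_range = c(3, 1), seed = 1), "t_range")
  expect_error(system_spec(3, matrix(c(1L, 1L), 1), 0.5, 1, c(1, -1, 1)),
               "self-loops")
  expect_error(system_spec(3, matrix(c(1L, 2L), 1), c(0.5, 0.3), 1, c(1, -1, 1)),
               "exactly one weight")
  expect_error(system_spec(3, matrix(c(1L, 2L), 1), 0.5, 1, c(1, 0, 1)),
               "state")
})

test_that("conditional probabilities follow the Boltzmann rule and normalise", {
  # isolated node: tau = 0 so both states are equally likely
  iso <- system_spec(2, matrix(integer(0), ncol = 2), numeric(0), 1.0, c(1, -1))
  expect_equal(conditional_probability(iso, 1, +1), 0.5)
  expect_equal(conditional_probability(iso, 1, -1), 0.5)

  # single neighbour J = 1, S_j = +1, T = 1: p(+1) = 1/(1+e^-2)
  pair <- system_spec(2, matrix(c(1L, 2L), 1), 1.0, 1.0, c(1, 1))
  expect_equal(conditional_probability(pair, 1, +1), 1 / (1 + exp(-2)),
               tolerance = 1e-12)

  # normalisation is exact for arbitrary systems
  for (k in 1:10) {
    sp <- generate_random_system(5, seed = k)
    i <- sample(5, 1)
    expect_identical(conditional_probability(sp, i, +1) +
                       conditional_probability(sp, i, -1), 1)
  }
})

test_that("the transition model is a proper stochastic model with inversion symmetry", {
  # N = 1, no edges: p(+1) = 0.5 for both rows
  one <- system_spec(1, matrix(integer(0), ncol = 2), numeric(0), 1.0, 1)
  tm1 <- build_transition_model(one)
  expect_equal(tm1$tpm, matrix(0.5, 2, 1))

  # N = 2, no edges: every full-state transition probability is 0.25
  two <- system_spec(2, matrix(integer(0), ncol = 2), numeric(0), 2.0, c(1, -1))
  P2 <- state_transition_matrix(build_transition_model(two))
  expect_equal(as.numeric(P2), rep(0.25, 16))

  # full-transition rows sum to 1
  sp <- generate_random_system(4, seed = 9)
  P <- state_transition_matrix(build_transition_model(sp))
  expect_equal(rowSums(P), rep(1, 16), tolerance = 1e-12)

  # p(S*|S) = p(-S*|-S): flipping a state reverses the row order
  for (k in 1:20) {
    n <- sample(2:6, 1)
    spk <- generate_random_system(n, seed = 100 + k)
    Pk <- state_transition_matrix(build_transition_model(spk))
    flip <- rev(seq_len(2^n))
    expect_lt(max(abs(Pk - Pk[flip, flip])), 1e-12)
  }
})

test_that("state ordering of the transition table is little-endian", {
  # node 1 varies fastest; bit 1 maps to state +1
  S <- phinet:::enumerate_states(3)
  expect_equal(S[1, ], c(-1, -1, -1))
  expect_equal(S[2, ], c(+1, -1, -1))
  expect_equal(S[3, ], c(-1, +1, -1))
  expect_equal(S[8, ], c(+1, +1, +1))
  expect_equal(phinet:::state_row_index(c(+1, -1, -1)), 2L)
  # tpm row at the assigned state matches the direct conditionals
  sp <- generate_random_system(4, seed = 3)
  tm <- build_transition_model(sp)
  r <- phinet:::state_row_index(sp$state)
  direct <- vapply(1:4, function(i) conditional_probability(sp, i, +1),
                   numeric(1))
  expect_equal(tm$tpm[r, ], direct, tolerance = 1e-14)
})

test_that("generated edge counts match their binomial expectation", {
  counts <- vapply(1:2000, function(k)
    nrow(generate_random_system(7, edge_prob = 0.4, seed = k)$edges),
    numeric(1))
  se <- sqrt(21 * 0.4 * 0.6 / length(counts))
  expect_lt(abs(mean(counts) - 0.4 * 21), 3 * se)
})

test_that("special topologies have the stated edge counts and cycle structure", {
  tr <- generate_topology("tree", 5, seed = 1)
  expect_equal(nrow(tr$edges), 4L)
  g <- igraph::graph_from_edgelist(tr$edges, directed = FALSE)
  expect_equal(igraph::count_components(g), 1)   # spanning tree: connected
  expect_equal(igraph::gsize(g), igraph::vcount(g) - 1)  # acyclic

  expect_equal(nrow(generate_topology("full", 5, seed = 2)$edges), 10L)

  lp7 <- generate_topology("loop", 7, seed = 3)
  expect_equal(nrow(lp7$edges), 8L)            # round(0.4 * 21)
  lp6 <- generate_topology("loop", 6, seed = 3)
  expect_equal(nrow(lp6$edges), 6L)
  for (n in 4:5) {
    lp <- generate_topology("loop", n, seed = 4)
    expect_equal(nrow(lp$edges), n + 1L)
    gl <- igraph::graph_from_edgelist(lp$edges, directed = FALSE)
    # must contain at least one cycle
    expect_gt(igraph::gsize(gl) -
                (igraph::vcount(gl) - igraph::count_components(gl)), 0)
  }
  expect_error(generate_topology("star", 5, seed = 1))
})

test_that("tree sampling covers distinct spanning trees", {
  keys <- vapply(1:30, function(k) {
    e <- generate_topology("tree", 5, seed = k)$edges
    paste(e[, 1], e[, 2], sep = "-", collapse = ",")
  }, character(1))
  expect_gt(length(unique(keys)), 10)
})

test_that("split-brain systems have the stated block structure", {
  sb0 <- generate_split_brain(0, seed = 1)
  expect_equal(sb0$n_nodes, 100L)
  blocks <- sb0$meta$blocks
  cross0 <- sum(sb0$edges[, 1L] <= 50 & sb0$edges[, 2L] > 50)
  expect_equal(cross0, 0L)

  sb1 <- generate_split_brain(1, seed = 1)
  cross1 <- sum(sb1$edges[, 1L] <= 50 & sb1$edges[, 2L] > 50)
  expect_equal(cross1, 2500L)

  # binomial expectation of the inter-block count at p_e = 0.02
  crosses <- vapply(1:300, function(k) {
    sb <- generate_split_brain(0.02, seed = k)
    sum(sb$edges[, 1L] <= 50 & sb$edges[, 2L] > 50)
  }, numeric(1))
  se <- sqrt(2500 * 0.02 * 0.98 / length(crosses))
  expect_lt(abs(mean(crosses) - 50), 3 * se)
})

test_that("state simulation produces valid trajectories", {
  sp <- generate_random_system(5, seed = 2)
  tr <- simulate_states(sp, nsteps = 20, seed = 3)
  expect_equal(dim(tr), c(21L, 5L))
  expect_true(all(abs(tr) == 1))
  expect_identical(tr[1, ], sp$state)
  expect_identical(simulate_states(sp, 20, seed = 3), tr)
})
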