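test_that("attention weights are normalised per node and head", {
  cfg <- phinet_config(d_in = 4, channels = 4, heads = 3)
  init <- init_params(cfg, seed = 2)
  layer <- init$params$conv[[1]]
  g <- toy_graph(6, edges = cbind(c(1, 1, 2, 4), c(2, 3, 3, 5)), d = 4,
                 seed = 3)
  aw <- attention_weights(layer, g, g$x, cfg)
  expect_equal(nrow(aw$alpha), ncol(g$edge_index))
  sums <- rowsum(aw$alpha, aw$dst)
  expect_equal(as.numeric(sums), rep(1, length(unique(aw$dst)) * 3),
               tolerance = 1e-6)
  # node 6 has no neighbours: absent from the attention map
  expect_false(6 %in% aw$dst)
  # node with exactly one neighbour: its single weight is 1 in every head
  one_nb <- aw$alpha[aw$dst == 5, , drop = FALSE]
  expect_equal(as.numeric(one_nb), rep(1, 3))
  expect_error(attention_weights(layer, g, g$x[, 1:2], cfg), "dimension")
})

test_that("two neighbours with identical keys, values and edge features split attention evenly", {
  cfg <- phinet_config(d_in = 3, channels = 2, heads = 2)
  init <- init_params(cfg, seed = 5)
  layer <- init$params$conv[[1]]
  x <- rbind(c(1, 2, -1), c(0.3, -0.7, 0.2), c(0.3, -0.7, 0.2))
  g <- structure(list(n = 3L, x = x,
                      edge_index = rbind(c(2L, 3L, 1L, 1L), c(1L, 1L, 2L, 3L)),
                      edge_attr = matrix(c(0.4, 0.4, 0.4, 0.4), ncol = 1),
                      graph = rep(1L, 3)), class = "feature_graph")
  aw <- attention_weights(layer, g, x, cfg)
  to1 <- aw$alpha[aw$dst == 1, , drop = FALSE]
  expect_equal(as.numeric(to1), rep(0.5, 4), tolerance = 1e-12)
})

test_that("a single transformer layer matches its closed form on a 2-node instance", {
  # d = 2, C = 2, H = 1, identity maps, kappa = C/H = 2
  cfg <- phinet_config(d_in = 2, channels = 2, heads = 1)
  expect_equal(cfg$kappa, 2)
  I2 <- diag(2)
  x <- rbind(c(0.6, -0.2), c(-1.1, 0.8))
  e <- 0.7
  We <- matrix(c(0.5, -0.25), 1, 2)
  layer <- list(Wq = I2, Wk = I2, Wv = I2, Wo = I2, We = We)
  g <- structure(list(n = 2L, x = x,
                      edge_index = rbind(c(1L, 2L), c(2L, 1L)),
                      edge_attr = matrix(c(e, e), ncol = 1),
                      graph = rep(1L, 2)), class = "feature_graph")
  z <- transformer_layer(layer, g, x, cfg)
  # single neighbour: softmax over one score is 1, so
  # z_i = x_i + (x_j + We * e)
  expect_equal(z[1, ], x[1, ] + x[2, ] + as.numeric(We) * e, tolerance = 1e-12)
  expect_equal(z[2, ], x[2, ] + x[1, ] + as.numeric(We) * e, tolerance = 1e-12)

  # with zero edge feature the update reduces to x_i + x_j
  g0 <- g; g0$edge_attr <- matrix(c(0, 0), ncol = 1)
  z0 <- transformer_layer(layer, g0, x, cfg)
  expect_equal(z0, x + x[2:1, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("an edge-free graph passes only through the skip transform", {
  cfg <- phinet_config(d_in = 3, channels = 4, heads = 2)
  init <- init_params(cfg, seed = 4)
  layer <- init$params$conv[[1]]
  g <- toy_graph(4, edges = NULL, d = 3, seed = 8)
  z <- transformer_layer(layer, g, g$x, cfg)
  expect_equal(z, g$x %*% layer$Wo, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("global max pooling and pooled subtraction behave as defined", {
  z <- matrix(c(1, 3, -2, 0.5, 2, 7), 3, 2)
  pool <- global_max_pool(z, rep(1L, 3))
  expect_equal(as.numeric(pool$r), c(3, 7))
  u <- subtract_pooled(z, pool$r, rep(1L, 3))
  expect_true(all(u <= 0))
  # single-node graph: r = z and the difference is exactly zero
  p1 <- global_max_pool(z[1, , drop = FALSE], 1L)
  expect_equal(as.numeric(p1$r), z[1, ])
  expect_equal(as.numeric(subtract_pooled(z[1, , drop = FALSE], p1$r, 1L)),
               c(0, 0))
  # max is monotone under adding a node
  z2 <- rbind(z, c(10, -10))
  p2 <- global_max_pool(z2, rep(1L, 4))
  expect_true(all(p2$r >= pool$r))
  expect_error(global_max_pool(z[0, , drop = FALSE], integer(0)), "empty")
})

test_that("the forward pass is permutation invariant/equivariant", {
  model <- toy_model(d = 6, channels = 4, heads = 2, layers = 3, seed = 6)
  for (k in 1:20) {
    sp <- generate_random_system(sample(4:7, 1), seed = 1200 + k)
    fg <- node_features(sp)
    out <- nn_forward(model, fg)
    for (r in 1:5) {
      perm <- sample(sp$n_nodes)
      fgp <- node_features(permute_spec(sp, perm))
      outp <- nn_forward(model, fgp)
      expect_equal(outp$phi_hat, out$phi_hat, tolerance = 1e-5)
      expect_equal(outp$prob_in[perm], out$prob_in, tolerance = 1e-5)
    }
  }
})

test_that("the full pipeline is exactly invariant under state inversion", {
  model <- toy_model(seed = 7)
  for (k in 1:10) {
    sp <- generate_random_system(5, seed = 1300 + k)
    flipped <- sp
    flipped$state <- -sp$state
    o1 <- nn_forward(model, node_features(sp))
    o2 <- nn_forward(model, node_features(flipped))
    expect_identical(o1$phi_hat, o2$phi_hat)
    expect_identical(o1$prob_in, o2$prob_in)
  }
})

test_that("joint processing of disconnected components reproduces standalone embeddings", {
  model <- toy_model(d = 6, channels = 4, heads = 2, layers = 4, seed = 9)
  for (k in 1:5) {
    a <- node_features(generate_random_system(4, seed = 1400 + k))
    b <- node_features(generate_random_system(5, seed = 1500 + k))
    za <- nn_forward(model, a)$z
    zb <- nn_forward(model, b)$z
    joint <- batch_graphs(list(a, b))
    joint$graph <- rep(1L, joint$n)   # evaluated as one disconnected system
    zj <- nn_forward(model, joint)$z
    expect_equal(zj[1:4, ], za, tolerance = 1e-5)
    expect_equal(zj[5:9, ], zb, tolerance = 1e-5)
  }
})

test_that("symmetric nodes receive identical membership probabilities", {
  # complete graph with equal weights and uniform state: all nodes equivalent
  n <- 4
  edges <- t(combn(n, 2))
  sp <- system_spec(n, edges, rep(0.8, nrow(edges)), 1.5, rep(1, n))
  model <- toy_model(seed = 10)
  out <- nn_forward(model, node_features(sp))
  expect_equal(max(out$prob_in) - min(out$prob_in), 0, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  cfg <- phinet_config(d_in = 3, channels = 3, heads = 2, layers = 2,
                       dropout = 0)
  init <- init_params(cfg, seed = 11)
  model <- list(params = init$params, bn_state = init$bn_state, config = cfg)
  g1 <- toy_graph(4, edges = cbind(c(1, 2, 3), c(2, 3, 4)), d = 3, seed = 12)
  g2 <- toy_graph(3, edges = cbind(1, 2), d = 3, seed = 13)
  batch <- batch_graphs(list(g1, g2))
  batch$graph <- c(rep(1L, 4), rep(2L, 3))
  phi <- c(0.7, 1.3)
  y_in <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  lossfn <- function(m) {
    fwd <- nn_forward(m, batch, train = TRUE)
    as.numeric(composite_loss(fwd$phi_hat, phi, fwd$prob, y_in))
  }
  fwd <- nn_forward(model, batch, train = TRUE, keep_cache = TRUE)
  grads <- phinet:::nn_backward(model, fwd, phi, y_in)
  flat_g <- phinet:::par_flatten(grads)
  flat_p <- phinet:::par_flatten(model$params)
  set.seed(14)
  idx <- sort(sample(length(flat_p), 50))
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    pp <- flat_p
    pp[i] <- flat_p[i] + eps
    m2 <- model
    m2$params <- phinet:::par_unflatten(model$params, pp)$p
    up <- lossfn(m2)
    pp[i] <- flat_p[i] - eps
    m2$params <- phinet:::par_unflatten(model$params, pp)$p
    (up - lossfn(m2)) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - flat_g[idx]) / pmax(1e-6, abs(num) + abs(flat_g[idx]))
  expect_lt(max(rel), 1e-4)
})
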