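test_that("the composite loss matches hand-computed values", {
  # perfect prediction: both terms vanish
  prob_perfect <- rbind(c(1 - 1e-12, 1e-12), c(1e-12, 1 - 1e-12))
  l0 <- composite_loss(phi_hat = 1.2, phi = 1.2, prob = prob_perfect,
                       y_in = c(TRUE, FALSE))
  expect_lt(as.numeric(l0), 1e-10)

  # correct classification, phi off by delta: loss = delta^2
  delta <- 0.37
  l1 <- composite_loss(1.2 + delta, 1.2, prob_perfect, c(TRUE, FALSE))
  expect_equal(as.numeric(l1), delta^2, tolerance = 1e-9)

  # two nodes at probability 0.5 each, one in / one out, no phi error:
  # loss = 5 * (-ln 0.5) * (1 + 1.8) / 2
  prob_half <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  l2 <- composite_loss(1, 1, prob_half, c(TRUE, FALSE))
  expect_equal(as.numeric(l2), 5 * (-log(0.5)) * (1 + 1.8) / 2,
               tolerance = 1e-12)
  expect_equal(attr(l2, "mse"), 0)
})

test_that("disconnected-pair augmentation obeys the max-phi and loser-out rules", {
  specs <- lapply(1:40, function(k) generate_random_system(4, seed = 1600 + k))
  labels <- label_dataset(specs)
  dataset <- make_labeled_graphs(specs, labels)
  aug <- augment_disconnected_pairs(dataset, fraction = 0.10, seed = 5)
  n_new <- length(aug) - length(dataset)
  expect_equal(n_new, round(0.10 * length(dataset)))
  phis <- vapply(dataset, `[[`, numeric(1), "phi")
  for (k in seq.int(length(dataset) + 1L, length(aug))) {
    comp <- aug[[k]]
    expect_identical(comp$provenance, "augmented")
    # composite phi equals the max over two existing graphs
    expect_true(any(abs(phis - comp$phi) < 1e-15))
    # the loser's nodes are all "out": the in-nodes must lie inside one
    # 4-node block and match a source graph with that phi
    n_nodes <- comp$fg$n
    expect_equal(n_nodes, 8L)
    in_nodes <- which(comp$y_in)
    expect_true(all(in_nodes <= 4))
    # no cross edges between the two blocks
    ei <- comp$fg$edge_index
    expect_false(any(ei[1, ] <= 4 & ei[2, ] > 4))
    expect_false(any(ei[1, ] > 4 & ei[2, ] <= 4))
    # the winner block carries the winner's own node labels
    src <- which(abs(phis - comp$phi) < 1e-15)[1]
    expect_equal(comp$y_in[1:4], dataset[[src]]$y_in)
  }
  # fraction 0 leaves the dataset untouched
  expect_identical(augment_disconnected_pairs(dataset, 0, seed = 1), dataset)
})

test_that("augmentation composites pair two distinct graphs", {
  # graphs are distinguishable by their temperature column
  specs <- lapply(1:10, function(k) generate_random_system(3, seed = 1700 + k))
  dataset <- make_labeled_graphs(specs, label_dataset(specs))
  for (s in 1:20) {
    aug <- augment_disconnected_pairs(dataset, 0.3, seed = s)
    for (k in seq.int(length(dataset) + 1L, length(aug))) {
      temps <- unique(aug[[k]]$fg$x[, "T"])
      expect_length(temps, 2L)
    }
  }
})

test_that("oversampling equalises the target bins with perturbed duplicates", {
  # two well-separated clusters of sizes 100 and 20
  mk <- function(phi, seed) {
    fg <- node_features(generate_random_system(3, seed = seed))
    labeled <- list(fg = fg, phi = phi, y_in = c(TRUE, TRUE, FALSE),
                    provenance = "real")
    labeled
  }
  set.seed(21)
  dataset <- c(lapply(1:100, function(k) mk(0.1 + 0.01 * rnorm(1), k)),
               lapply(1:20, function(k) mk(5 + 0.01 * rnorm(1), 200 + k)))
  out <- oversample_by_phi(dataset, k = 2, noise_level = 0.05, seed = 3)
  expect_length(out, 200L)
  prov <- vapply(out, `[[`, character(1), "provenance")
  expect_equal(sum(prov == "oversampled"), 80L)
  # duplicates come from the small bin and are perturbed within 5%
  dup_phis <- vapply(out[prov == "oversampled"], `[[`, numeric(1), "phi")
  expect_true(all(dup_phis > 4 * 0.95))
  expect_true(all(dup_phis < 5.2 * 1.05))
  # originals are untouched (apart from the recorded bin id)
  stripped <- lapply(out[seq_along(dataset)], function(lg) {
    lg$bin <- NULL
    lg
  })
  expect_identical(stripped, dataset)

  # noise level 0: duplicates are exact copies
  out0 <- oversample_by_phi(dataset, k = 2, noise_level = 0, seed = 3)
  prov0 <- vapply(out0, `[[`, character(1), "provenance")
  dup0 <- out0[prov0 == "oversampled"][[1]]
  src_phis <- vapply(dataset, `[[`, numeric(1), "phi")
  expect_true(any(abs(src_phis - dup0$phi) < 1e-15))

  # equal bins: nothing added
  balanced <- c(dataset[1:20], dataset[101:120])
  outb <- oversample_by_phi(balanced, k = 2, noise_level = 0.05, seed = 4)
  expect_length(outb, 40L)

  # all seven bins end up with equal cardinality
  set.seed(33)
  ds7 <- lapply(1:70, function(k) mk(rexp(1), 300 + k))
  out7 <- oversample_by_phi(ds7, k = 7, noise_level = 0.05, seed = 9)
  bins <- attr(out7, "bins")
  km_sizes <- table(bins)
  expect_equal(length(out7), 70L + sum(max(km_sizes) - km_sizes))
})

test_that("the sign-momentum optimizer follows its hand-computed recursion", {
  # zero gradient, zero momentum: no movement
  p <- list(w = c(1, -2))
  g <- list(w = c(0, 0))
  m <- list(w = c(0, 0))
  up <- sign_momentum_step(p, g, m, lr = 0.1)
  expect_identical(up$params$w, p$w)

  # sign-only: scaling the gradient by 1000 gives the identical update
  g1 <- list(w = c(0.3, -0.002))
  u1 <- sign_momentum_step(p, g1, m, lr = 0.1)
  u2 <- sign_momentum_step(p, list(w = g1$w * 1000), m, lr = 0.1)
  expect_identical(u1$params, u2$params)
  # every coordinate moves by exactly lr
  expect_equal(abs(u1$params$w - p$w), c(0.1, 0.1))

  # three-step scalar recursion, hand-computed:
  # lr=0.1, b1=0.9, b2=0.99; p0=1, m0=0; g = 0.5, -0.2, 0.01
  p <- list(w = 1); m <- list(w = 0)
  s1 <- sign_momentum_step(p, list(w = 0.5), m, lr = 0.1)
  expect_equal(s1$params$w, 0.9)
  expect_equal(s1$state$w, 0.005)
  s2 <- sign_momentum_step(s1$params, list(w = -0.2), s1$state, lr = 0.1)
  expect_equal(s2$params$w, 1.0)      # sign(0.0045 - 0.02) = -1
  expect_equal(s2$state$w, 0.00295)
  s3 <- sign_momentum_step(s2$params, list(w = 0.01), s2$state, lr = 0.1)
  expect_equal(s3$params$w, 0.9)      # sign(0.002655 + 0.001) = +1
  expect_equal(s3$state$w, 0.0030205)

  # decoupled weight decay bounds the step magnitude
  pw <- list(w = c(2, -3))
  uw <- sign_momentum_step(pw, list(w = c(1, 1)), list(w = c(0, 0)),
                           lr = 0.1, weight_decay = 0.5)
  expect_true(all(abs(uw$params$w - pw$w) <=
                    0.1 + 0.1 * 0.5 * abs(pw$w) + 1e-12))
})

test_that("training is seeded-deterministic and returns the best checkpoint", {
  fx <- fixture_pack()
  keep <- which(vapply(fx$specs, `[[`, integer(1), "n_nodes") == 4L)[1:40]
  dataset <- make_labeled_graphs(fx$specs[keep], fx$labels[keep])
  cfg <- train_config(max_epochs = 8, patience_epochs = 50, seed = 99)
  r1 <- train_network(dataset, cfg)
  r2 <- train_network(dataset, cfg)
  expect_identical(phinet:::par_flatten(r1$model$params),
                   phinet:::par_flatten(r2$model$params))
  expect_identical(r1$log, r2$log)
  # returned checkpoint is the best validation loss seen
  expect_equal(r1$best_val_loss, min(r1$log$val_loss))
  expect_equal(r1$log$val_loss[r1$best_epoch], r1$best_val_loss)
})

test_that("early stopping honours the patience boundary", {
  fx <- fixture_pack()
  keep <- which(vapply(fx$specs, `[[`, integer(1), "n_nodes") == 3L)[1:20]
  dataset <- make_labeled_graphs(fx$specs[keep], fx$labels[keep])
  # patience 0 stops at the first epoch whose validation loss fails to
  # improve; with a tiny learning rate that happens almost immediately
  cfg0 <- train_config(max_epochs = 200, patience_epochs = 0,
                       learning_rate = 1e-9, seed = 3)
  r0 <- train_network(dataset, cfg0)
  expect_lt(r0$stopped_epoch, 50)
  expect_equal(r0$best_val_loss, min(r0$log$val_loss))
  # the log ends at the stopping epoch
  expect_equal(nrow(r0$log), r0$stopped_epoch)
})

test_that("a short optimisation run reduces the training loss", {
  fx <- fixture_pack()
  keep <- which(vapply(fx$specs, `[[`, integer(1), "n_nodes") %in% c(3L, 4L))[1:30]
  dataset <- make_labeled_graphs(fx$specs[keep], fx$labels[keep])
  r <- train_network(dataset, train_config(max_epochs = 60,
                                           patience_epochs = 60, seed = 11))
  expect_lt(min(r$log$train_loss), r$log$train_loss[1])
  expect_lte(r$best_val_loss, min(r$log$val_loss))
})
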