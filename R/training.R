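# Training recipe: disconnected-pair augmentation, k-means oversampling over
# the regression target, stratified validation split, sign-momentum (LION)
# optimisation, and early stopping.

#' Training configuration
#'
#' Defaults reproduce the study recipe: learning rate 1e-4, mini-batch 128,
#' class weight 1.8 on label "out", classification loss weight 5,
#' augmentation fraction 0.05, seven oversampling bins, 5% multiplicative
#' noise, patience 50, validation fraction 0.10.
#'
#' @param learning_rate,batch_size,out_class_weight,ce_loss_weight
#'   Optimisation and loss settings.
#' @param augmentation_fraction Fraction of extra disconnected-pair
#'   composites, relative to the training-set size.
#' @param oversample_bins Number of k-means bins over the target.
#' @param noise_level Half-width of the multiplicative perturbation
#'   (`Uniform[1 - level, 1 + level]`).
#' @param patience_epochs Early-stopping patience.
#' @param validation_fraction Fraction held out for validation.
#' @param max_epochs Hard epoch cap.
#' @param beta1,beta2,weight_decay LION optimizer settings.
#' @param seed Root seed for all training randomness.
#' @return Named list of class `"phinet_train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         out_class_weight = 1.8, ce_loss_weight = 5,
                         augmentation_fraction = 0.05, oversample_bins = 7L,
                         noise_level = 0.05, patience_epochs = 50L,
                         validation_fraction = 0.10, max_epochs = 2000L,
                         beta1 = 0.9, beta2 = 0.99, weight_decay = 0,
                         seed = 1L) {
  cfg <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
              out_class_weight = out_class_weight,
              ce_loss_weight = ce_loss_weight,
              augmentation_fraction = augmentation_fraction,
              oversample_bins = as.integer(oversample_bins),
              noise_level = noise_level,
              patience_epochs = as.integer(patience_epochs),
              validation_fraction = validation_fraction,
              max_epochs = as.integer(max_epochs),
              beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
              seed = as.integer(seed))
  stopifnot(cfg$learning_rate > 0, cfg$batch_size > 0,
            cfg$validation_fraction > 0, cfg$validation_fraction < 1,
            cfg$augmentation_fraction >= 0, cfg$patience_epochs >= 0)
  class(cfg) <- "phinet_train_config"
  cfg
}

# A labeled graph bundles features with its targets.
labeled_graph <- function(fg, phi, members, provenance = "real") {
  y_in <- rep(FALSE, fg$n)
  y_in[members] <- TRUE
  list(fg = fg, phi = phi, y_in = y_in, provenance = provenance)
}

#' Build labeled graphs from specs and labels
#'
#' @param specs List of [system_spec()].
#' @param labels Aligned list of labels (see [compute_labels()]).
#' @return List of labeled graphs (features + phi + per-node in/out labels).
#' @export
make_labeled_graphs <- function(specs, labels) {
  lapply(seq_along(specs), function(k)
    labeled_graph(node_features(specs[[k]]), labels[[k]]$phi,
                  labels[[k]]$major_complex))
}

#' Disconnected-pair augmentation
#'
#' Adds `round(fraction * n)` composites. Each composite is the disjoint
#' union of two distinct training graphs A and B: no cross edges, features
#' kept per original graph (including each part's own temperature column).
#' The composite's target is `max(phi_A, phi_B)`; the winner keeps its node
#' labels and every node of the loser is labeled "out".
#'
#' @param dataset List of labeled graphs.
#' @param fraction Fraction of composites to add.
#' @param seed Integer seed.
#' @return The dataset with composites appended (`provenance = "augmented"`).
#' @export
augment_disconnected_pairs <- function(dataset, fraction = 0.05, seed = 1L) {
  n_add <- round(fraction * length(dataset))
  if (n_add == 0L) return(dataset)
  if (length(dataset) < 2L) stop("augmentation needs at least two graphs")
  pairs <- with_seed(child_seed(seed, "augment"), {
    lapply(seq_len(n_add), function(k) sample.int(length(dataset), 2L))
  })
  extra <- lapply(pairs, function(pr) {
    a <- dataset[[pr[1L]]]; b <- dataset[[pr[2L]]]
    if (b$phi > a$phi) { tmp <- a; a <- b; b <- tmp }
    fg <- batch_graphs(list(a$fg, b$fg))
    fg$graph <- rep(1L, fg$n)            # one composite graph
    lg <- list(fg = fg, phi = a$phi,
               y_in = c(a$y_in, rep(FALSE, b$fg$n)),
               provenance = "augmented")
    lg
  })
  c(dataset, extra)
}

#' Oversample sparse target regions
#'
#' 1-D k-means over the graph-level targets splits the data into `k` bins;
#' every smaller bin is upsampled with replacement to the size of the largest
#' bin. Each duplicate is perturbed by independent multiplicative factors
#' `Uniform[1 - noise, 1 + noise]` applied to the target and to every
#' node-feature entry; originals are kept unmodified.
#'
#' @param dataset List of labeled graphs.
#' @param k Number of bins (reduced, with a warning, if there are fewer
#'   distinct targets).
#' @param noise_level Multiplicative noise half-width.
#' @param seed Integer seed.
#' @return Dataset with perturbed duplicates appended
#'   (`provenance = "oversampled"`); attribute `bin` gives each item's bin.
#' @export
oversample_by_phi <- function(dataset, k = 7L, noise_level = 0.05, seed = 1L) {
  phis <- vapply(dataset, `[[`, numeric(1), "phi")
  k_eff <- min(k, length(unique(phis)))
  if (k_eff < k)
    warning(sprintf("only %d distinct targets; reducing bins to %d",
                    k_eff, k_eff))
  if (k_eff < 2L) return(dataset)
  km <- with_seed(child_seed(seed, "kmeans"),
                  stats::kmeans(phis, centers = k_eff, nstart = 100L,
                                iter.max = 100L))
  bins <- km$cluster
  sizes <- tabulate(bins, nbins = k_eff)
  target <- max(sizes)
  out <- dataset
  for (i in seq_along(dataset)) out[[i]]$bin <- bins[i]
  with_seed(child_seed(seed, "oversample"), {
    for (b in seq_len(k_eff)) {
      idx <- which(bins == b)
      need <- target - length(idx)
      if (need <= 0L) next
      take <- sample(idx, need, replace = TRUE)
      for (j in take) {
        lg <- dataset[[j]]
        lg$phi <- lg$phi * stats::runif(1, 1 - noise_level, 1 + noise_level)
        lg$fg$x <- lg$fg$x *
          matrix(stats::runif(length(lg$fg$x), 1 - noise_level,
                              1 + noise_level), nrow(lg$fg$x))
        lg$provenance <- "oversampled"
        lg$bin <- b
        out[[length(out) + 1L]] <- lg
      }
    }
  })
  attr(out, "bins") <- bins
  out
}

#' One LION (sign-momentum) update
#'
#' Direction `sign(beta1 * m + (1 - beta1) * g)`; every coordinate moves by
#' exactly `lr` (plus decoupled weight decay); momentum update
#' `m <- beta2 * m + (1 - beta2) * g`.
#'
#' @param params,grads,state Parallel parameter / gradient / momentum trees.
#' @param lr Learning rate.
#' @param betas `c(beta1, beta2)`.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @return List with updated `params` and `state`.
#' @export
sign_momentum_step <- function(params, grads, state, lr = 1e-4,
                               betas = c(0.9, 0.99), weight_decay = 0) {
  b1 <- betas[1L]; b2 <- betas[2L]
  direction <- par_map2(function(m, g) sign(b1 * m + (1 - b1) * g),
                        state, grads)
  params2 <- par_map2(function(p, d) p - lr * d, params, direction)
  if (weight_decay > 0)
    params2 <- par_map2(function(p2, p) p2 - lr * weight_decay * p,
                        params2, params)
  state2 <- par_map2(function(m, g) b2 * m + (1 - b2) * g, state, grads)
  list(params = params2, state = state2)
}

# stratified validation split: bin targets into quantile strata and sample
# the validation fraction inside each stratum
stratified_split <- function(phis, fraction, seed, n_strata = 5L) {
  n <- length(phis)
  qs <- unique(stats::quantile(phis, probs = seq(0, 1, length.out = n_strata + 1L)))
  strata <- cut(phis, breaks = qs, include.lowest = TRUE, labels = FALSE)
  strata[is.na(strata)] <- 1L
  val <- with_seed(child_seed(seed, "valsplit"), {
    unlist(lapply(unique(strata), function(s) {
      idx <- which(strata == s)
      nv <- max(1L, round(fraction * length(idx)))
      if (length(idx) <= 1L) return(integer(0))
      sample(idx, min(nv, length(idx) - 1L))
    }))
  })
  sort(val)
}

# evaluate composite loss of a model over a dataset (eval mode)
dataset_loss <- function(model, dataset, config) {
  batch <- batch_labeled(dataset)
  fwd <- nn_forward(model, batch$fg, train = FALSE)
  as.numeric(composite_loss(fwd$phi_hat, batch$phi, fwd$prob, batch$y_in,
                            out_weight = config$out_class_weight,
                            ce_weight = config$ce_loss_weight))
}

# merge labeled graphs into one batch (targets aligned with graph ids)
batch_labeled <- function(items) {
  fg <- batch_graphs(lapply(items, `[[`, "fg"))
  fg$graph <- unlist(lapply(seq_along(items), function(k)
    rep(k, items[[k]]$fg$n)))
  list(fg = fg,
       phi = vapply(items, `[[`, numeric(1), "phi"),
       y_in = unlist(lapply(items, `[[`, "y_in")))
}

#' Train the network on labeled graphs
#'
#' Pipeline order: disconnected-pair augmentation, target-binned
#' oversampling, stratified validation split, normalizer fit on the expanded
#' training portion, then mini-batch LION optimisation of the composite loss
#' with early stopping on the validation composite loss. The checkpoint with
#' the best validation loss is returned.
#'
#' @param dataset List of labeled graphs (see [make_labeled_graphs()]).
#' @param config A [train_config()].
#' @param net_config A [phinet_config()].
#' @return A list: `model` (params + bn_state + config + normalizer), `log`
#'   (per-epoch data frame), `best_epoch`, `stopped_epoch`, `config`.
#' @export
train_network <- function(dataset, config = train_config(),
                          net_config = phinet_config()) {
  if (length(dataset) == 0L) stop("empty dataset")
  seed <- config$seed
  expanded <- augment_disconnected_pairs(dataset, config$augmentation_fraction,
                                         seed = child_seed(seed, "aug"))
  expanded <- oversample_by_phi(expanded, config$oversample_bins,
                                config$noise_level,
                                seed = child_seed(seed, "ovs"))
  phis <- vapply(expanded, `[[`, numeric(1), "phi")
  val_idx <- stratified_split(phis, config$validation_fraction, seed)
  val <- expanded[val_idx]
  tr <- expanded[setdiff(seq_along(expanded), val_idx)]
  norm <- suppressWarnings(fit_normalizer(lapply(tr, `[[`, "fg")))
  tr <- lapply(tr, function(lg) { lg$fg <- apply_normalizer(norm, lg$fg); lg })
  val <- lapply(val, function(lg) { lg$fg <- apply_normalizer(norm, lg$fg); lg })

  init <- init_params(net_config, seed = child_seed(seed, "params"))
  model <- list(params = init$params, bn_state = init$bn_state,
                config = net_config, normalizer = norm)
  mstate <- par_map(function(p) p * 0, model$params)
  best <- list(loss = Inf, params = model$params, bn_state = model$bn_state,
               epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  n_tr <- length(tr)
  bad_epochs <- 0L
  stopped <- config$max_epochs
  with_seed(child_seed(seed, "trainloop"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        batch <- batch_labeled(tr[idx])
        fwd <- nn_forward(model, batch$fg, train = TRUE, keep_cache = TRUE)
        model$bn_state <- fwd$bn_state
        loss <- composite_loss(fwd$phi_hat, batch$phi, fwd$prob, batch$y_in,
                               out_weight = config$out_class_weight,
                               ce_weight = config$ce_loss_weight)
        grads <- nn_backward(model, fwd, batch$phi, batch$y_in,
                             out_weight = config$out_class_weight,
                             ce_weight = config$ce_loss_weight)
        upd <- sign_momentum_step(model$params, grads, mstate,
                                  lr = config$learning_rate,
                                  betas = c(config$beta1, config$beta2),
                                  weight_decay = config$weight_decay)
        model$params <- upd$params
        mstate <- upd$state
        ep_loss <- ep_loss + as.numeric(loss); n_batches <- n_batches + 1L
      }
      vl <- if (length(val)) dataset_loss(model, val, config)
            else ep_loss / n_batches
      log[nrow(log) + 1L, ] <- list(epoch, ep_loss / n_batches, vl)
      if (vl < best$loss) {
        best <- list(loss = vl, params = model$params,
                     bn_state = model$bn_state, epoch = epoch)
        bad_epochs <- 0L
      } else {
        # halt once the validation loss has failed to improve for
        # `patience_epochs` consecutive epochs (immediately if patience is 0)
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= max(1L, config$patience_epochs)) {
          stopped <- epoch; break
        }
      }
      stopped <- epoch
    }
  })
  model$params <- best$params
  model$bn_state <- best$bn_state
  list(model = model, log = log, best_epoch = best$epoch,
       best_val_loss = best$loss, stopped_epoch = stopped, config = config)
}
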