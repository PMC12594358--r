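# The user-facing modelling surface: one fitting function returning a
# classed object, in the style of classic R modelling packages.

#' Fit the integrated-information network
#'
#' `phinet()` is the package's main fitting function. Given a list of
#' systems (and, optionally, precomputed labels), it labels any unlabeled
#' systems with the exact engine, extracts node and edge features, runs the
#' full training recipe (augmentation, oversampling, stratified validation
#' split, normalisation, sign-momentum optimisation with early stopping) and
#' returns the best-validation checkpoint.
#'
#' @param systems List of [system_spec()] objects, or a list of labeled
#'   graphs from [make_labeled_graphs()].
#' @param labels Optional list of labels aligned with `systems`; when `NULL`
#'   and `systems` are specs, labels are computed with [compute_labels()]
#'   (requires `N <= 8` per system).
#' @param control A [train_config()].
#' @param net A [phinet_config()].
#' @return An object of class `"phinet"`: the trained model plus training
#'   log, configurations and training-set references.
#' @examples
#' specs <- lapply(1:30, function(k) generate_random_system(4, seed = k))
#' fit <- phinet(specs, control = train_config(max_epochs = 3, seed = 1))
#' print(fit)
#' predict(fit, specs[1:2])
#' @export
phinet <- function(systems, labels = NULL, control = train_config(),
                   net = phinet_config()) {
  if (length(systems) == 0L) stop("no systems supplied")
  if (inherits(systems[[1L]], "system_spec")) {
    if (is.null(labels)) labels <- label_dataset(systems)
    dataset <- make_labeled_graphs(systems, labels)
  } else {
    dataset <- systems
  }
  res <- train_network(dataset, config = control, net_config = net)
  structure(list(model = res$model, log = res$log,
                 best_epoch = res$best_epoch,
                 best_val_loss = res$best_val_loss,
                 stopped_epoch = res$stopped_epoch,
                 control = control, net = net,
                 train_phi = vapply(dataset, `[[`, numeric(1), "phi"),
                 dataset = dataset),
            class = "phinet")
}

#' @export
print.phinet <- function(x, ...) {
  cat("Multi-task transformer-convolution network\n")
  cat(sprintf("  %d layers, %d heads x %d channels (hidden %d)\n",
              x$net$layers, x$net$heads, x$net$channels, x$net$hidden))
  cat(sprintf("  trained on %d graphs; stopped at epoch %d (best epoch %d, val loss %.4f)\n",
              length(x$train_phi), x$stopped_epoch, x$best_epoch,
              x$best_val_loss))
  invisible(x)
}

#' @export
summary.phinet <- function(object, ...) {
  preds <- predict(object, lapply(object$dataset, `[[`, "fg"))
  labels <- lapply(object$dataset, function(lg)
    list(phi = lg$phi, major_complex = which(lg$y_in)))
  m <- compute_metrics(preds, labels)
  out <- list(fit = object, train_metrics = m)
  class(out) <- "summary.phinet"
  out
}

#' @export
print.summary.phinet <- function(x, ...) {
  print(x$fit)
  cat("Training-set metrics:\n")
  print(x$train_metrics)
  invisible(x)
}

#' @export
coef.phinet <- function(object, ...) {
  par_flatten(object$model$params)
}

#' Predict integrated information and major-complex membership
#'
#' @param object A fitted [phinet()] model.
#' @param newdata List of [system_spec()] objects or raw feature graphs.
#' @param ... Unused.
#' @return A list of predictions, one per graph, each with `phi_hat`,
#'   `prob_in` (per-node probability of inclusion) and logical `membership`
#'   (`prob_in >= 0.5`).
#' @export
predict.phinet <- function(object, newdata, ...) {
  if (inherits(newdata, "system_spec")) newdata <- list(newdata)
  if (inherits(newdata, "feature_graph")) newdata <- list(newdata)
  fgs <- lapply(newdata, function(item)
    if (inherits(item, "system_spec")) node_features(item) else item)
  lapply(fgs, function(fg) predict_one(object$model, fg))
}

#' @export
fitted.phinet <- function(object, ...) {
  preds <- predict(object, lapply(object$dataset, `[[`, "fg"))
  vapply(preds, `[[`, numeric(1), "phi_hat")
}

#' @export
residuals.phinet <- function(object, ...) {
  object$train_phi - fitted(object)
}

#' @export
plot.phinet <- function(x, ...) {
  log <- x$log
  graphics::matplot(log$epoch, cbind(log$train_loss, log$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "composite loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Fit an ensemble of networks
#'
#' Trains `n_models` networks on the same dataset under different seeds and
#' returns a `"phinet_ensemble"` whose `predict` method performs
#' model-averaged estimation and vote-thresholded membership (see
#' [ensemble_predict()]).
#'
#' @param systems,labels,control,net As in [phinet()].
#' @param n_models Ensemble size.
#' @param threshold Membership vote threshold (default 0.6).
#' @return An object of class `"phinet_ensemble"`.
#' @export
phinet_ensemble <- function(systems, labels = NULL, n_models = 10L,
                            control = train_config(), net = phinet_config(),
                            threshold = 0.6) {
  fits <- lapply(seq_len(n_models), function(k) {
    ctl <- control
    ctl$seed <- child_seed(control$seed, sprintf("ensemble:%d", k))
    phinet(systems, labels, control = ctl, net = net)
  })
  structure(list(fits = fits, threshold = threshold),
            class = "phinet_ensemble")
}

#' @export
print.phinet_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d networks (vote threshold %.2f)\n",
              length(x$fits), x$threshold))
  invisible(x)
}

#' @export
predict.phinet_ensemble <- function(object, newdata, threshold = NULL, ...) {
  if (inherits(newdata, "system_spec")) newdata <- list(newdata)
  if (is.null(threshold)) threshold <- object$threshold
  models <- lapply(object$fits, `[[`, "model")
  lapply(newdata, function(item) {
    fg <- if (inherits(item, "system_spec")) node_features(item) else item
    ensemble_predict(models, fg, threshold = threshold)
  })
}
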