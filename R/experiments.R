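# Drivers for the four studies: non-extrapolative, extrapolative,
# topology scaling, and the split-brain sweep.

#' Construct an experiment plan
#'
#' Desk-scale defaults keep every study runnable on one CPU in minutes; the
#' full-scale protocols (used for the published reference bands, see
#' [cluster_reference_metrics()]) are available via `scale = "full"`.
#'
#' @param study One of `"nonextrap"`, `"extrap"`, `"scaling"`,
#'   `"splitbrain"`.
#' @param scale `"desk"` (default) or `"full"`.
#' @param seed Root seed.
#' @return A named list of plan settings.
#' @export
experiment_plan <- function(study = c("nonextrap", "extrap", "scaling",
                                      "splitbrain"),
                            scale = c("desk", "full"), seed = 1L) {
  study <- match.arg(study); scale <- match.arg(scale)
  full <- scale == "full"
  plan <- switch(study,
    nonextrap = list(
      sizes = if (full) c(5L, 6L, 7L) else c(4L, 5L),
      per_size = if (full) 1000L else 100L,
      repetitions = if (full) 100L else 1L,
      train_fraction = 0.9),
    extrap = list(
      train_sizes = if (full) c(5L, 6L) else c(3L, 4L),
      train_per_size = if (full) 1500L else 100L,
      test_size = if (full) 7L else 5L,
      test_count = if (full) 1000L else 50L),
    scaling = list(
      sizes = if (full) seq(10L, 100L, by = 10L) else c(10L, 20L, 40L),
      topologies = c("tree", "full", "loop"),
      instances = 10L,
      ensemble_size = if (full) 100L else 10L),
    splitbrain = list(
      p_e_grid = c(0, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4),
      systems_per_condition = if (full) 50L else 10L,
      ensemble_size = if (full) 100L else 10L))
  c(plan, list(study = study, scale = scale, seed = as.integer(seed)))
}

# generate + label a pool of random systems for given sizes
labeled_pool <- function(sizes, per_size, seed, cache_path = NULL) {
  specs <- list()
  for (n in sizes) {
    specs <- c(specs, lapply(seq_len(per_size), function(k)
      generate_random_system(n, seed = child_seed(seed,
                                                  sprintf("pool:%d:%d", n, k)))))
  }
  labels <- label_dataset(specs, cache_path = cache_path)
  list(specs = specs, labels = labels)
}

#' Non-extrapolative study
#'
#' Mixes systems of the plan's sizes, shuffles, splits train/test
#' (`train_fraction`), fits the network and evaluates the four test metrics;
#' repeats with fresh splits and reports per-repetition records plus means.
#'
#' @param plan An [experiment_plan()] (`study = "nonextrap"`).
#' @param dataset Optional pre-labeled dataset (`list(specs, labels)`), e.g.
#'   from [load_fixture_pack()]; generated and labeled per plan when `NULL`.
#' @param control,net Training and network configuration.
#' @return List with `records` (one metrics row per repetition) and `mean`
#'   (column means).
#' @export
run_non_extrapolative <- function(plan = experiment_plan("nonextrap"),
                                  dataset = NULL,
                                  control = train_config(),
                                  net = phinet_config()) {
  if (is.null(dataset))
    dataset <- labeled_pool(plan$sizes, plan$per_size, plan$seed)
  n <- length(dataset$specs)
  records <- data.frame()
  for (rep_i in seq_len(plan$repetitions)) {
    ord <- with_seed(child_seed(plan$seed, sprintf("split:%d", rep_i)),
                     sample.int(n))
    n_train <- round(plan$train_fraction * n)
    tr_idx <- ord[seq_len(n_train)]; te_idx <- ord[-seq_len(n_train)]
    ctl <- control
    ctl$seed <- child_seed(plan$seed, sprintf("fit:%d", rep_i))
    fit <- phinet(dataset$specs[tr_idx], dataset$labels[tr_idx],
                  control = ctl, net = net)
    preds <- predict(fit, dataset$specs[te_idx])
    m <- compute_metrics(preds, dataset$labels[te_idx])
    records <- rbind(records, data.frame(
      repetition = rep_i, mse = m$mse, pearson_r = as.numeric(m$pearson_r),
      node_accuracy = m$node_accuracy, graph_accuracy = m$graph_accuracy,
      best_epoch = fit$best_epoch))
  }
  list(records = records,
       mean = colMeans(records[, c("mse", "pearson_r", "node_accuracy",
                                   "graph_accuracy")]))
}

#' Extrapolative study
#'
#' Trains on the plan's smaller sizes and tests on a strictly larger size,
#' reusing the training normalizer statistics unchanged on the test graphs.
#'
#' @param plan An [experiment_plan()] (`study = "extrap"`).
#' @param train_dataset,test_dataset Optional pre-labeled datasets.
#' @param control,net Training and network configuration.
#' @return List with `metrics`, the fitted model, and the protocol audit
#'   fields `train_sizes` / `test_size`.
#' @export
run_extrapolative <- function(plan = experiment_plan("extrap"),
                              train_dataset = NULL, test_dataset = NULL,
                              control = train_config(),
                              net = phinet_config()) {
  if (is.null(train_dataset))
    train_dataset <- labeled_pool(plan$train_sizes, plan$train_per_size,
                                  child_seed(plan$seed, "train"))
  if (is.null(test_dataset))
    test_dataset <- labeled_pool(plan$test_size, plan$test_count,
                                 child_seed(plan$seed, "test"))
  ctl <- control
  ctl$seed <- child_seed(plan$seed, "fit")
  fit <- phinet(train_dataset$specs, train_dataset$labels,
                control = ctl, net = net)
  preds <- predict(fit, test_dataset$specs)
  m <- compute_metrics(preds, test_dataset$labels)
  list(metrics = m, fit = fit,
       train_sizes = sort(unique(vapply(train_dataset$specs, `[[`,
                                        integer(1), "n_nodes"))),
       test_size = unique(vapply(test_dataset$specs, `[[`, integer(1),
                                 "n_nodes")))
}

#' Topology-scaling study
#'
#' For each system size and topology (tree / full / loop), generates the
#' plan's number of instances and records the ensemble-estimated integrated
#' information and major-complex size ratio.
#'
#' @param models List of trained models (e.g. `lapply(ens$fits, \(f) f$model)`).
#' @param plan An [experiment_plan()] (`study = "scaling"`).
#' @param threshold Membership vote threshold.
#' @return A tidy data frame: one row per instance with `n`, `topology`,
#'   `instance`, `phi_mean`, `mc_ratio`, `n_edges`.
#' @export
run_scaling <- function(models, plan = experiment_plan("scaling"),
                        threshold = 0.6) {
  records <- data.frame()
  for (n in plan$sizes) {
    for (topo in plan$topologies) {
      for (inst in seq_len(plan$instances)) {
        spec <- generate_topology(topo, n,
                                  seed = child_seed(plan$seed,
                                                    sprintf("scal:%s:%d:%d",
                                                            topo, n, inst)))
        res <- ensemble_predict(models, node_features(spec), threshold)
        records <- rbind(records, data.frame(
          n = n, topology = topo, instance = inst,
          phi_mean = res$phi_mean,
          mc_ratio = mean(res$membership),
          n_edges = nrow(spec$edges)))
      }
    }
  }
  records
}

#' Split-brain sweep
#'
#' For every inter-block edge probability in the plan's grid, generates the
#' plan's number of two-block systems, runs ensemble prediction and records:
#' whether the predicted major complex equals exactly the first block
#' (`local_exact`), whether it is contained in the first block
#' (`local_subset`), the membership ratio over all nodes, and the ensemble
#' integrated-information estimate.
#'
#' @param models List of trained models.
#' @param plan An [experiment_plan()] (`study = "splitbrain"`).
#' @param threshold Membership vote threshold.
#' @return List with `records` (replicate level) and `aggregates` (one row
#'   per `p_e`: local-integration rates, mean membership ratio, mean phi).
#' @export
run_split_brain <- function(models, plan = experiment_plan("splitbrain"),
                            threshold = 0.6) {
  records <- data.frame()
  for (p_e in plan$p_e_grid) {
    for (inst in seq_len(plan$systems_per_condition)) {
      spec <- generate_split_brain(p_e,
                                   seed = child_seed(plan$seed,
                                                     sprintf("sb:%g:%d",
                                                             p_e, inst)))
      block1 <- spec$meta$blocks[[1L]]
      res <- ensemble_predict(models, node_features(spec), threshold)
      mem <- which(res$membership)
      records <- rbind(records, data.frame(
        p_e = p_e, instance = inst,
        local_exact = setequal(mem, block1),
        local_subset = length(mem) > 0 && all(mem %in% block1),
        mc_ratio = mean(res$membership),
        phi_mean = res$phi_mean))
    }
  }
  aggregates <- do.call(rbind, lapply(split(records, records$p_e), function(d)
    data.frame(p_e = d$p_e[1L],
               local_exact_rate = mean(d$local_exact),
               local_subset_rate = mean(d$local_subset),
               mean_mc_ratio = mean(d$mc_ratio),
               mean_phi = mean(d$phi_mean))))
  rownames(aggregates) <- NULL
  list(records = records, aggregates = aggregates[order(aggregates$p_e), ])
}
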