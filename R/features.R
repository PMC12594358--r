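# Node and edge features for the network.
#
# Six node features, in fixed column order:
#   1. max_prob  : max{p_i(+1|S), p_i(-1|S)} at the assigned state
#   2. T         : system temperature (shared by all nodes)
#   3. degree    : number of incident edges
#   4. closeness : hop-count closeness, disconnected-graph convention below
#   5. betweenness: shortest-path betweenness, normalised by (N-1)(N-2)/2
#   6. clustering: local clustering coefficient (0 for degree < 2)
# The node state S_i itself is never a feature, which makes all features --
# and hence the whole network -- exactly invariant under global state
# inversion S -> -S (feature 1 depends on |tau_i| only).
#
# Edge feature: the raw coupling J_ij (one dimension, not normalised by
# default). Undirected edges expand to two directed messages sharing J_ij.

PHINET_FEATURE_NAMES <- c("max_prob", "T", "degree", "closeness",
                          "betweenness", "clustering")

#' Compute the feature graph of a system
#'
#' Returns the network-ready representation: an `N x 6` node-feature matrix,
#' a directed edge index containing both `(i,j)` and `(j,i)` for every
#' undirected edge, and the per-directed-edge 1-dimensional feature `J_ij`.
#'
#' Centralities use unweighted hop counts. Closeness of node `i` is
#' `(R_i / (N-1)) / mean(d_ij over reachable j)` where `R_i` counts the other
#' nodes reachable from `i`; an isolated node gets 0. Betweenness is divided
#' by `(N-1)(N-2)/2`; clustering of a node with fewer than two neighbours
#' is 0.
#'
#' @param spec A [system_spec()].
#' @return An object of class `"feature_graph"`: list with `n`, `x`
#'   (`N x 6`), `edge_index` (`2 x 2M`, row 1 = source, row 2 = destination),
#'   `edge_attr` (`2M x 1`), and `graph` (graph id per node, all 1).
#' @export
node_features <- function(spec) {
  n <- spec$n_nodes
  tau <- local_fields(spec)
  # max{p(+1), p(-1)} = 1 / (1 + exp(-2|tau|/T)), exactly inversion-invariant
  max_prob <- 1 / (1 + exp(-2 * abs(tau) / spec$temperature))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(spec$edges) > 0L)
    g <- igraph::add_edges(g, t(spec$edges))
  deg <- igraph::degree(g)
  D <- igraph::distances(g)          # hop counts, Inf across components
  closeness <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    if (!any(reach) || n == 1L) return(0)
    (sum(reach) / (n - 1)) / mean(d[reach])
  }, numeric(1))
  betw <- if (n > 2L)
    igraph::betweenness(g, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  else rep(0, n)
  clus <- igraph::transitivity(g, type = "local", isolates = "zero")
  clus[is.na(clus)] <- 0
  x <- cbind(max_prob, spec$temperature, deg, closeness, betw, clus)
  colnames(x) <- PHINET_FEATURE_NAMES
  m <- nrow(spec$edges)
  if (m > 0L) {
    edge_index <- rbind(c(spec$edges[, 1L], spec$edges[, 2L]),
                        c(spec$edges[, 2L], spec$edges[, 1L]))
    edge_attr <- matrix(c(spec$weights, spec$weights), ncol = 1L)
  } else {
    edge_index <- matrix(integer(0), nrow = 2L)
    edge_attr <- matrix(numeric(0), ncol = 1L)
  }
  structure(list(n = n, x = x, edge_index = edge_index, edge_attr = edge_attr,
                 graph = rep(1L, n)),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("<feature_graph> %d nodes, %d directed edges, %d features\n",
              x$n, ncol(x$edge_index), ncol(x$x)))
  invisible(x)
}

#' Check state-inversion invariance of the features
#'
#' `TRUE` iff the feature matrix of `spec` equals, elementwise, that of the
#' same system with the state vector globally flipped.
#'
#' @param spec A [system_spec()].
#' @return Logical scalar.
#' @export
check_inversion_invariance <- function(spec) {
  flipped <- spec
  flipped$state <- -spec$state
  identical(node_features(spec)$x, node_features(flipped)$x)
}

#' Fit a per-column z-score normalizer on training feature graphs
#'
#' Location and scale are computed over all nodes of all training graphs.
#' A zero-variance column keeps scale 1 (with a warning), so the transform
#' stays well defined.
#'
#' @param training_graphs List of [node_features()] results.
#' @param normalize_edges Also standardise the edge feature (off by default;
#'   the raw coupling is the canonical edge feature).
#' @return An object of class `"phinet_normalizer"`.
#' @export
fit_normalizer <- function(training_graphs, normalize_edges = FALSE) {
  if (length(training_graphs) == 0L) stop("empty training set")
  X <- do.call(rbind, lapply(training_graphs, `[[`, "x"))
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  bad <- !is.finite(scale) | scale < 1e-12
  if (any(bad)) {
    warning(sprintf("zero-variance feature column(s) %s; scale set to 1",
                    paste(which(bad), collapse = ", ")))
    scale[bad] <- 1
  }
  e_center <- 0; e_scale <- 1
  if (normalize_edges) {
    E <- do.call(rbind, lapply(training_graphs, `[[`, "edge_attr"))
    if (nrow(E) > 1L) {
      e_center <- mean(E); e_scale <- stats::sd(E)
      if (!is.finite(e_scale) || e_scale < 1e-12) e_scale <- 1
    }
  }
  structure(list(center = center, scale = scale,
                 normalize_edges = normalize_edges,
                 edge_center = e_center, edge_scale = e_scale),
            class = "phinet_normalizer")
}

#' Apply a fitted normalizer to a feature graph
#'
#' Affine per-column transform using the training statistics only; the
#' graph's own statistics are never used.
#'
#' @param norm A [fit_normalizer()] result.
#' @param g A [node_features()] result.
#' @return The transformed feature graph.
#' @export
apply_normalizer <- function(norm, g) {
  g$x <- sweep(sweep(g$x, 2L, norm$center), 2L, norm$scale, "/")
  if (isTRUE(norm$normalize_edges) && nrow(g$edge_attr) > 0L)
    g$edge_attr <- (g$edge_attr - norm$edge_center) / norm$edge_scale
  g
}

#' Merge feature graphs into one block-diagonal batch
#'
#' Standard mini-batching for graph networks: node sets are concatenated with
#' shifted indices and a `graph` id per node; no edges cross graphs, so
#' message passing inside the batch equals standalone processing.
#'
#' @param graphs List of feature graphs.
#' @return One `"feature_graph"` whose `graph` field maps nodes to their
#'   source graph.
#' @export
batch_graphs <- function(graphs) {
  offs <- cumsum(c(0L, vapply(graphs, function(g) as.integer(g$n), integer(1))))
  x <- do.call(rbind, lapply(graphs, `[[`, "x"))
  ei <- do.call(cbind, lapply(seq_along(graphs), function(k)
    graphs[[k]]$edge_index + offs[k]))
  ea <- do.call(rbind, lapply(graphs, `[[`, "edge_attr"))
  gid <- unlist(lapply(seq_along(graphs), function(k)
    rep(k, graphs[[k]]$n)))
  structure(list(n = sum(vapply(graphs, function(g) as.integer(g$n), integer(1))), x = x,
                 edge_index = ei, edge_attr = ea, graph = as.integer(gid)),
            class = "feature_graph")
}
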