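# Shared test helpers: tiny graphs built in code, fast training settings.

# a bare feature graph with arbitrary dimensions (for network-level tests)
toy_graph <- function(n, edges = NULL, d = 6L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  if (is.null(edges) || nrow(edges) == 0L) {
    ei <- matrix(integer(0), nrow = 2L)
    ea <- matrix(numeric(0), ncol = 1L)
  } else {
    ei <- rbind(c(edges[, 1L], edges[, 2L]), c(edges[, 2L], edges[, 1L]))
    w <- rnorm(nrow(edges))
    ea <- matrix(c(w, w), ncol = 1L)
  }
  structure(list(n = as.integer(n), x = x, edge_index = ei, edge_attr = ea,
                 graph = rep(1L, n)),
            class = "feature_graph")
}

toy_model <- function(d = 6L, channels = 4L, heads = 2L, layers = 2L,
                      dropout = 0, seed = 1L) {
  cfg <- phinet_config(d_in = d, channels = channels, heads = heads,
                       layers = layers, dropout = dropout)
  init <- init_params(cfg, seed = seed)
  list(params = init$params, bn_state = init$bn_state, config = cfg)
}

# permute the nodes of a system spec (perm[i] = new index of old node i)
permute_spec <- function(spec, perm) {
  edges <- cbind(perm[spec$edges[, 1L]], perm[spec$edges[, 2L]])
  state <- numeric(spec$n_nodes)
  state[perm] <- spec$state
  system_spec(spec$n_nodes, edges, spec$weights, spec$temperature, state,
              meta = spec$meta)
}

# quick training settings for smoke tests
fast_train_config <- function(seed = 1L, max_epochs = 30L) {
  train_config(max_epochs = max_epochs, patience_epochs = 10L, seed = seed)
}

fixture_pack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_fixture_pack()
    cache
  }
})
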