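# Binary-node systems with Boltzmann transition dynamics.
#
# A system is an undirected weighted graph of N nodes, each in state +1 or -1,
# with a shared temperature T. Node i flips according to
#   p_i(s | S) = 1 / (1 + exp(-2 * tau_i * s / T)),  tau_i = sum_j J_ij S_j
# over its neighbours j, conditionally independently across nodes.
#
# In-memory node indices are 1-based (R convention); the JSONL serialization
# is 0-based (see read/write_systems_jsonl).

#' Construct a system specification
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param edges Integer matrix with two columns (1-based endpoints, stored
#'   with `i < j`), possibly zero rows.
#' @param weights Numeric coupling `J_ij` per edge row.
#' @param temperature Positive scalar temperature `T` shared by all nodes.
#' @param state Length-`n_nodes` vector with entries in `{+1, -1}`.
#' @param meta Optional list of provenance metadata (e.g. `rng_seed`, block
#'   structure for split-brain systems).
#' @return An object of class `"system_spec"`.
#' @export
system_spec <- function(n_nodes, edges, weights, temperature, state,
                        meta = list()) {
  n_nodes <- as.integer(n_nodes)
  edges <- matrix(as.integer(edges), ncol = 2L)
  weights <- as.numeric(weights)
  if (n_nodes < 1L) stop("n_nodes must be >= 1")
  if (nrow(edges) != length(weights))
    stop("every edge must have exactly one weight")
  if (nrow(edges) > 0L) {
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    if (any(edges < 1L) || any(edges > n_nodes)) stop("edge endpoint out of range")
    # canonical order i < j, duplicates forbidden
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, c(2L, 1L)]
    key <- (edges[, 1L] - 1L) * n_nodes + (edges[, 2L] - 1L)
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    ord <- order(key)
    edges <- edges[ord, , drop = FALSE]
    weights <- weights[ord]
  }
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a positive scalar")
  state <- as.numeric(state)
  if (length(state) != n_nodes || !all(abs(state) == 1))
    stop("state must be a length-n vector of +1/-1")
  structure(list(n_nodes = n_nodes, edges = edges, weights = weights,
                 temperature = as.numeric(temperature), state = state,
                 meta = meta),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("<system_spec> N = %d, %d edges, T = %.4g, state = [%s]\n",
              x$n_nodes, nrow(x$edges), x$temperature,
              paste(ifelse(x$state > 0, "+", "-"), collapse = "")))
  invisible(x)
}

# Symmetric coupling matrix J (zero diagonal).
coupling_matrix <- function(spec) {
  J <- matrix(0, spec$n_nodes, spec$n_nodes)
  if (nrow(spec$edges) > 0L) {
    J[spec$edges] <- spec$weights
    J[spec$edges[, c(2L, 1L), drop = FALSE]] <- spec$weights
  }
  J
}

#' Local field at every node
#'
#' `tau_i = sum_{j in N(i)} J_ij S_j` for a given global state.
#'
#' @param spec A [system_spec()].
#' @param state Optional state vector; defaults to the spec's assigned state.
#' @return Numeric vector of length `n_nodes`.
#' @export
local_fields <- function(spec, state = spec$state) {
  as.numeric(coupling_matrix(spec) %*% state)
}

#' Boltzmann conditional flip probability of one node
#'
#' Probability that node `i` takes state `s` at the next step given the
#' current global state: `1 / (1 + exp(-2 * tau_i * s / T))`.
#'
#' @param spec A [system_spec()].
#' @param i Node index (1-based).
#' @param s Target state, `+1` or `-1`.
#' @param state Optional conditioning state; defaults to the assigned state.
#' @return Probability in `(0, 1)`.
#' @export
conditional_probability <- function(spec, i, s, state = spec$state) {
  stopifnot(i >= 1L, i <= spec$n_nodes, s %in% c(-1, 1))
  tau <- sum(coupling_matrix(spec)[i, ] * state)
  p_plus <- 1 / (1 + exp(-2 * tau / spec$temperature))
  # the -1 probability is defined as the exact complement so that the two
  # conditionals sum to 1 in floating point as well as on paper
  if (s > 0) p_plus else 1 - p_plus
}

# All 2^n global states as a (2^n x n) matrix of +1/-1, little-endian:
# node 1 varies fastest; row r (1-based) encodes r-1 with bit b -> node b+1,
# bit 1 mapping to state +1 and bit 0 to state -1.
enumerate_states <- function(n) {
  stopifnot(n >= 1L, n <= 24L)
  S <- matrix(-1, nrow = 2^n, ncol = n)
  for (i in seq_len(n))
    S[, i] <- rep(rep(c(-1, 1), each = 2^(i - 1L)), length.out = 2^n)
  S
}

# Row index (1-based) of a +1/-1 state vector under the little-endian order.
state_row_index <- function(state) {
  bits <- as.integer(state > 0)
  sum(bits * 2^(seq_along(state) - 1L)) + 1L
}

#' Build the transition model of a system
#'
#' Materialises the state-by-node transition table: for each of the `2^N`
#' current states (rows, little-endian order: node 1 varies fastest, bit 1
#' meaning state `+1`), the probability that each node is `+1` at the next
#' step. Full-state transition probabilities follow by conditional
#' independence as `p(S*|S) = prod_i p_i(S*_i|S)`.
#'
#' @param spec A [system_spec()].
#' @param full Whether to materialise the full `2^N`-row table (default if
#'   `N <= cap`); otherwise only the node conditionals at the assigned state.
#' @param cap Largest `N` for which the full table may be built.
#' @return An object of class `"transition_model"` with elements `tpm`
#'   (`2^N x N`, or `NULL`), `p_plus_current` (length-`N` conditionals at the
#'   assigned state), `states`, and the generating `spec`.
#' @export
build_transition_model <- function(spec, full = spec$n_nodes <= cap, cap = 20L) {
  n <- spec$n_nodes
  J <- coupling_matrix(spec)
  p_cur <- 1 / (1 + exp(-2 * as.numeric(J %*% spec$state) / spec$temperature))
  tpm <- NULL; states <- NULL
  if (full) {
    if (n > cap)
      stop(sprintf("full transition table for N = %d exceeds the cap (%d)", n, cap))
    states <- enumerate_states(n)
    tau <- states %*% J            # row r, column i: tau_i at state r
    tpm <- 1 / (1 + exp(-2 * tau / spec$temperature))
  }
  structure(list(tpm = tpm, states = states, p_plus_current = p_cur,
                 spec = spec), class = "transition_model")
}

#' Full-state transition probability
#'
#' `p(to | from)` under conditional independence across nodes.
#'
#' @param model A [build_transition_model()] result (full table not required).
#' @param from,to State vectors of `+1/-1`.
#' @return Probability.
#' @export
transition_probability <- function(model, from, to) {
  spec <- model$spec
  p_plus <- 1 / (1 + exp(-2 * local_fields(spec, from) / spec$temperature))
  prod(ifelse(to > 0, p_plus, 1 - p_plus))
}

#' Full 2^N x 2^N state-transition matrix
#'
#' Rows index the current state, columns the successor, both little-endian.
#' Intended for small systems (`N <= 12`).
#'
#' @param model A full [build_transition_model()] result.
#' @return A `2^N x 2^N` stochastic matrix.
#' @export
state_transition_matrix <- function(model) {
  if (is.null(model$tpm)) stop("model was built without the full table")
  n <- ncol(model$tpm)
  if (n > 12L) stop("state-transition matrix limited to N <= 12")
  S <- model$states
  P <- matrix(1, 2^n, 2^n)
  for (i in seq_len(n)) {
    pi_plus <- model$tpm[, i]
    # column block: successor state of node i per column
    succ_plus <- S[, i] > 0
    P <- P * ifelse(matrix(succ_plus, nrow = 2^n, ncol = 2^n, byrow = TRUE),
                    pi_plus, 1 - pi_plus)
  }
  P
}

#' Generate a random system
#'
#' Each of the `C(n,2)` node pairs becomes an edge independently with
#' probability `edge_prob`; weights are standard normal; one temperature is
#' drawn uniformly from `t_range` and shared by all nodes; the state is
#' uniform over `{+1,-1}^n`. Four independent child streams (topology,
#' weights, temperature, state) are derived from `seed`.
#'
#' @param n Number of nodes (>= 2).
#' @param edge_prob Edge probability in `[0, 1]`.
#' @param t_range Temperature interval, default `c(0.1, 3.0)`.
#' @param seed Integer seed.
#' @return A [system_spec()].
#' @export
generate_random_system <- function(n, edge_prob = 0.4, t_range = c(0.1, 3.0),
                                   seed = 1L) {
  if (n < 2L) stop("n must be >= 2")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  if (length(t_range) != 2L || any(t_range <= 0) || t_range[2] < t_range[1])
    stop("t_range must be a positive, non-empty interval")
  pairs <- t(utils::combn(n, 2L))
  keep <- with_seed(child_seed(seed, "topology"),
                    stats::runif(nrow(pairs)) < edge_prob)
  edges <- pairs[keep, , drop = FALSE]
  weights <- with_seed(child_seed(seed, "weights"), stats::rnorm(nrow(edges)))
  temperature <- with_seed(child_seed(seed, "temperature"),
                           stats::runif(1, t_range[1], t_range[2]))
  state <- with_seed(child_seed(seed, "state"),
                     sample(c(-1, 1), n, replace = TRUE))
  system_spec(n, edges, weights, temperature, state,
              meta = list(rng_seed = seed, generator = "random",
                          edge_prob = edge_prob))
}

# Uniform random labelled tree on n nodes via a uniform Pruefer sequence.
random_tree_edges <- function(n) {
  if (n == 2L) return(matrix(c(1L, 2L), ncol = 2L))
  pruefer <- sample.int(n, n - 2L, replace = TRUE)
  # standard decode
  degree <- tabulate(pruefer, nbins = n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(pruefer)) {
    leaf <- which(degree == 1L)[1L]
    edges[k, ] <- c(leaf, pruefer[k])
    degree[leaf] <- degree[leaf] - 1L
    degree[pruefer[k]] <- degree[pruefer[k]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

#' Generate a special-topology system
#'
#' `"tree"`: a uniformly random spanning tree (exactly `n - 1` edges, no
#' cycles). `"full"`: all `C(n,2)` edges. `"loop"`: `round(0.4 * C(n,2))`
#' edges for `n >= 6` and `n + 1` edges for `n` in `{4, 5}`, sampled without
#' replacement and guaranteed to contain at least one cycle. Weights,
#' temperature and state are drawn as in [generate_random_system()].
#'
#' @param kind One of `"tree"`, `"full"`, `"loop"`.
#' @param n Number of nodes (>= 4 for tree/loop).
#' @param t_range Temperature interval.
#' @param seed Integer seed.
#' @return A [system_spec()].
#' @export
generate_topology <- function(kind = c("tree", "full", "loop"), n,
                              t_range = c(0.1, 3.0), seed = 1L) {
  kind <- match.arg(kind)
  if (kind != "full" && n < 4L) stop("tree/loop topologies require n >= 4")
  if (n < 2L) stop("n must be >= 2")
  edges <- with_seed(child_seed(seed, paste0("topology:", kind)), {
    if (kind == "tree") {
      random_tree_edges(n)
    } else if (kind == "full") {
      t(utils::combn(n, 2L))
    } else {
      m <- if (n >= 6L) round(0.4 * choose(n, 2L)) else n + 1L
      pairs <- t(utils::combn(n, 2L))
      repeat {
        sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
        g <- igraph::graph_from_edgelist(sel, directed = FALSE)
        if (igraph::gsize(g) - (igraph::vcount(g) -
                                igraph::count_components(g)) > 0) break
      }
      sel
    }
  })
  m <- nrow(edges)
  weights <- with_seed(child_seed(seed, "weights"), stats::rnorm(m))
  temperature <- with_seed(child_seed(seed, "temperature"),
                           stats::runif(1, t_range[1], t_range[2]))
  state <- with_seed(child_seed(seed, "state"),
                     sample(c(-1, 1), n, replace = TRUE))
  system_spec(n, edges, weights, temperature, state,
              meta = list(rng_seed = seed, generator = "topology", kind = kind))
}

#' Generate a split-brain-like two-block system
#'
#' 100 nodes by default: edges appear with probability `p_intra[1]` inside
#' the first block, `p_intra[2]` inside the second, and `p_e` between blocks;
#' weights are standard normal. The block partition is recorded in
#' `meta$blocks`.
#'
#' @param p_e Inter-block edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param block_size Nodes per block (default 50).
#' @param p_intra Intra-block edge probabilities, default `c(0.6, 0.4)`.
#' @param t_range Temperature interval.
#' @return A [system_spec()] whose `meta$blocks` lists the two node sets.
#' @export
generate_split_brain <- function(p_e, seed = 1L, block_size = 50L,
                                 p_intra = c(0.6, 0.4),
                                 t_range = c(0.1, 3.0)) {
  if (p_e < 0 || p_e > 1) stop("p_e must be in [0, 1]")
  n <- 2L * block_size
  pairs <- t(utils::combn(n, 2L))
  block <- function(v) ifelse(v <= block_size, 1L, 2L)
  b1 <- block(pairs[, 1L]); b2 <- block(pairs[, 2L])
  prob <- ifelse(b1 == 1L & b2 == 1L, p_intra[1],
                 ifelse(b1 == 2L & b2 == 2L, p_intra[2], p_e))
  keep <- with_seed(child_seed(seed, "topology:splitbrain"),
                    stats::runif(nrow(pairs)) < prob)
  edges <- pairs[keep, , drop = FALSE]
  weights <- with_seed(child_seed(seed, "weights"), stats::rnorm(nrow(edges)))
  temperature <- with_seed(child_seed(seed, "temperature"),
                           stats::runif(1, t_range[1], t_range[2]))
  state <- with_seed(child_seed(seed, "state"),
                     sample(c(-1, 1), n, replace = TRUE))
  system_spec(n, edges, weights, temperature, state,
              meta = list(rng_seed = seed, generator = "split_brain", p_e = p_e,
                          blocks = list(seq_len(block_size),
                                        seq.int(block_size + 1L, n))))
}

#' Simulate the Markov dynamics of a system
#'
#' Samples `nsteps` successive global states, all nodes updating in parallel
#' from their Boltzmann conditionals.
#'
#' @param spec A [system_spec()].
#' @param nsteps Number of steps.
#' @param seed Integer seed.
#' @return A `(nsteps + 1) x N` matrix of `+1/-1` states (first row = the
#'   assigned state).
#' @export
simulate_states <- function(spec, nsteps = 10L, seed = 1L) {
  J <- coupling_matrix(spec)
  out <- matrix(0, nsteps + 1L, spec$n_nodes)
  out[1L, ] <- spec$state
  with_seed(child_seed(seed, "simulate"), {
    s <- spec$state
    for (t in seq_len(nsteps)) {
      p_plus <- 1 / (1 + exp(-2 * as.numeric(J %*% s) / spec$temperature))
      s <- ifelse(stats::runif(spec$n_nodes) < p_plus, 1, -1)
      out[t + 1L, ] <- s
    }
  })
  out
}
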