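# The multi-task transformer-convolution network.
#
# Four transformer-convolution layers with H-head, edge-aware attention:
#   q_i^h = Wq^h x_i,  k_j^h = Wk^h x_j,  v_j^h = Wv^h x_j
#   alpha_ij^h = softmax_j( q_i^h . (k_j^h + We^h e_ij) / kappa )
#   z_i^h = W0^h x_i + sum_j alpha_ij^h (v_j^h + We^h e_ij)
#   z_i   = concat_h z_i^h                     (dimension C*H)
# Batch normalisation, ReLU and dropout follow each of the first three
# layers. After the fourth layer the network splits: Branch 1 applies global
# max pooling, dropout and an affine map to a scalar phi estimate; Branch 2
# subtracts the pooled vector from every node embedding and applies an
# affine map to two logits ("in"/"out") followed by a softmax.
#
# The backward pass is derived by hand and validated against finite
# differences in the test suite. All ops are plain matrix algebra; attention
# softmax is computed per destination node with grouped reductions.

#' Default network configuration
#'
#' @param d_in Input feature dimension (6).
#' @param channels Channels per head `C` (16).
#' @param heads Attention heads `H` (4); hidden width is `C * H`.
#' @param layers Number of transformer layers (4).
#' @param dropout Dropout rate after the first three layers and before the
#'   phi head (0.2).
#' @param kappa Attention scaling; default `C / H`.
#' @param relu Apply ReLU after each batch-normalised block.
#' @param bn_momentum,bn_eps Batch-normalisation running-statistics momentum
#'   and variance floor.
#' @return A named list of configuration values.
#' @export
phinet_config <- function(d_in = 6L, channels = 16L, heads = 4L, layers = 4L,
                          dropout = 0.2, kappa = NULL, relu = TRUE,
                          bn_momentum = 0.1, bn_eps = 1e-5) {
  if (is.null(kappa)) kappa <- channels / heads
  list(d_in = as.integer(d_in), channels = as.integer(channels),
       heads = as.integer(heads), layers = as.integer(layers),
       dropout = dropout, kappa = kappa, relu = isTRUE(relu),
       bn_momentum = bn_momentum, bn_eps = bn_eps,
       hidden = as.integer(channels * heads))
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise network parameters
#'
#' Glorot-uniform weights, zero biases, unit batch-norm scale.
#'
#' @param config A [phinet_config()].
#' @param seed Integer seed.
#' @return A list with `params` (trainable tensors) and `bn_state`
#'   (running batch-norm statistics).
#' @export
init_params <- function(config, seed = 1L) {
  CH <- config$hidden
  with_seed(child_seed(seed, "init"), {
    conv <- lapply(seq_len(config$layers), function(l) {
      d <- if (l == 1L) config$d_in else CH
      list(Wq = glorot(d, CH), Wk = glorot(d, CH), Wv = glorot(d, CH),
           Wo = glorot(d, CH), We = glorot(1L, CH))
    })
    bn <- lapply(seq_len(max(0L, config$layers - 1L)), function(l)
      list(gamma = rep(1, CH), beta = rep(0, CH)))
    params <- list(conv = conv, bn = bn,
                   phi = list(W = glorot(CH, 1L), b = 0),
                   cls = list(W = glorot(CH, 2L), b = c(0, 0)))
    bn_state <- lapply(seq_len(max(0L, config$layers - 1L)), function(l)
      list(mean = rep(0, CH), var = rep(1, CH)))
    list(params = params, bn_state = bn_state)
  })
}

# grouped softmax over rows of `scores` (M x H) with integer groups g
group_softmax <- function(scores, g) {
  gi <- match(g, sort(unique(g)))
  ng <- max(gi)
  mx <- matrix(0, ng, ncol(scores))
  for (h in seq_len(ncol(scores)))
    mx[, h] <- as.numeric(tapply(scores[, h], gi, max))
  ex <- exp(scores - mx[gi, , drop = FALSE])
  sm <- rowsum(ex, gi)
  list(alpha = ex / sm[gi, , drop = FALSE], gi = gi)
}

# rowsum into a fixed number of rows (groups absent from `g` give zeros)
rowsum_n <- function(x, g, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Attention weights of one transformer layer
#'
#' Returns the per-head attention map for given node vectors; rows align
#' with the directed edges of the graph (source j, destination i).
#'
#' @param layer Conv-layer parameter list (`Wq`, `Wk`, `Wv`, `Wo`, `We`).
#' @param g A feature graph (for `edge_index` / `edge_attr`).
#' @param x Node-vector matrix (`N x d`).
#' @param config A [phinet_config()].
#' @return A list: `alpha` (`M x H` matrix, one row per directed edge),
#'   `src`, `dst`.
#' @export
attention_weights <- function(layer, g, x, config) {
  if (ncol(x) != nrow(layer$Wq)) stop("node-vector dimension mismatch")
  M <- ncol(g$edge_index)
  H <- config$heads; C <- config$channels
  if (M == 0L)
    return(list(alpha = matrix(0, 0L, H), src = integer(0), dst = integer(0)))
  src <- g$edge_index[1L, ]; dst <- g$edge_index[2L, ]
  Q <- x %*% layer$Wq; K <- x %*% layer$Wk
  Eh <- g$edge_attr %*% layer$We
  A <- K[src, , drop = FALSE] + Eh
  P <- Q[dst, , drop = FALSE] * A
  block <- matrix(0, H * C, H)
  for (h in seq_len(H)) block[((h - 1L) * C + 1L):(h * C), h] <- 1
  scores <- (P %*% block) / config$kappa
  sm <- group_softmax(scores, dst)
  list(alpha = sm$alpha, src = src, dst = dst)
}

#' Apply one transformer-convolution layer
#'
#' `z_i = W0 x_i + sum_j alpha_ij (v_j + We e_ij)` per head, heads
#' concatenated; a node with no neighbours outputs its skip term only.
#'
#' @param layer Conv-layer parameter list (`Wq`, `Wk`, `Wv`, `Wo`, `We`).
#' @param g A feature graph (for `edge_index` / `edge_attr`).
#' @param x Node-vector matrix (`N x d`).
#' @param config A [phinet_config()].
#' @return `N x (C*H)` matrix of updated node vectors.
#' @export
transformer_layer <- function(layer, g, x, config) {
  if (ncol(x) != nrow(layer$Wq)) stop("node-vector dimension mismatch")
  conv_forward(layer, x, g$edge_index, g$edge_attr, config)$z
}

# Forward through one conv layer; returns z and a cache for backprop.
conv_forward <- function(layer, x, edge_index, edge_attr, config) {
  N <- nrow(x); H <- config$heads; C <- config$channels; CH <- H * C
  M <- ncol(edge_index)
  z <- x %*% layer$Wo
  if (M == 0L)
    return(list(z = z, cache = list(x = x, M = 0L)))
  src <- edge_index[1L, ]; dst <- edge_index[2L, ]
  Q <- x %*% layer$Wq; K <- x %*% layer$Wk; V <- x %*% layer$Wv
  Eh <- edge_attr %*% layer$We
  A <- K[src, , drop = FALSE] + Eh
  block <- matrix(0, CH, H)
  for (h in seq_len(H)) block[((h - 1L) * C + 1L):(h * C), h] <- 1
  scores <- ((Q[dst, , drop = FALSE] * A) %*% block) / config$kappa
  sm <- group_softmax(scores, dst)
  alpha <- sm$alpha
  expand <- rep(seq_len(H), each = C)
  alpha_full <- alpha[, expand, drop = FALSE]
  VE <- V[src, , drop = FALSE] + Eh
  msg <- alpha_full * VE
  z <- z + rowsum_n(msg, dst, N)
  list(z = z,
       cache = list(x = x, M = M, src = src, dst = dst, Q = Q, K = K, V = V,
                    Eh = Eh, A = A, VE = VE, alpha = alpha, gi = sm$gi,
                    block = block, expand = expand, edge_attr = edge_attr))
}

# Backward through one conv layer.
conv_backward <- function(layer, dz, cache, config) {
  x <- cache$x
  grads <- list(Wq = matrix(0, nrow(layer$Wq), ncol(layer$Wq)),
                Wk = matrix(0, nrow(layer$Wk), ncol(layer$Wk)),
                Wv = matrix(0, nrow(layer$Wv), ncol(layer$Wv)),
                Wo = crossprod(x, dz),
                We = matrix(0, 1L, ncol(layer$We)))
  dx <- dz %*% t(layer$Wo)
  if (cache$M == 0L) return(list(dx = dx, grads = grads))
  src <- cache$src; dst <- cache$dst
  N <- nrow(x)
  dmsg <- dz[dst, , drop = FALSE]
  dalpha <- (dmsg * cache$VE) %*% cache$block
  dVE <- cache$alpha[, cache$expand, drop = FALSE] * dmsg
  # softmax backward per destination group
  inner <- rowsum(cache$alpha * dalpha, cache$gi)
  ds <- cache$alpha * (dalpha - inner[cache$gi, , drop = FALSE])
  ds_full <- ds[, cache$expand, drop = FALSE] / config$kappa
  dQ <- rowsum_n(ds_full * cache$A, dst, N)
  dA <- ds_full * cache$Q[dst, , drop = FALSE]
  dK <- rowsum_n(dA, src, N)
  dEh <- dA + dVE
  dV <- rowsum_n(dVE, src, N)
  grads$Wq <- crossprod(x, dQ)
  grads$Wk <- crossprod(x, dK)
  grads$Wv <- crossprod(x, dV)
  grads$We <- crossprod(cache$edge_attr, dEh)
  dx <- dx + dQ %*% t(layer$Wq) + dK %*% t(layer$Wk) + dV %*% t(layer$Wv)
  list(dx = dx, grads = grads)
}

bn_forward <- function(p, state, x, config, train) {
  eps <- config$bn_eps
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
    sd_ <- sqrt(v + eps)
    xhat <- sweep(sweep(x, 2L, mu), 2L, sd_, "/")
    mom <- config$bn_momentum
    state$mean <- (1 - mom) * state$mean + mom * mu
    state$var <- (1 - mom) * state$var + mom * v
    cache <- list(xhat = xhat, sd = sd_, n = nrow(x))
  } else {
    sd_ <- sqrt(state$var + eps)
    xhat <- sweep(sweep(x, 2L, state$mean), 2L, sd_, "/")
    cache <- list(xhat = xhat, sd = sd_, n = nrow(x))
  }
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(y = y, state = state, cache = cache)
}

bn_backward <- function(p, dy, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, p$gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*"),
                    2L, cache$sd, "/"), 2L, 1, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Global max pooling over nodes of each graph
#'
#' @param z Node-embedding matrix (`N x CH`).
#' @param graph Integer graph id per node.
#' @return A list: `r` (`G x CH` pooled matrix) and `argmax` (`G x CH`
#'   global row indices attaining the maxima; first index on ties).
#' @export
global_max_pool <- function(z, graph) {
  if (nrow(z) == 0L) stop("empty graph: nothing to pool")
  gids <- sort(unique(graph))
  G <- length(gids)
  r <- matrix(0, G, ncol(z))
  am <- matrix(0L, G, ncol(z))
  for (k in seq_len(G)) {
    rows <- which(graph == gids[k])
    zb <- z[rows, , drop = FALSE]
    loc <- max.col(t(zb), ties.method = "first")
    am[k, ] <- rows[loc]
    r[k, ] <- zb[cbind(loc, seq_len(ncol(z)))]
  }
  list(r = r, argmax = am)
}

#' Subtract the pooled graph vector from every node embedding
#'
#' Every entry of the result is `<= 0` by construction.
#'
#' @param z Node-embedding matrix.
#' @param r Pooled matrix from [global_max_pool()].
#' @param graph Integer graph id per node.
#' @return `N x CH` matrix `z_i - r_{graph(i)}`.
#' @export
subtract_pooled <- function(z, r, graph) {
  gi <- match(graph, sort(unique(graph)))
  z - r[gi, , drop = FALSE]
}

#' Forward pass of the network
#'
#' @param model A list with `params`, `bn_state`, `config` (see
#'   [init_params()]).
#' @param batch A (possibly batched) normalised feature graph.
#' @param train Training mode: batch statistics for batch norm, active
#'   dropout (uses the current RNG stream).
#' @param keep_cache Keep intermediate tensors for backprop.
#' @return A list with `phi_hat` (length-G), `prob_in` (length-N), `logits`,
#'   `z` (final node embeddings), `r`, updated `bn_state`, and (optionally)
#'   `cache`.
#' @export
nn_forward <- function(model, batch, train = FALSE, keep_cache = FALSE) {
  params <- model$params; config <- model$config
  bn_state <- model$bn_state
  x <- batch$x
  L <- config$layers
  cache <- list(layers = vector("list", L), bn = vector("list", L),
                relu = vector("list", L), drop = vector("list", L))
  for (l in seq_len(L)) {
    cf <- conv_forward(params$conv[[l]], x, batch$edge_index, batch$edge_attr,
                       config)
    cache$layers[[l]] <- cf$cache
    x <- cf$z
    if (l < L) {
      bf <- bn_forward(params$bn[[l]], bn_state[[l]], x, config, train)
      bn_state[[l]] <- bf$state
      cache$bn[[l]] <- bf$cache
      x <- bf$y
      if (config$relu) {
        mask <- x > 0
        cache$relu[[l]] <- mask
        x <- x * mask
      }
      if (train && config$dropout > 0) {
        keep <- matrix(stats::runif(length(x)) >= config$dropout, nrow(x))
        cache$drop[[l]] <- keep
        x <- x * keep / (1 - config$dropout)
      }
    }
  }
  z <- x
  pool <- global_max_pool(z, batch$graph)
  r <- pool$r
  r_do <- r
  if (train && config$dropout > 0) {
    keepr <- matrix(stats::runif(length(r)) >= config$dropout, nrow(r))
    cache$drop_r <- keepr
    r_do <- r * keepr / (1 - config$dropout)
  }
  phi_hat <- as.numeric(r_do %*% params$phi$W + params$phi$b)
  u <- subtract_pooled(z, r, batch$graph)
  logits <- sweep(u %*% params$cls$W, 2L, params$cls$b, "+")
  mx <- pmax(logits[, 1L], logits[, 2L])
  ex <- exp(logits - mx)
  prob <- ex / rowSums(ex)
  out <- list(phi_hat = phi_hat, prob_in = prob[, 1L], prob = prob,
              logits = logits, z = z, r = r, bn_state = bn_state)
  if (keep_cache) {
    cache$pool <- pool
    cache$u <- u
    cache$r_do <- r_do
    cache$batch <- batch
    out$cache <- cache
  }
  out
}

#' Composite multi-task loss
#'
#' `MSE(phi_hat, phi) + ce_weight * CE` where the cross-entropy is averaged
#' over nodes with a per-term class weight (`out_weight` on "out" nodes, 1 on
#' "in" nodes).
#'
#' @param phi_hat,phi Predicted / true graph-level values (length G).
#' @param prob `N x 2` class probabilities (columns: in, out).
#' @param y_in Logical length-N vector, `TRUE` for nodes in the major
#'   complex.
#' @param out_weight Penalty factor on "out" terms (1.8).
#' @param ce_weight Multiplier on the classification term (5).
#' @return Scalar loss; attributes `mse` and `ce` carry the two components.
#' @export
composite_loss <- function(phi_hat, phi, prob, y_in, out_weight = 1.8,
                           ce_weight = 5) {
  mse <- mean((phi_hat - phi)^2)
  p_true <- ifelse(y_in, prob[, 1L], prob[, 2L])
  w <- ifelse(y_in, 1, out_weight)
  ce <- sum(w * -log(pmax(p_true, 1e-300))) / length(y_in)
  structure(mse + ce_weight * ce, mse = mse, ce = ce)
}

# Full backward pass: returns gradients shaped like `params`.
nn_backward <- function(model, fwd, phi, y_in, out_weight = 1.8,
                        ce_weight = 5) {
  params <- model$params; config <- model$config
  cache <- fwd$cache
  batch <- cache$batch
  G <- length(fwd$phi_hat); N <- nrow(fwd$prob)
  L <- config$layers
  grads <- list(conv = vector("list", L), bn = vector("list", L - 1L),
                phi = list(), cls = list())
  # heads
  dphi <- matrix(2 * (fwd$phi_hat - phi) / G, ncol = 1L)
  Y <- cbind(as.numeric(y_in), as.numeric(!y_in))
  w <- ifelse(y_in, 1, out_weight)
  dlogits <- (fwd$prob - Y) * (w * ce_weight / N)
  grads$phi$W <- crossprod(cache$r_do, dphi)
  grads$phi$b <- sum(dphi)
  dr_do <- dphi %*% t(params$phi$W)
  if (!is.null(cache$drop_r)) dr_do <- dr_do * cache$drop_r / (1 - config$dropout)
  grads$cls$W <- crossprod(cache$u, dlogits)
  grads$cls$b <- colSums(dlogits)
  du <- dlogits %*% t(params$cls$W)
  gi <- match(batch$graph, sort(unique(batch$graph)))
  dz <- du
  dr <- dr_do - rowsum(du, gi)
  # max-pool backward
  am <- cache$pool$argmax
  CH <- ncol(dz)
  for (k in seq_len(G))
    dz[cbind(am[k, ], seq_len(CH))] <- dz[cbind(am[k, ], seq_len(CH))] + dr[k, ]
  # blocks in reverse
  for (l in rev(seq_len(L))) {
    if (l < L) {
      if (!is.null(cache$drop[[l]]))
        dz <- dz * cache$drop[[l]] / (1 - config$dropout)
      if (config$relu) dz <- dz * cache$relu[[l]]
      bb <- bn_backward(params$bn[[l]], dz, cache$bn[[l]])
      grads$bn[[l]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      dz <- bb$dx
    }
    cb <- conv_backward(params$conv[[l]], dz, cache$layers[[l]], config)
    grads$conv[[l]] <- cb$grads
    dz <- cb$dx
  }
  grads
}

# ---- parameter-tree utilities -------------------------------------------

# apply f elementwise over two parallel parameter trees
par_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- par_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

par_map <- function(f, a) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- par_map(f, a[[nm]])
    a
  } else f(a)
}

# flatten a parameter tree into one named numeric vector
par_flatten <- function(p, prefix = "") {
  if (is.list(p)) {
    nms <- names(p)
    if (is.null(nms)) nms <- as.character(seq_along(p))
    out <- lapply(seq_along(p), function(k)
      par_flatten(p[[k]], paste0(prefix, if (nzchar(prefix)) "." else "", nms[k])))
    do.call(c, out)
  } else {
    v <- as.numeric(p)
    names(v) <- if (length(v) == 1L) prefix
    else paste0(prefix, "[", seq_along(v), "]")
    v
  }
}

# write a flat vector back into the shape of tree `p`
par_unflatten <- function(p, v, pos = 1L) {
  if (is.list(p)) {
    for (k in seq_along(p)) {
      res <- par_unflatten(p[[k]], v, pos)
      p[[k]] <- res$p; pos <- res$pos
    }
    list(p = p, pos = pos)
  } else {
    len <- length(p)
    newp <- p
    newp[] <- v[pos:(pos + len - 1L)]
    list(p = newp, pos = pos + len)
  }
}
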