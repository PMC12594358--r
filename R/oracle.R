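# Exact ground-truth labeling engine.
#
# Labels are the system-level integrated information Phi of the major complex
# and the complex's node set. The engine computes, exactly and exhaustively
# for N <= 8, a state-conditional effective-information measure:
#
#   For a candidate subsystem M (|M| >= 2), with all nodes outside M frozen
#   at the assigned state, and for a bipartition {A, B} of M:
#
#     ei(M; A, B) = sum_{i in A} KL( p_i(. | S) || p_i^{A}(.) )
#                 + sum_{i in B} KL( p_i(. | S) || p_i^{B}(.) )
#
#   where p_i^{A}(.) marginalises the inputs that node i receives from the
#   other part B uniformly (inputs from A and from outside M stay at the
#   assigned state). phi(M) is the minimum of ei over all bipartitions (the
#   minimum-information bipartition), and the system label is
#
#     Phi = max_M phi(M),  major complex = argmax_M phi(M).
#
# This is an integration measure in the effective-information / minimum-
# information-partition family, computed exactly at the assigned state. It
# deliberately does not implement cause-effect repertoires, mechanism-level
# integration, or earth-mover distances; the oracle interface is pluggable,
# so labels from any engine producing {phi, major_complex} can be substituted
# via the JSONL label cache.

PHINET_ENGINE_VERSION <- "phinet-ei-mip/1.0"

# KL divergence between two Bernoulli(+1) distributions given p = P(+1).
bernoulli_kl <- function(p, q) {
  term <- function(a, b) if (a == 0) 0 else a * log(a / b)
  term(p, q) + term(1 - p, 1 - q)
}

# Conditional p_i(+1 | state) with inputs from nodes in `marg` marginalised
# uniformly over their 2^|marg| joint states; all other nodes at `state`.
marginal_p_plus <- function(J, Tt, i, state, marg) {
  nb <- which(J[i, ] != 0)
  marg_nb <- intersect(nb, marg)
  fixed_nb <- setdiff(nb, marg)
  base <- if (length(fixed_nb)) sum(J[i, fixed_nb] * state[fixed_nb]) else 0
  if (length(marg_nb) == 0L)
    return(1 / (1 + exp(-2 * base / Tt)))
  S <- enumerate_states(length(marg_nb))
  taus <- base + as.numeric(S %*% J[i, marg_nb])
  mean(1 / (1 + exp(-2 * taus / Tt)))
}

# phi of one subsystem: effective information across the minimum-information
# bipartition at the assigned state. The bipartition is selected under the
# usual size normalisation (ei divided by the smaller part's size, the
# per-capacity cost of the cut); the reported phi is the unnormalised ei at
# that cut, so it can grow with subsystem size.
subsystem_phi <- function(J, Tt, state, nodes) {
  m <- length(nodes)
  if (m < 2L) return(0)
  p_actual <- vapply(nodes, function(i) {
    tau <- sum(J[i, ] * state)
    1 / (1 + exp(-2 * tau / Tt))
  }, numeric(1))
  names(p_actual) <- as.character(nodes)
  best <- Inf; best_raw <- 0
  # bipartitions {A, B}: iterate subsets of nodes[-1] so each {A,B} appears once
  rest <- nodes[-1L]
  n_sub <- 2^(m - 1L) - 1L        # proper, non-empty B
  for (mask in seq_len(n_sub)) {
    B <- rest[bitwAnd(mask, 2^(seq_len(m - 1L) - 1L)) > 0]
    A <- setdiff(nodes, B)
    ei <- 0
    for (i in A) {
      q <- marginal_p_plus(J, Tt, i, state, marg = B)
      ei <- ei + bernoulli_kl(p_actual[[as.character(i)]], q)
    }
    for (i in B) {
      q <- marginal_p_plus(J, Tt, i, state, marg = A)
      ei <- ei + bernoulli_kl(p_actual[[as.character(i)]], q)
    }
    score <- ei / min(length(A), length(B))
    if (score < best) { best <- score; best_raw <- ei }
    if (best == 0) break
  }
  best_raw
}

#' Compute exact ground-truth labels for a small system
#'
#' Runs the exhaustive subsystem search described in the package vignette:
#' every node subset of size at least two is scored by its
#' minimum-information-bipartition effective information at the assigned
#' state; the maximising subset is the major complex and its score is the
#' system-level integrated information. A system whose maximum is zero (no
#' causal interactions) is labeled `phi = 0` with an empty complex.
#'
#' Labels are invariant under global state inversion and equivariant under
#' node relabeling. Ties between subsystems with equal maximal scores are
#' broken deterministically by enumeration order (increasing size, then
#' lexicographic) and flagged in the result.
#'
#' @param spec A [system_spec()] with `N <= cap`.
#' @param cap Exhaustive-search size cap (default 8).
#' @return A list with `phi` (non-negative), `major_complex` (1-based sorted
#'   node indices, possibly empty), `engine_version`, `tie` flag, and `hash`.
#' @export
compute_labels <- function(spec, cap = 8L) {
  n <- spec$n_nodes
  if (n > cap)
    stop(sprintf("exact labeling is exponential; N = %d exceeds cap %d", n, cap))
  J <- coupling_matrix(spec)
  Tt <- spec$temperature
  state <- spec$state
  best_phi <- 0; best_set <- integer(0); tie <- FALSE
  for (size in 2:max(2L, n)) {
    if (size > n) break
    combs <- utils::combn(n, size)
    for (c_idx in seq_len(ncol(combs))) {
      nodes <- combs[, c_idx]
      ph <- subsystem_phi(J, Tt, state, nodes)
      if (ph > best_phi + 1e-12) {
        best_phi <- ph; best_set <- nodes; tie <- FALSE
      } else if (ph > 0 && abs(ph - best_phi) <= 1e-12 && length(best_set)) {
        tie <- TRUE
      }
    }
  }
  if (best_phi <= 1e-12) {
    best_phi <- 0; best_set <- integer(0)
  }
  list(phi = best_phi, major_complex = sort(as.integer(best_set)),
       engine_version = PHINET_ENGINE_VERSION, tie = tie,
       hash = spec_hash(spec))
}

#' Label a dataset with caching
#'
#' Fetches labels from a JSONL cache keyed by content hash; cache misses are
#' computed with [compute_labels()] and appended, so batch labeling is
#' resumable.
#'
#' @param specs List of [system_spec()] objects.
#' @param cache_path Optional path of the JSONL label cache; `NULL` disables
#'   caching.
#' @param cap Size cap forwarded to [compute_labels()].
#' @param progress_every Log a progress line to stderr every this many
#'   computed labels (0 silences logging).
#' @return List of labels, aligned with `specs`.
#' @export
label_dataset <- function(specs, cache_path = NULL, cap = 8L,
                          progress_every = 0L) {
  cache <- if (is.null(cache_path)) list() else read_labels_jsonl(cache_path)
  out <- vector("list", length(specs))
  n_computed <- 0L
  for (k in seq_along(specs)) {
    h <- spec_hash(specs[[k]])
    if (!is.null(cache[[h]])) {
      out[[k]] <- cache[[h]]
    } else {
      lab <- compute_labels(specs[[k]], cap = cap)
      out[[k]] <- lab
      cache[[h]] <- lab
      n_computed <- n_computed + 1L
      if (!is.null(cache_path))
        cat(jsonl_label_line(lab), file = cache_path, append = TRUE, sep = "\n")
      if (progress_every > 0L && n_computed %% progress_every == 0L)
        message(sprintf("labeled %d/%d systems", k, length(specs)))
    }
  }
  out
}

jsonl_label_line <- function(lab) {
  sprintf('{"hash":"%s","phi":%s,"major_complex":[%s],"engine_version":"%s"%s}',
          lab$hash, json_num(lab$phi),
          paste(as.integer(lab$major_complex) - 1L, collapse = ","),
          lab$engine_version,
          if (isTRUE(lab$tie)) ',"tie":true' else "")
}

#' Build a frozen fixture pack of labeled systems
#'
#' Generates random systems for each requested size, labels them with the
#' exact engine, audits the label invariants (state-inversion invariance and
#' non-negativity) and writes `systems_n<k>.jsonl` files plus one
#' `labels.jsonl` cache into `dir`. Aborts without writing if the audit
#' fails.
#'
#' @param counts Named integer vector, e.g. `c("3" = 60, "4" = 100)`; names
#'   are node counts.
#' @param dir Output directory (created if needed).
#' @param seed Root seed.
#' @param edge_prob,t_range Generator settings.
#' @return Invisibly, the list of file paths written.
#' @export
build_fixture_pack <- function(counts, dir, seed = 1L, edge_prob = 0.4,
                               t_range = c(0.1, 3.0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_specs <- list(); per_size <- list()
  for (nm in names(counts)) {
    n <- as.integer(nm)
    specs <- lapply(seq_len(counts[[nm]]), function(k)
      generate_random_system(n, edge_prob, t_range,
                             seed = child_seed(seed, sprintf("fix:%d:%d", n, k))))
    per_size[[nm]] <- specs
    all_specs <- c(all_specs, specs)
  }
  labels <- label_dataset(all_specs)
  # audit before freezing
  for (k in seq_along(all_specs)) {
    lab <- labels[[k]]
    if (lab$phi < 0) stop("audit failure: negative phi")
    flipped <- all_specs[[k]]
    flipped$state <- -flipped$state
    lab2 <- compute_labels(flipped)
    if (abs(lab2$phi - lab$phi) > 1e-9 ||
        !identical(lab2$major_complex, lab$major_complex))
      stop("audit failure: state-inversion invariance violated")
  }
  paths <- character(0)
  for (nm in names(per_size)) {
    p <- file.path(dir, sprintf("systems_n%s.jsonl", nm))
    write_systems_jsonl(per_size[[nm]], p)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "labels.jsonl")
  write_labels_jsonl(labels, lp)
  invisible(c(paths, lp))
}

#' Load the fixture pack shipped with the package
#'
#' @param sizes Node counts to load (default all shipped sizes).
#' @param dir Fixture directory; defaults to the installed package copy.
#' @return A list with `specs` and aligned `labels`.
#' @export
load_fixture_pack <- function(sizes = NULL, dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", "fixtures", package = "phinet")
  files <- list.files(dir, pattern = "^systems_n[0-9]+\\.jsonl$",
                      full.names = TRUE)
  if (!is.null(sizes)) {
    keep <- vapply(files, function(f)
      as.integer(sub(".*systems_n([0-9]+)\\.jsonl$", "\\1", f)) %in% sizes,
      logical(1))
    files <- files[keep]
  }
  specs <- do.call(c, lapply(sort(files), read_systems_jsonl))
  cache <- read_labels_jsonl(file.path(dir, "labels.jsonl"))
  labels <- lapply(specs, function(sp) {
    lab <- cache[[spec_hash(sp)]]
    if (is.null(lab)) stop("fixture label missing for a shipped system")
    lab
  })
  list(specs = specs, labels = labels)
}
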