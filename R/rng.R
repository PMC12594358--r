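# Seed plumbing: one root seed, per-purpose child streams, so that changing
# the draws for one purpose (e.g. edge topology) never shifts another
# (e.g. weights).

#' Derive a child seed from a root seed and a purpose label
#'
#' Deterministically maps `(seed, purpose)` to an integer in `[1, 2^31 - 2]`
#' via a polynomial rolling hash of the label. Used throughout the package so
#' that every source of randomness has its own stream under one root seed.
#'
#' @param seed Integer root seed.
#' @param purpose Character scalar naming the stream.
#' @return A single integer seed.
#' @export
child_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  bytes <- utf8ToInt(paste0(purpose, ":", format(seed, scientific = FALSE)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
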