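# JSON Lines serialization for systems and labels.
#
# On disk node indices are 0-based (one convention shared with common graph
# tooling); in memory they are 1-based. Floats are written at full precision
# (shortest round-trip representation).

# full-precision float literal (17 significant digits round-trip exactly)
json_num <- function(x) sprintf("%.17g", x)

spec_to_json <- function(spec) {
  edges <- vapply(seq_len(nrow(spec$edges)), function(k)
    sprintf("[%d,%d,%s]", spec$edges[k, 1L] - 1L, spec$edges[k, 2L] - 1L,
            json_num(spec$weights[k])), character(1))
  meta <- as.character(jsonlite::toJSON(spec$meta, auto_unbox = TRUE,
                                        digits = NA, null = "null"))
  sprintf('{"n":%d,"edges":[%s],"T":%s,"state":[%s],"meta":%s}',
          spec$n_nodes, paste(edges, collapse = ","),
          json_num(spec$temperature),
          paste(as.integer(spec$state), collapse = ","), meta)
}

json_to_spec <- function(line) {
  obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  m <- length(obj$edges)
  edges <- matrix(0L, m, 2L); weights <- numeric(m)
  for (k in seq_len(m)) {
    e <- obj$edges[[k]]
    edges[k, ] <- c(as.integer(e[[1]]) + 1L, as.integer(e[[2]]) + 1L)
    weights[k] <- as.numeric(e[[3]])
  }
  meta <- if (is.null(obj$meta)) list() else obj$meta
  if (!is.null(meta$blocks))
    meta$blocks <- lapply(meta$blocks, function(b) as.integer(unlist(b)))
  system_spec(obj$n, edges, weights, obj$T,
              as.numeric(unlist(obj$state)), meta = meta)
}

#' Write systems to a JSON Lines file
#'
#' One object per line: `{"n":..., "edges":[[i,j,weight],...], "T":...,
#' "state":[...], "meta":{...}}` with 0-based node indices and full-precision
#' floats.
#'
#' @param specs List of [system_spec()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_systems_jsonl <- function(specs, path) {
  writeLines(vapply(specs, spec_to_json, character(1)), path)
  invisible(path)
}

#' Read systems from a JSON Lines file
#'
#' Validates all system invariants while reconstructing each spec.
#'
#' @param path Input file path.
#' @return List of [system_spec()] objects.
#' @export
read_systems_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, json_to_spec)
}

#' Write labels to a JSON Lines cache file
#'
#' One object per line: `{"hash":..., "phi":..., "major_complex":[...],
#' "engine_version":...}` with 0-based node indices.
#'
#' @param labels List of label objects (see [compute_labels()]).
#' @param path Output file path.
#' @param hashes Optional character vector of content hashes (defaults to the
#'   `hash` element of each label).
#' @return `path`, invisibly.
#' @export
write_labels_jsonl <- function(labels, path, hashes = NULL) {
  lines <- vapply(seq_along(labels), function(k) {
    lab <- labels[[k]]
    if (!is.null(hashes)) lab$hash <- hashes[k]
    jsonl_label_line(lab)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read labels from a JSON Lines cache file
#'
#' @param path Input file path.
#' @return Named list of labels keyed by content hash; malformed lines raise
#'   an error reporting the offending line number.
#' @export
read_labels_jsonl <- function(path) {
  if (!file.exists(path)) return(structure(list(), names = character(0)))
  lines <- readLines(path)
  out <- list()
  for (k in seq_along(lines)) {
    if (!nzchar(lines[k])) next
    obj <- tryCatch(jsonlite::fromJSON(lines[k], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$hash) || is.null(obj$phi))
      stop(sprintf("corrupted label cache at line %d of %s", k, path))
    out[[obj$hash]] <- list(
      phi = as.numeric(obj$phi),
      major_complex = as.integer(unlist(obj$major_complex)) + 1L,
      engine_version = as.character(obj$engine_version),
      tie = isTRUE(obj$tie), hash = obj$hash)
  }
  out
}

#' Content hash of a system
#'
#' Hash of the canonical serialization (sorted edges, full-precision values),
#' excluding metadata, so that semantically equal specs with different edge
#' orderings map to the same key.
#'
#' @param spec A [system_spec()].
#' @return Character hash key.
#' @export
spec_hash <- function(spec) {
  canon <- paste(
    spec$n_nodes,
    paste(sprintf("%d-%d:%.17g", spec$edges[, 1L], spec$edges[, 2L],
                  spec$weights), collapse = ","),
    sprintf("%.17g", spec$temperature),
    paste(as.integer(spec$state), collapse = ""),
    sep = "|")
  bytes <- utf8ToInt(canon)
  h1 <- 17; h2 <- 29
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 37 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
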