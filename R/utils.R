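#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Locale-independent lexicographic sort: protein identifiers are opaque
# case-sensitive strings and tie-break order must not depend on LC_COLLATE.
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

# Canonical unordered edge representation: two-column character matrix with
# the lexicographically smaller endpoint first.
canonical_edges <- function(from, to) {
  swap <- to < from
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  cbind(from, to)
}

edge_tibble <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el) == 0L) {
    return(tibble(from = character(), to = character()))
  }
  el <- canonical_edges(el[, 1L], el[, 2L])
  tibble(from = el[, 1L], to = el[, 2L]) |>
    arrange(.data$from, .data$to)
}

edge_key <- function(graph) {
  et <- edge_tibble(graph)
  paste(et$from, et$to, sep = "\t")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_category <- function(x) {
  bad <- setdiff(unique(x), c("CVD", "CD", "OS"))
  if (length(bad) > 0L) {
    stopf("unknown category label(s): %s (expected CVD, CD or OS)",
          paste(bad, collapse = ", "))
  }
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a master seed so that every
# stochastic stage draws from its own reproducible stream.
derive_seed <- function(rng_seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(rng_seed) * 69069 + h) %% 2147483647)
}
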