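#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query is enriched in the set against
#' a background universe with the one-sided hypergeometric upper tail
#' `P(X >= overlap)` (Fisher's exact test's enrichment tail). Gene sets are
#' intersected with the universe first; sets with fewer than `min_set_size`
#' members in the universe are skipped (and reported in a message). Results
#' are Benjamini-Hochberg adjusted and sorted by p-value.
#'
#' @param query Character vector (subset of `universe`, non-empty).
#' @param universe Character vector background (non-empty).
#' @param collection Named list of gene sets from [read_gmt()].
#' @param min_set_size Minimum in-universe set size (default 3).
#' @return Tibble `set_id`, `description`, `overlap_count`, `query_size`,
#'   `set_size`, `universe_size`, `p_value`, `adjusted_p`, sorted by
#'   ascending p (lexicographic set id on ties).
#' @export
hypergeom_enrich <- function(query, universe, collection, min_set_size = 3L) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(query) == 0L) stopf("empty query set")
  if (length(universe) == 0L) stopf("empty universe")
  extra <- setdiff(query, universe)
  if (length(extra) > 0L) {
    stopf("query protein(s) outside the universe: %s",
          paste(utils::head(extra, 5), collapse = ", "))
  }
  descs <- attr(collection, "descriptions") %||%
    stats::setNames(names(collection), names(collection))
  members <- lapply(collection, function(s) intersect(unique(s), universe))
  small <- lengths(members) < min_set_size
  if (any(small)) {
    message(sprintf("skipped %d gene set(s) with < %d members in the universe",
                    sum(small), min_set_size))
  }
  members <- members[!small]
  if (length(members) == 0L) {
    return(tibble(set_id = character(), description = character(),
                  overlap_count = integer(), query_size = integer(),
                  set_size = integer(), universe_size = integer(),
                  p_value = numeric(), adjusted_p = numeric()))
  }
  N <- length(universe)
  q <- length(query)
  res <- tibble(
    set_id = names(members),
    description = unname(descs[names(members)]),
    overlap_count = vapply(members, function(s) length(intersect(s, query)),
                           integer(1), USE.NAMES = FALSE),
    query_size = q,
    set_size = unname(lengths(members)),
    universe_size = N
  )
  # P(X >= k) where X ~ Hypergeom(N, set_size, q)
  res$p_value <- stats::phyper(res$overlap_count - 1L, res$set_size,
                               N - res$set_size, q, lower.tail = FALSE)
  res$adjusted_p <- bh_adjust(res$p_value)
  res[lex_order(res$p_value, res$set_id), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a thin validated wrapper around
#' [stats::p.adjust()] that restores the original order and caps at 1.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of central proteins in the three interactor settings
#'
#' Enriches the refined central proteins together with (1) their
#' CVD-only interactors, (2) their CD-only interactors and (3) their
#' interactors shared by CVD and CD, each setting tested and adjusted
#' independently against the same universe.
#'
#' @param global A `global_network`.
#' @param centrals Character vector of central proteins.
#' @param collection Gene-set collection ([read_gmt()]).
#' @param universe Background universe; default the Global Network node set.
#' @param min_set_size Passed to [hypergeom_enrich()].
#' @return Named list (`cvd`, `cd`, `both`) of enrichment tibbles, each with
#'   a `setting` column.
#' @export
enrich_three_settings <- function(global, centrals, collection,
                                  universe = NULL, min_set_size = 3L) {
  if (is.null(universe)) universe <- igraph::V(global$graph)$name
  missing <- setdiff(centrals, universe)
  if (length(missing) > 0L) {
    stopf("central protein(s) outside the universe: %s",
          paste(missing, collapse = ", "))
  }
  cls <- classify_interactors(global, centrals)
  cls <- cls[cls$protein %in% universe, , drop = FALSE]
  queries <- list(
    cvd = union(centrals, cls$protein[cls$class == "cvd_only"]),
    cd = union(centrals, cls$protein[cls$class == "cd_only"]),
    both = union(centrals, cls$protein[cls$class == "both"])
  )
  purrr::imap(queries, function(qq, nm) {
    hypergeom_enrich(qq, universe, collection, min_set_size) |>
      mutate(setting = nm)
  })
}
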