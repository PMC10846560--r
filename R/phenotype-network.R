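#' Select the top-scoring fraction of the network
#'
#' Returns the `ceiling(fraction * n)` highest-scoring proteins. Seeds count
#' toward the quota if they rank there. Ties at the cutoff are broken by
#' lexicographic protein id so the selection is deterministic.
#'
#' @param score_table A `score_table` tibble.
#' @param fraction Fraction of the node set in `(0, 1]` (default 0.02, the
#'   "top 2%" subnetwork).
#' @return Character vector of selected proteins.
#' @export
select_top_fraction <- function(score_table, fraction = 0.02) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(score_table)
  k <- ceiling(fraction * n)
  if (k < 1L) stopf("fraction * n must be >= 1")
  ord <- lex_order(-score_table$score, score_table$protein)
  score_table$protein[ord][seq_len(k)]
}

#' Find linker proteins
#'
#' Linkers are nodes outside the selected set that interact with at least two
#' nodes of the selected network: `{v not in selected : |N(v) & selected| >= 2}`.
#'
#' @param interactome igraph interactome.
#' @param selected Character vector of selected proteins (subset of nodes).
#' @return Character vector of linkers (lexicographically sorted).
#' @export
find_linkers <- function(interactome, selected) {
  nodes <- igraph::V(interactome)$name
  missing <- setdiff(selected, nodes)
  if (length(missing) > 0L) {
    stopf("selected protein(s) not in the interactome: %s",
          paste(missing, collapse = ", "))
  }
  if (length(selected) == 0L) return(character(0))
  outside <- setdiff(nodes, selected)
  if (length(outside) == 0L) return(character(0))
  nb <- igraph::adjacent_vertices(interactome, outside)
  counts <- vapply(nb, function(v) sum(v$name %in% selected), integer(1))
  lex_sort(outside[counts >= 2L])
}

#' Build a phenotype subnetwork (seeds + top fraction + linkers)
#'
#' Extracts the phenotype's subnetwork: the top-scoring `fraction` of the
#' interactome, its seed proteins (always included even when they rank below
#' the cutoff), and linker nodes connecting at least two selected nodes.
#' Roles follow the precedence seed > top > linker.
#'
#' @param interactome igraph interactome.
#' @param score_table `score_table` for the phenotype.
#' @param seeds Character vector of seed proteins.
#' @param phenotype_id,category Labels carried on the result.
#' @param fraction Top fraction (default 0.02).
#' @param max_linkers Optional cap: keep only the `max_linkers`
#'   highest-scoring linkers (default `Inf`, unlimited).
#' @return A `phenotype_network` object: list with `phenotype_id`, `category`,
#'   `graph` (induced igraph subgraph) and `nodes` (tibble `protein`, `role`,
#'   `score`).
#' @export
build_phenotype_network <- function(interactome, score_table, seeds,
                                    phenotype_id = "phenotype",
                                    category = NA_character_,
                                    fraction = 0.02, max_linkers = Inf) {
  top <- select_top_fraction(score_table, fraction)
  selected <- union(seeds, top)
  linkers <- find_linkers(interactome, selected)
  if (is.finite(max_linkers) && length(linkers) > max_linkers) {
    sv <- scores_vector(score_table)[linkers]
    ord <- lex_order(-sv, linkers)
    linkers <- lex_sort(linkers[ord][seq_len(max_linkers)])
  }
  members <- lex_sort(unique(c(selected, linkers)))
  role <- ifelse(members %in% seeds, "seed",
                 ifelse(members %in% top, "top", "linker"))
  sv <- scores_vector(score_table)
  nodes <- tibble(protein = members,
                  role = role,
                  score = unname(sv[members]))
  sub <- igraph::induced_subgraph(interactome, members)
  structure(
    list(phenotype_id = phenotype_id, category = category,
         graph = sub, nodes = nodes),
    class = "phenotype_network"
  )
}

#' Build every phenotype's subnetwork
#'
#' @param interactome igraph interactome.
#' @param score_tables Named list of `score_table`s from
#'   [score_all_phenotypes()].
#' @param seed_sets Seed tibble (supplies seeds and categories).
#' @param fraction,max_linkers Passed to [build_phenotype_network()].
#' @return Named list of `phenotype_network`s.
#' @export
build_all_phenotype_networks <- function(interactome, score_tables, seed_sets,
                                         fraction = 0.02, max_linkers = Inf) {
  out <- lapply(names(score_tables), function(p) {
    cat_p <- unique(seed_sets$category[seed_sets$phenotype_id == p])
    build_phenotype_network(
      interactome, score_tables[[p]], seed_proteins(seed_sets, p),
      phenotype_id = p, category = cat_p[[1]],
      fraction = fraction, max_linkers = max_linkers
    )
  })
  stats::setNames(out, names(score_tables))
}

#' @export
print.phenotype_network <- function(x, ...) {
  tab <- table(x$nodes$role)
  cat(sprintf(
    "<phenotype_network> %s (%s): %d nodes (%d seed, %d top, %d linker), %d edges\n",
    x$phenotype_id, x$category, nrow(x$nodes),
    tab["seed"] %|0|% 0L, tab["top"] %|0|% 0L, tab["linker"] %|0|% 0L,
    igraph::ecount(x$graph)
  ))
  invisible(x)
}

`%|0|%` <- function(a, b) if (is.na(a)) b else a
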