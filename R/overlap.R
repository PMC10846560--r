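#' Overlap score of a protein shared by two phenotype networks
#'
#' The crosstalk ranking statistic: the mean of the protein's propagation
#' scores in the two phenotypes.
#'
#' @param score_1,score_2 Scores in `[0, 1]`.
#' @return `(score_1 + score_2) / 2`.
#' @export
overlap_score <- function(score_1, score_2) {
  stopifnot(all(score_1 >= 0 & score_1 <= 1), all(score_2 >= 0 & score_2 <= 1))
  (score_1 + score_2) / 2
}

#' Overlap network between two phenotype networks
#'
#' Nodes are the intersection of the two parents' node sets; edges are, by
#' default, the union of the parents' edges induced on the intersection
#' (`edge_mode = "union"`, which keeps the overlap view connected when either
#' parent connects two shared nodes), or their intersection. Each shared
#' node's overlap score is the mean of its two parent scores, and both parent
#' roles are recorded.
#'
#' @param net_1,net_2 `phenotype_network` objects built over the same
#'   interactome.
#' @param edge_mode `"union"` or `"intersection"`.
#' @return An `overlap_network`: list with `pair` (the two phenotype ids),
#'   `categories`, `graph`, and `nodes` (tibble `protein`, `overlap_score`,
#'   `role_1`, `role_2`).
#' @export
overlap_network <- function(net_1, net_2, edge_mode = c("union", "intersection")) {
  edge_mode <- match.arg(edge_mode)
  shared <- lex_sort(intersect(net_1$nodes$protein, net_2$nodes$protein))
  if (length(shared) == 0L) {
    warnf("empty overlap between %s and %s", net_1$phenotype_id,
          net_2$phenotype_id)
  }
  e1 <- edge_key(igraph::induced_subgraph(net_1$graph,
                                          intersect(igraph::V(net_1$graph)$name, shared)))
  e2 <- edge_key(igraph::induced_subgraph(net_2$graph,
                                          intersect(igraph::V(net_2$graph)$name, shared)))
  keys <- if (edge_mode == "union") union(e1, e2) else intersect(e1, e2)
  keys <- lex_sort(keys)
  g <- if (length(keys) > 0L) {
    parts <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    igraph::graph_from_data_frame(
      data.frame(from = parts[, 1L], to = parts[, 2L]),
      directed = FALSE, vertices = shared
    )
  } else {
    igraph::make_empty_graph(n = 0, directed = FALSE) |>
      igraph::add_vertices(length(shared), name = shared)
  }
  role_of <- function(net) stats::setNames(net$nodes$role, net$nodes$protein)
  score_of <- function(net) stats::setNames(net$nodes$score, net$nodes$protein)
  nodes <- tibble(
    protein = shared,
    overlap_score = overlap_score(unname(score_of(net_1)[shared]),
                                  unname(score_of(net_2)[shared])),
    role_1 = unname(role_of(net_1)[shared]),
    role_2 = unname(role_of(net_2)[shared])
  )
  structure(
    list(pair = c(net_1$phenotype_id, net_2$phenotype_id),
         categories = c(net_1$category, net_2$category),
         graph = g, nodes = nodes),
    class = "overlap_network"
  )
}

#' Top non-seed crosstalk candidates of an overlap network
#'
#' Ranks the overlap's proteins by overlap score, excluding any protein that
#' is a seed in either parent (seeds are literature-curated, so they cannot
#' be novel), and returns the first `k`. Ties are broken by lexicographic
#' protein id.
#'
#' @param overlap An `overlap_network`.
#' @param k Number of candidates (>= 1).
#' @return Tibble `protein`, `overlap_score`, `role_1`, `role_2`, ranked.
#' @export
top_candidates <- function(overlap, k = 3L) {
  stopifnot(k >= 1L)
  cand <- overlap$nodes |>
    filter(.data$role_1 != "seed", .data$role_2 != "seed")
  ord <- lex_order(-cand$overlap_score, cand$protein)
  cand <- cand[ord, , drop = FALSE]
  if (nrow(cand) < k) {
    warnf("only %d non-seed candidate(s) available (requested %d)",
          nrow(cand), k)
    return(cand)
  }
  cand[seq_len(k), , drop = FALSE]
}

#' All pairwise overlap networks between disease categories
#'
#' `"cvd_vs_cd"` pairs every CVD phenotype with every CD phenotype;
#' `"vs_os"` pairs every non-OS phenotype with every OS phenotype; `"all"`
#' concatenates both lists (the full crosstalk panel of
#' `|CVD| * |CD| + (|CVD| + |CD|) * |OS|` overlaps).
#'
#' @param networks List of `phenotype_network`s (categories set).
#' @param pairing `"cvd_vs_cd"`, `"vs_os"` or `"all"`.
#' @param edge_mode Passed to [overlap_network()].
#' @return Named list of `overlap_network`s (`"P1~P2"` names).
#' @export
all_pairwise_overlaps <- function(networks,
                                  pairing = c("all", "cvd_vs_cd", "vs_os"),
                                  edge_mode = "union") {
  pairing <- match.arg(pairing)
  cats <- vapply(networks, function(n) n$category, character(1))
  ids <- vapply(networks, function(n) n$phenotype_id, character(1))
  by_cat <- function(cc) which(cats == cc)
  pairs <- list()
  if (pairing %in% c("all", "cvd_vs_cd")) {
    for (i in by_cat("CVD")) for (j in by_cat("CD")) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (pairing %in% c("all", "vs_os")) {
    for (i in which(cats != "OS")) for (j in by_cat("OS")) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  out <- lapply(pairs, function(ij) {
    overlap_network(networks[[ij[1]]], networks[[ij[2]]],
                    edge_mode = edge_mode)
  })
  stats::setNames(out, vapply(pairs, function(ij) {
    paste(ids[ij[1]], ids[ij[2]], sep = "~")
  }, character(1)))
}

#' @export
print.overlap_network <- function(x, ...) {
  cat(sprintf("<overlap_network> %s ~ %s: %d shared nodes, %d edges\n",
              x$pair[1], x$pair[2], nrow(x$nodes), igraph::ecount(x$graph)))
  invisible(x)
}
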