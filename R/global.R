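#' Merge phenotype networks into the Global Network
#'
#' Union of the member networks' node and edge sets. Every node records the
#' set of phenotypes it came from (`origin`) and a category label obtained by
#' projecting those phenotypes to their disease categories and joining the
#' distinct categories with `&` in the canonical order CVD, CD, OS (so a node
#' present in one cardiovascular network and the oxidative-stress network is
#' labelled `CVD&OS`). Multiplicity is ignored: three CVD parents and one CD
#' parent still give `CVD&CD`.
#'
#' @param networks List of `phenotype_network`s (>= 2).
#' @param category_map Named character vector phenotype id -> category; by
#'   default taken from the networks themselves.
#' @return A `global_network`: list with `graph` and `nodes`
#'   (tibble `protein`, `origin` list-column, `category_label`).
#' @export
merge_networks <- function(networks, category_map = NULL) {
  stopifnot(length(networks) >= 2L)
  ids <- vapply(networks, function(n) n$phenotype_id, character(1))
  if (is.null(category_map)) {
    category_map <- stats::setNames(
      vapply(networks, function(n) n$category, character(1)), ids)
  }
  missing <- setdiff(ids, names(category_map))
  if (length(missing) > 0L) {
    stopf("phenotype(s) missing from category map: %s",
          paste(missing, collapse = ", "))
  }
  assert_category(unname(category_map[ids]))

  all_nodes <- lex_sort(unique(unlist(lapply(networks, function(n) n$nodes$protein))))
  all_keys <- lex_sort(unique(unlist(lapply(networks, function(n) edge_key(n$graph)))))
  g <- if (length(all_keys) > 0L) {
    parts <- do.call(rbind, strsplit(all_keys, "\t", fixed = TRUE))
    igraph::graph_from_data_frame(
      data.frame(from = parts[, 1L], to = parts[, 2L]),
      directed = FALSE, vertices = all_nodes)
  } else {
    igraph::make_empty_graph(0, directed = FALSE) |>
      igraph::add_vertices(length(all_nodes), name = all_nodes)
  }

  origin <- stats::setNames(vector("list", length(all_nodes)), all_nodes)
  for (n in networks) {
    for (p in n$nodes$protein) origin[[p]] <- c(origin[[p]], n$phenotype_id)
  }
  origin <- lapply(origin, lex_sort)
  label <- vapply(origin, function(ph) {
    cats <- unique(unname(category_map[ph]))
    paste(c("CVD", "CD", "OS")[c("CVD", "CD", "OS") %in% cats], collapse = "&")
  }, character(1))

  structure(
    list(graph = g,
         nodes = tibble(protein = all_nodes,
                        origin = unname(origin),
                        category_label = unname(label)),
         category_map = category_map),
    class = "global_network"
  )
}

#' Annotate a Global Network with centralities
#'
#' Adds normalized degree centrality (`deg(v) / (n - 1)`) and normalized
#' shortest-path betweenness (scaled by `2 / ((n - 1)(n - 2))` for undirected
#' graphs) to the node table.
#'
#' @param global A `global_network` (>= 3 nodes).
#' @return The `global_network` with `degree_centrality` and
#'   `betweenness_centrality` columns added.
#' @export
compute_centralities <- function(global) {
  g <- global$graph
  n <- igraph::vcount(g)
  stopifnot(n >= 3L)
  dc <- igraph::degree(g) / (n - 1)
  bc <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  global$nodes$degree_centrality <- unname(dc[global$nodes$protein])
  global$nodes$betweenness_centrality <- unname(bc[global$nodes$protein])
  global
}

#' Dual stress-included / stress-excluded crosstalk scores
#'
#' For every protein, takes the maximum propagation score across the CVD
#' phenotypes and across the CD phenotypes, plus its oxidative-stress (OS)
#' score. The OS-excluded score is the mean of the two category maxima; the
#' OS-included score additionally averages in the OS score. Their difference
#' `delta = os_included - os_excluded = (os_score - os_excluded) / 3` flags
#' stress-sensitive proteins; `|delta| <= 1/3` always.
#'
#' @param score_tables Named list of `score_table`s (all phenotypes).
#' @param category_map Named character vector phenotype id -> category; must
#'   contain at least one CVD, one CD and exactly one OS phenotype.
#' @param universe Character vector of proteins to score (every protein must
#'   be present in every table; propagation scores all interactome nodes).
#' @return Tibble `protein`, `cvd_max`, `cd_max`, `os_score`, `os_excluded`,
#'   `os_included`, `delta`.
#' @export
crosstalk_scores <- function(score_tables, category_map, universe) {
  ids <- names(score_tables)
  missing <- setdiff(ids, names(category_map))
  if (length(missing) > 0L) {
    stopf("phenotype(s) missing from category map: %s",
          paste(missing, collapse = ", "))
  }
  cats <- unname(category_map[ids])
  if (!any(cats == "CVD") || !any(cats == "CD")) {
    stopf("need at least one CVD and one CD score table")
  }
  os_ids <- ids[cats == "OS"]
  if (length(os_ids) != 1L) {
    stopf("need exactly one OS score table, got %d", length(os_ids))
  }
  universe <- lex_sort(unique(universe))
  col <- function(p) {
    sv <- scores_vector(score_tables[[p]])
    if (!all(universe %in% names(sv))) {
      stopf("score table '%s' does not cover the universe", p)
    }
    unname(sv[universe])
  }
  cat_max <- function(cc) {
    m <- vapply(ids[cats == cc], col, numeric(length(universe)))
    apply(matrix(m, nrow = length(universe)), 1L, max)
  }
  cvd_max <- cat_max("CVD")
  cd_max <- cat_max("CD")
  os_score <- col(os_ids)
  os_excluded <- (cvd_max + cd_max) / 2
  os_included <- (cvd_max + cd_max + os_score) / 3
  tibble(protein = universe, cvd_max = cvd_max, cd_max = cd_max,
         os_score = os_score, os_excluded = os_excluded,
         os_included = os_included, delta = os_included - os_excluded)
}

#' Central proteins per category group
#'
#' Within each category label group of the Global Network (restricted to
#' OS-containing labels, non-OS labels, or all), returns the `k` nodes with
#' the highest degree centrality and the `k` with the highest betweenness
#' centrality (lexicographic tiebreak). A protein may appear in both lists;
#' the per-group union is the group's central set.
#'
#' @param global A `global_network` annotated by [compute_centralities()].
#' @param k Top count per measure (default 5).
#' @param restrict `"os_related"` (labels containing OS), `"non_os"` or
#'   `"all"`.
#' @return Tibble `category_label`, `measure` (`degree` | `betweenness`),
#'   `rank`, `protein`, `centrality`.
#' @export
select_central <- function(global, k = 5L,
                           restrict = c("os_related", "non_os", "all")) {
  restrict <- match.arg(restrict)
  stopifnot(k >= 1L)
  if (is.null(global$nodes$degree_centrality)) {
    stopf("run compute_centralities() first")
  }
  nd <- global$nodes
  has_os <- grepl("(^|&)OS($|&)", nd$category_label)
  nd <- switch(restrict,
               os_related = nd[has_os, , drop = FALSE],
               non_os = nd[!has_os, , drop = FALSE],
               all = nd)
  measures <- c(degree = "degree_centrality",
                betweenness = "betweenness_centrality")
  out <- list()
  for (lab in lex_sort(unique(nd$category_label))) {
    grp <- nd[nd$category_label == lab, , drop = FALSE]
    for (m in names(measures)) {
      v <- grp[[measures[[m]]]]
      ord <- lex_order(-v, grp$protein)
      take <- seq_len(min(k, nrow(grp)))
      out[[length(out) + 1L]] <- tibble(
        category_label = lab, measure = m, rank = take,
        protein = grp$protein[ord][take],
        centrality = v[ord][take])
    }
  }
  bind_rows(out)
}

#' Refine proteins by the stress-sensitivity threshold
#'
#' Keeps the proteins whose score shifts by at least `threshold` (in absolute
#' value, inclusive) when the oxidative-stress score enters the average.
#'
#' @param scores Crosstalk-score tibble from [crosstalk_scores()].
#' @param proteins Character vector to refine.
#' @param threshold Positive delta threshold (default 0.1).
#' @return Character vector (lexicographically sorted).
#' @export
filter_by_delta <- function(scores, proteins, threshold = 0.1) {
  stopifnot(threshold > 0)
  dv <- stats::setNames(scores$delta, scores$protein)
  missing <- setdiff(proteins, names(dv))
  if (length(missing) > 0L) {
    stopf("protein(s) missing from crosstalk scores: %s",
          paste(missing, collapse = ", "))
  }
  lex_sort(proteins[abs(dv[proteins]) >= threshold])
}

#' Classify the interactors of a central-protein set
#'
#' Pools the Global Network neighbours of the central proteins (the centrals
#' themselves excluded) and classifies each by the disease categories in its
#' origin: `cvd_only`, `cd_only`, `both`, or `os_only` for neighbours coming
#' from the OS network alone (reported separately, not merged).
#'
#' @param global A `global_network`.
#' @param centrals Character vector of central proteins (subset of nodes).
#' @return Tibble `protein`, `class`.
#' @export
classify_interactors <- function(global, centrals) {
  nodes <- igraph::V(global$graph)$name
  missing <- setdiff(centrals, nodes)
  if (length(missing) > 0L) {
    stopf("central protein(s) not in the Global Network: %s",
          paste(missing, collapse = ", "))
  }
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(global$graph, centrals),
    function(v) v$name)))
  nb <- lex_sort(setdiff(nb, centrals))
  lab <- stats::setNames(global$nodes$category_label, global$nodes$protein)[nb]
  has <- function(cc) grepl(paste0("(^|&)", cc, "($|&)"), lab)
  cls <- ifelse(has("CVD") & has("CD"), "both",
                ifelse(has("CVD"), "cvd_only",
                       ifelse(has("CD"), "cd_only", "os_only")))
  tibble(protein = nb, class = unname(cls))
}

#' Topology summary of the Global Network
#'
#' Average unweighted shortest-path length over the largest connected
#' component, and the mean local clustering coefficient over all nodes
#' (nodes of degree < 2 contribute 0).
#'
#' @param global A `global_network` or plain igraph graph.
#' @return Tibble `node_count`, `edge_count`,
#'   `average_shortest_path_length`, `average_clustering_coefficient`.
#' @export
summarize_topology <- function(global) {
  g <- if (inherits(global, "global_network")) global$graph else global
  stopifnot(igraph::vcount(g) >= 2L)
  if (igraph::ecount(g) == 0L) {
    warnf("graph has no edges; average shortest path reported as 0")
    aspl <- 0
  } else {
    comp <- igraph::components(g)
    giant <- which.max(comp$csize)
    lcc <- igraph::induced_subgraph(
      g, igraph::V(g)[comp$membership == giant])
    aspl <- igraph::mean_distance(lcc, directed = FALSE)
  }
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  tibble(node_count = igraph::vcount(g), edge_count = igraph::ecount(g),
         average_shortest_path_length = aspl,
         average_clustering_coefficient = cc)
}

#' Distribution of the stress-sensitivity delta
#'
#' Counts proteins whose OS-included minus OS-excluded score difference is at
#' or above `+threshold`, at or below `-threshold`, or in between, and
#' reports the delta extrema (`|delta| < 1/3` always holds algebraically).
#'
#' @param scores Crosstalk-score tibble.
#' @param threshold Positive threshold (default 0.1).
#' @return Tibble `n_increased`, `n_decreased`, `n_unaffected`, `n_total`,
#'   `min_delta`, `max_delta`.
#' @export
delta_distribution <- function(scores, threshold = 0.1) {
  stopifnot(threshold > 0)
  d <- scores$delta
  tibble(
    n_increased = sum(d >= threshold),
    n_decreased = sum(d <= -threshold),
    n_unaffected = sum(d > -threshold & d < threshold),
    n_total = length(d),
    min_delta = if (length(d)) min(d) else NA_real_,
    max_delta = if (length(d)) max(d) else NA_real_
  )
}

#' @export
print.global_network <- function(x, ...) {
  cat(sprintf("<global_network> %d nodes, %d edges, %d category labels\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(unique(x$nodes$category_label))))
  invisible(x)
}
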