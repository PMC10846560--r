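# Independent brute-force oracles and graph fixtures used across the suite.
# All oracles work on plain adjacency matrices, independent of igraph and of
# the implementation paths they check.

# Build an igraph from a named adjacency matrix.
graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Random simple graph as a named adjacency matrix (Erdos-Renyi).
random_adj <- function(n, p = 0.3, min_edges = 1L) {
  labels <- sprintf("N%02d", seq_len(n))
  repeat {
    adj <- matrix(0L, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
      }
    }
    if (sum(adj) / 2 >= min_edges) return(adj)
  }
}

# Small helper: graph from an edge string like "A-B B-C".
graph_from_spec <- function(spec) {
  pairs <- strsplit(strsplit(spec, " ", fixed = TRUE)[[1]], "-", fixed = TRUE)
  df <- data.frame(from = vapply(pairs, `[[`, "", 1L),
                   to = vapply(pairs, `[[`, "", 2L))
  igraph::graph_from_data_frame(df, directed = FALSE)
}

# BFS distances from one source on an adjacency matrix.
bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in which(adj[v, ] > 0)) {
        if (is.infinite(d[u])) {
          d[u] <- d[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# Enumerate every shortest path between s and t (lists of vertex indices).
enumerate_shortest_paths <- function(adj, s, t) {
  dt <- bfs_dist(adj, t)
  if (is.infinite(dt[s])) return(list())
  walk <- function(v) {
    if (v == t) return(list(v))
    nexts <- which(adj[v, ] > 0 & dt == dt[v] - 1)
    out <- list()
    for (u in nexts) {
      for (p in walk(u)) out[[length(out) + 1L]] <- c(v, p)
    }
    out
  }
  walk(s)
}

# Normalized betweenness by exhaustive shortest-path enumeration.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bet <- rep(0, n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- enumerate_shortest_paths(adj, s, t)
      if (length(paths) == 0L) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(paths, function(p) v %in% p[-c(1, length(p))],
                              logical(1)))
        bet[v] <- bet[v] + through / length(paths)
      }
    }
  }
  stats::setNames(bet * 2 / ((n - 1) * (n - 2)), rownames(adj))
}

oracle_degree_centrality <- function(adj) {
  stats::setNames(rowSums(adj) / (nrow(adj) - 1), rownames(adj))
}

# Floyd-Warshall weighted all-pairs distances.
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- w
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# NetShort oracle: direct evaluation of the stated formula with
# Floyd-Warshall distances.
oracle_netshort <- function(adj, seeds) {
  labels <- rownames(adj)
  s0 <- stats::setNames(as.numeric(labels %in% seeds), labels)
  w <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  for (i in seq_len(nrow(adj))) {
    for (j in seq_len(ncol(adj))) {
      if (adj[i, j] > 0) w[i, j] <- 1 / (1 + s0[i] + s0[j])
    }
  }
  d <- floyd_warshall(w)
  raw <- stats::setNames(rep(0, length(labels)), labels)
  for (v in labels) {
    for (t in seeds) {
      if (t == v) next
      if (is.finite(d[v, t])) raw[v] <- raw[v] + 1 / d[v, t]
    }
  }
  raw[seeds] <- max(raw)
  rng <- range(raw)
  if (rng[1] == rng[2]) return(stats::setNames(rep(0.5, length(raw)), labels))
  (raw - rng[1]) / (rng[2] - rng[1])
}

# Linker oracle: plain neighbourhood counting.
oracle_linkers <- function(adj, selected) {
  labels <- rownames(adj)
  out <- character(0)
  for (v in setdiff(labels, selected)) {
    if (sum(adj[v, selected]) >= 2) out <- c(out, v)
  }
  sort(out, method = "radix")
}

# Hypergeometric upper-tail oracle by exhaustive enumeration of all
# C(N, q) equally likely query draws.
oracle_hypergeom <- function(universe_size, set_size, query_size, overlap) {
  draws <- utils::combn(universe_size, query_size)
  # members 1..set_size form the gene set
  hits <- apply(draws, 2L, function(d) sum(d <= set_size))
  mean(hits >= overlap)
}

# All connected graphs on <= 6 vertices, one per isomorphism class, from the
# graph atlas (indices 0..208 cover orders 0..6).
atlas_connected_graphs <- function(max_nodes = 6L) {
  out <- list()
  for (i in 1:208) {
    g <- igraph::graph_from_atlas(i)
    if (igraph::vcount(g) < 2L || igraph::vcount(g) > max_nodes) next
    if (!igraph::is_connected(g)) next
    igraph::V(g)$name <- LETTERS[seq_len(igraph::vcount(g))]
    out[[length(out) + 1L]] <- g
  }
  out
}

adj_from_graph <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

scores_named <- function(tab) stats::setNames(tab$score, tab$protein)

scale01_helper <- function(x) {
  s <- stats::sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

# Canonical sorted edge keys of a graph (for set comparisons in tests).
edge_key_for_test <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  sort(apply(el, 1L, function(e) paste(sort(e, method = "radix"),
                                       collapse = "|")),
       method = "radix")
}

# Small synthetic study shared by several test files (kept small for speed).
small_study <- function(rng_seed = 42) {
  synthetic_crosstalk_study(
    n_nodes = 250L, attach_m = 2L,
    phenotype_specs = c(CVD1 = "CVD", CVD2 = "CVD", CD1 = "CD", OS1 = "OS"),
    module_size = 20L, module_density = 0.35, seed_fraction = 0.4,
    inter_category_overlap = 0.1, n_bridges = 5L, rng_seed = rng_seed)
}

small_params <- function(rng_seed = 42) {
  propagation_params(null_replicates = 20L, rng_seed = rng_seed)
}
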