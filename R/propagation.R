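#' Propagation parameters
#'
#' Bundles the tunable constants of the guilt-by-association scoring
#' algorithms. `rng_seed` has no default: every stochastic component
#' (the degree-preserving null model of NetZcore, and any synthetic input)
#' must be seeded explicitly so runs are reproducible.
#'
#' @param repetitions Number of NetScore repetitions `r` (>= 1). After each
#'   repetition the propagated scores are rescaled to `[0, 1]` and become the
#'   new baseline.
#' @param iterations Number of message-passing iterations `i` per repetition
#'   (>= 1), shared by NetScore and NetZcore.
#' @param damping NetScore damping `lambda` in `[0, 1]`: the weight of the
#'   propagated signal versus the baseline score.
#' @param null_replicates Number `R` of degree-preserving rewired replicates
#'   used by NetZcore's null distribution (>= 2 for a defined sd).
#' @param swaps_per_edge Double-edge swaps per edge when rewiring (>= 1).
#' @param rng_seed Integer master seed (required).
#' @return A list of class `propagation_params`.
#' @export
propagation_params <- function(repetitions = 3L, iterations = 2L,
                               damping = 0.5, null_replicates = 100L,
                               swaps_per_edge = 10L, rng_seed) {
  if (missing(rng_seed)) stopf("rng_seed is required (no silent default)")
  stopifnot(repetitions >= 1L, iterations >= 1L,
            damping >= 0, damping <= 1,
            null_replicates >= 1L, swaps_per_edge >= 1L)
  structure(
    list(repetitions = as.integer(repetitions),
         iterations = as.integer(iterations),
         damping = damping,
         null_replicates = as.integer(null_replicates),
         swaps_per_edge = as.integer(swaps_per_edge),
         rng_seed = as.integer(rng_seed)),
    class = "propagation_params"
  )
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Initial seed scores
#'
#' Assigns score 1 to seed proteins and 0 to every other interactome node,
#' the starting state of all propagation algorithms.
#'
#' @param interactome igraph interactome.
#' @param seeds Character vector of seed proteins (must be interactome nodes).
#' @return Named numeric vector over all nodes, values in `{0, 1}`.
#' @export
initial_scores <- function(interactome, seeds) {
  nodes <- igraph::V(interactome)$name
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0L) {
    stopf("seed(s) not in the interactome: %s", paste(missing, collapse = ", "))
  }
  if (length(seeds) == 0L) stopf("empty seed set")
  s0 <- stats::setNames(numeric(length(nodes)), nodes)
  s0[seeds] <- 1
  s0
}

#' Min-max scale a score vector to \[0, 1\]
#'
#' `(x - min) / (max - min)`; if all values are equal the result is uniformly
#' 0.5 (a neutral score, since ranks carry no information).
#'
#' @param raw Named numeric vector (finite, no NaN).
#' @return Scaled vector on the same names.
#' @export
minmax_scale <- function(raw) {
  if (length(raw) == 0L) stopf("cannot scale an empty score vector")
  if (any(is.na(raw)) || any(!is.finite(raw))) {
    stopf("scores must be finite and non-missing")
  }
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    return(stats::setNames(rep(0.5, length(raw)), names(raw)))
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

score_table <- function(scores, seeds, phenotype_id, algorithm) {
  ord <- lex_order(names(scores))
  tibble(
    protein = names(scores)[ord],
    score = unname(scores)[ord],
    is_seed = names(scores)[ord] %in% seeds
  ) |>
    structure(class = c("score_table", class(tibble())),
              phenotype_id = phenotype_id, algorithm = algorithm)
}

scores_vector <- function(table) {
  stats::setNames(table$score, table$protein)
}

#' NetShort: shortest-path scoring with seed-shortened edges
#'
#' Edges incident to seeds are shortened (`w(u,v) = 1/(1 + s0(u) + s0(v))`),
#' so paths through seed neighbourhoods are cheap. A node's raw score is the
#' sum of inverse weighted shortest-path distances to every seed
#' (`raw(v) = sum over seeds t != v of 1/d_w(v, t)`; unreachable seeds
#' contribute 0). Seeds themselves are then assigned the maximum raw score so
#' they stay top-ranked, and the result is min-max scaled.
#'
#' @param interactome igraph interactome.
#' @param seeds Character vector of seed proteins.
#' @param phenotype_id Phenotype label carried on the result.
#' @return A `score_table` tibble (`protein`, `score`, `is_seed`).
#' @export
netshort <- function(interactome, seeds, phenotype_id = "phenotype") {
  s0 <- initial_scores(interactome, seeds)
  el <- igraph::as_edgelist(interactome, names = TRUE)
  w <- if (nrow(el) > 0L) 1 / (1 + s0[el[, 1L]] + s0[el[, 2L]]) else numeric(0)
  d <- igraph::distances(interactome, v = seeds,
                         weights = w, algorithm = "dijkstra")
  nodes <- igraph::V(interactome)$name
  raw <- stats::setNames(numeric(length(nodes)), nodes)
  for (t in seeds) {
    dt <- d[t, ]
    contrib <- 1 / dt
    contrib[!is.finite(contrib)] <- 0  # unreachable, and the seed itself (d=0 -> Inf handled below)
    contrib[t] <- 0                    # t != v
    contrib[dt == 0 & nodes != t] <- 0 # coincident zero distances guard
    raw <- raw + contrib
  }
  raw[seeds] <- max(raw)
  score_table(minmax_scale(raw), seeds, phenotype_id, "netshort")
}

# One synchronous round of neighbour averaging; isolated nodes keep their
# current value.
neighbor_average <- function(adj, deg, s) {
  out <- as.numeric(adj %*% s)
  iso <- deg == 0
  out[!iso] <- out[!iso] / deg[!iso]
  out[iso] <- s[iso]
  stats::setNames(out, names(s))
}

netzcore_raw <- function(graph, s0, iterations) {
  adj <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  # align to s0's name order (rewired replicates keep vertex names)
  adj <- adj[names(s0), names(s0)]
  deg <- as.numeric(Matrix::rowSums(adj))
  s <- s0
  for (k in seq_len(iterations)) s <- neighbor_average(adj, deg, s)
  s
}

#' Degree-preserving rewiring (null interactome)
#'
#' Produces a random simple graph with the same degree sequence via repeated
#' double-edge swaps; the null model behind NetZcore's z-scores.
#'
#' @param interactome igraph interactome (>= 2 edges).
#' @param swaps_per_edge Number of attempted swaps per edge.
#' @param rng_seed Integer seed; the result is deterministic given the seed.
#' @return A rewired igraph graph over the same vertices.
#' @export
rewire_preserving_degree <- function(interactome, swaps_per_edge = 10L,
                                     rng_seed) {
  if (missing(rng_seed)) stopf("rng_seed is required")
  ne <- igraph::ecount(interactome)
  if (ne < 2L) stopf("rewiring needs a graph with >= 2 edges")
  niter <- as.integer(swaps_per_edge) * ne
  out <- with_seed(rng_seed, {
    igraph::rewire(interactome,
                   igraph::keeping_degseq(loops = FALSE, niter = niter))
  })
  if (setequal(edge_key(out), edge_key(interactome)) &&
      !has_legal_swap(interactome)) {
    warnf("no legal degree-preserving swap exists; returning input unchanged")
    return(interactome)
  }
  out
}

# Exhaustive check for a legal double-edge swap (only consulted when the
# rewired graph came back identical, which for rigid graphs means no swap
# exists). Quadratic in edge count; capped to keep the check cheap.
has_legal_swap <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  ne <- nrow(el)
  if (ne > 400L) return(TRUE)
  keys <- new.env(hash = TRUE)
  for (i in seq_len(ne)) {
    k <- paste(lex_sort(el[i, ]), collapse = "\t")
    assign(k, TRUE, envir = keys)
  }
  has_edge <- function(a, b) {
    if (a == b) return(TRUE)
    exists(paste(lex_sort(c(a, b)), collapse = "\t"), envir = keys)
  }
  for (i in seq_len(ne - 1L)) {
    for (j in (i + 1L):ne) {
      a <- el[i, 1L]; b <- el[i, 2L]; c <- el[j, 1L]; d <- el[j, 2L]
      if (length(unique(c(a, b, c, d))) < 4L) next
      if (!has_edge(a, d) && !has_edge(c, b)) return(TRUE)
      if (!has_edge(a, c) && !has_edge(b, d)) return(TRUE)
    }
  }
  FALSE
}

#' NetZcore: neighbour averaging standardized against a degree-preserving null
#'
#' Scores propagate by `iterations` synchronous rounds of neighbour averaging
#' (`s_{k+1}(v) = mean over u in N(v) of s_k(u)`; isolated nodes keep their
#' initial score). The raw score of each node is converted to a z-score
#' against the mean and sd of the same statistic over `null_replicates`
#' degree-preserving rewired replicates; nodes whose null sd is 0 get z = 0
#' (neutral). The z-scores are min-max scaled.
#'
#' @inheritParams netshort
#' @param params A [propagation_params()] object.
#' @param null_graphs Optional list of igraph graphs to use as the null
#'   ensemble instead of sampled rewirings (e.g. an exhaustive enumeration on
#'   a small graph); vertex names must match the interactome.
#' @return A `score_table` tibble.
#' @export
netzcore <- function(interactome, seeds, params, phenotype_id = "phenotype",
                     null_graphs = NULL) {
  s0 <- initial_scores(interactome, seeds)
  raw <- netzcore_raw(interactome, s0, params$iterations)
  if (is.null(null_graphs)) {
    R <- params$null_replicates
    null_graphs <- lapply(seq_len(R), function(rix) {
      rewire_preserving_degree(
        interactome, params$swaps_per_edge,
        rng_seed = derive_seed(params$rng_seed, paste0("netzcore-null-", rix)))
    })
  }
  R <- length(null_graphs)
  if (R < 2L) stopf("the null ensemble needs >= 2 replicates")
  null_mat <- matrix(0, nrow = length(s0), ncol = R)
  for (rix in seq_len(R)) {
    null_mat[, rix] <- netzcore_raw(null_graphs[[rix]], s0, params$iterations)
  }
  mu <- rowMeans(null_mat)
  sdv <- apply(null_mat, 1L, stats::sd)
  z <- ifelse(sdv > 0, (raw - mu) / sdv, 0)
  names(z) <- names(s0)
  score_table(minmax_scale(z), seeds, phenotype_id, "netzcore")
}

#' NetScore: damped degree-normalized message passing with re-based repetitions
#'
#' Within each of `repetitions` rounds, runs `iterations` updates of
#' `s_{k+1}(v) = (1 - lambda) * s_base(v) + lambda * sum over u in N(v) of
#' s_k(u) / deg(u)`: each node broadcasts its score split evenly over its
#' neighbours, damped toward the baseline. After each repetition the current
#' scores are min-max rescaled and become the new baseline, letting the
#' signal radiate one ring further per repetition. The final result is
#' min-max scaled.
#'
#' @inheritParams netzcore
#' @return A `score_table` tibble.
#' @export
netscore <- function(interactome, seeds, params, phenotype_id = "phenotype") {
  s0 <- initial_scores(interactome, seeds)
  adj <- igraph::as_adjacency_matrix(interactome, sparse = TRUE)
  adj <- adj[names(s0), names(s0)]
  deg <- as.numeric(Matrix::rowSums(adj))
  lam <- params$damping
  outdiv <- function(s) {
    contrib <- ifelse(deg > 0, s / deg, 0)
    as.numeric(adj %*% contrib)
  }
  s_base <- s0
  for (rep_ix in seq_len(params$repetitions)) {
    s <- s_base
    for (k in seq_len(params$iterations)) {
      s <- (1 - lam) * s_base + lam * outdiv(s)
    }
    s_base <- minmax_scale(stats::setNames(s, names(s0)))
  }
  score_table(s_base, seeds, phenotype_id, "netscore")
}

#' NetCombo: average of standardized NetScore, NetZcore and NetShort
#'
#' Each input table is standardized to zero mean and unit variance (a
#' zero-variance table contributes a zero vector), the three standardized
#' vectors are averaged elementwise, and the mean is min-max scaled.
#'
#' @param t1,t2,t3 `score_table` objects over identical protein domains.
#' @return A `score_table` with `algorithm = "netcombo"`.
#' @export
netcombo <- function(t1, t2, t3) {
  tabs <- list(t1, t2, t3)
  doms <- lapply(tabs, function(t) t$protein)
  if (!all(vapply(doms[-1], identical, logical(1), doms[[1]]))) {
    stopf("netcombo inputs must share an identical protein domain")
  }
  std <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  m <- rowMeans(vapply(tabs, function(t) std(t$score),
                       numeric(nrow(t1))))
  seeds <- t1$protein[t1$is_seed]
  score_table(stats::setNames(m, t1$protein) |> minmax_scale(),
              seeds, attr(t1, "phenotype_id"), "netcombo")
}

#' Score one phenotype with the combined prioritization
#'
#' Runs NetShort, NetZcore and NetScore and combines them with [netcombo()];
#' the standard prioritization used throughout the crosstalk pipeline.
#'
#' @inheritParams netzcore
#' @return A `score_table` with `algorithm = "netcombo"`.
#' @export
score_phenotype <- function(interactome, seeds, params,
                            phenotype_id = "phenotype") {
  ns <- netshort(interactome, seeds, phenotype_id)
  nz <- netzcore(interactome, seeds, params, phenotype_id)
  nc <- netscore(interactome, seeds, params, phenotype_id)
  netcombo(nc, nz, ns)
}

#' Score every phenotype in a seed table
#'
#' @param interactome igraph interactome.
#' @param seed_sets Seed tibble from [read_seed_sets()].
#' @param params A [propagation_params()] object; each phenotype's null model
#'   is seeded from `params$rng_seed` and the phenotype id, so results do not
#'   depend on phenotype order.
#' @return Named list of `score_table`s, one per phenotype (lexicographic
#'   phenotype order).
#' @export
score_all_phenotypes <- function(interactome, seed_sets, params) {
  phenos <- lex_sort(unique(seed_sets$phenotype_id))
  out <- lapply(phenos, function(p) {
    pp <- params
    pp$rng_seed <- derive_seed(params$rng_seed, paste0("phenotype-", p))
    score_phenotype(interactome, seed_proteins(seed_sets, p), pp,
                    phenotype_id = p)
  })
  stats::setNames(out, phenos)
}
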