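test_that("initial scores are 1 on seeds and 0 elsewhere", {
  g <- graph_from_spec("A-B B-C")
  expect_identical(initial_scores(g, "A"), c(A = 1, B = 0, C = 0))
  expect_identical(initial_scores(g, c("A", "B", "C")), c(A = 1, B = 1, C = 1))
  expect_error(initial_scores(g, "Z"), "not in the interactome")
  expect_error(initial_scores(g, character(0)), "empty seed set")
})

test_that("min-max scaling maps to [0,1] with the degenerate 0.5 rule", {
  expect_equal(minmax_scale(c(A = 2, B = 1, C = 0)), c(A = 1, B = 0.5, C = 0))
  expect_equal(minmax_scale(c(A = 7, B = 7)), c(A = 0.5, B = 0.5))
  expect_equal(minmax_scale(c(A = -1, B = 1)), c(A = 0, B = 1))
  expect_error(minmax_scale(c(A = NaN)), "finite")
})

test_that("netshort reproduces hand-computed path examples", {
  g <- graph_from_spec("A-B B-C")
  # seed A: w(A,B)=0.5, w(B,C)=1 -> raw B=2, C=2/3, A=max=2 -> {1, 1, 0}
  sv <- stats::setNames(netshort(g, "A")$score, netshort(g, "A")$protein)
  expect_equal(sv, c(A = 1, B = 1, C = 0))
  # seeds {A, C}: raw(B) = 1/0.5 + 1/0.5 = 4
  raw_b <- {
    adj <- adj_from_graph(g)
    o <- oracle_netshort(adj, c("A", "C"))
    o
  }
  sv2 <- scores_named(netshort(g, c("A", "C")))
  expect_equal(sv2, raw_b[names(sv2)])
})

test_that("netshort gives isolated non-seed nodes score zero", {
  g <- graph_from_spec("A-B")
  g <- igraph::add_vertices(g, 1, name = "Z")
  sv <- scores_named(netshort(g, "A"))
  expect_equal(unname(sv["Z"]), 0)
})

test_that("netshort matches the Floyd-Warshall oracle on random graphs", {
  set.seed(101)
  for (rep in 1:40) {
    adj <- random_adj(sample(4:8, 1), p = 0.4)
    g <- graph_from_adj(adj)
    seeds <- sample(rownames(adj), sample(1:2, 1))
    got <- scores_named(netshort(g, seeds))
    want <- oracle_netshort(adj, seeds)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("degree-preserving rewiring keeps the degree sequence", {
  set.seed(7)
  adj <- random_adj(10, 0.4, min_edges = 8)
  g <- graph_from_adj(adj)
  gr <- rewire_preserving_degree(g, 10L, rng_seed = 5)
  expect_identical(sort(igraph::degree(gr)), sort(igraph::degree(g)))
  expect_false(igraph::any_loop(gr))
  expect_false(igraph::any_multiple(gr))
  # deterministic per seed
  gr2 <- rewire_preserving_degree(g, 10L, rng_seed = 5)
  expect_identical(edge_key_for_test(gr), edge_key_for_test(gr2))
})

test_that("rewiring a 4-cycle always yields a labeled 4-cycle", {
  g <- graph_from_spec("A-B B-C C-D D-A")
  # the only simple 2-regular graphs on 4 labeled nodes are 4-cycles
  for (s in 1:20) {
    gr <- rewire_preserving_degree(g, 10L, rng_seed = s)
    expect_true(all(igraph::degree(gr) == 2))
    expect_false(igraph::any_multiple(gr))
    expect_true(igraph::is_connected(gr))
  }
})

test_that("rigid graphs come back unchanged with a warning", {
  star <- graph_from_spec("C-L1 C-L2 C-L3")
  expect_warning(gr <- rewire_preserving_degree(star, 10L, rng_seed = 1),
                 "no legal")
  expect_identical(edge_key_for_test(gr), edge_key_for_test(star))
})

test_that("netzcore raw propagation matches the star hand example", {
  # star center seed, one averaging round: leaves get 1, center gets 0;
  # with a rigid null (sd 0) all z are 0 and scale to 0.5
  star <- graph_from_spec("C-L1 C-L2 C-L3")
  p <- propagation_params(iterations = 1L, null_replicates = 3L, rng_seed = 2)
  suppressWarnings(tab <- netzcore(star, "C", p))
  expect_equal(unname(scores_named(tab)), rep(0.5, 4))
})

test_that("netzcore with an identical-graph null ensemble is all 0.5", {
  g <- graph_from_spec("A-B B-C C-D D-A A-C")
  p <- propagation_params(iterations = 2L, rng_seed = 3)
  tab <- netzcore(g, "A", p, null_graphs = list(g, g, g))
  expect_equal(unname(scores_named(tab)), rep(0.5, 4))
})

test_that("automorphic nodes score equally under an exhaustive null ensemble", {
  # C4 with opposite seeds {A, C}; the exhaustive degree-preserving ensemble
  # is the three labeled 4-cycles, and swapping B and D maps it to itself.
  g <- graph_from_spec("A-B B-C C-D D-A")
  nulls <- list(
    graph_from_spec("A-B B-C C-D D-A"),
    graph_from_spec("A-B B-D D-C C-A"),
    graph_from_spec("A-C C-B B-D D-A"))
  p <- propagation_params(iterations = 1L, rng_seed = 4)
  sv <- scores_named(netzcore(g, c("A", "C"), p, null_graphs = nulls))
  expect_equal(sv[["B"]], sv[["D"]], tolerance = 1e-12)
  expect_equal(sv[["A"]], sv[["C"]], tolerance = 1e-12)
})

test_that("netscore matches hand examples and the identity case", {
  star <- graph_from_spec("C0-L1 C0-L2 C0-L3")
  # lambda=1, i=1, r=1: each leaf receives 1/3 from the degree-3 center,
  # the center receives 0; min-max scaling maps leaves to 1, center to 0
  p1 <- propagation_params(repetitions = 1L, iterations = 1L, damping = 1,
                           null_replicates = 2L, rng_seed = 1)
  sv <- scores_named(netscore(star, "C0", p1))
  expect_equal(sv, c(C0 = 0, L1 = 1, L2 = 1, L3 = 1))
  # lambda=0 is the identity on the seed indicator
  p0 <- propagation_params(repetitions = 2L, iterations = 3L, damping = 0,
                           null_replicates = 2L, rng_seed = 1)
  sv0 <- scores_named(netscore(star, "C0", p0))
  expect_equal(sv0, c(C0 = 1, L1 = 0, L2 = 0, L3 = 0))
})

test_that("r repetitions compose the single-repetition operator", {
  set.seed(11)
  adj <- random_adj(8, 0.4)
  g <- graph_from_adj(adj)
  seeds <- c("N01", "N03")
  p2 <- propagation_params(repetitions = 2L, iterations = 2L, damping = 0.5,
                           null_replicates = 2L, rng_seed = 1)
  p1 <- propagation_params(repetitions = 1L, iterations = 2L, damping = 0.5,
                           null_replicates = 2L, rng_seed = 1)
  two <- scores_named(netscore(g, seeds, p2))
  # apply the r=1 operator twice by hand: rebased scores feed the second round
  once <- scores_named(netscore(g, seeds, p1))
  s_base <- once
  adjm <- igraph::as_adjacency_matrix(g, sparse = FALSE)[names(s_base), names(s_base)]
  deg <- rowSums(adjm)
  s <- s_base
  for (k in 1:2) {
    contrib <- ifelse(deg > 0, s / deg, 0)
    s <- 0.5 * s_base + 0.5 * as.numeric(adjm %*% contrib)
  }
  expect_equal(two, minmax_scale(stats::setNames(s, names(s_base))),
               tolerance = 1e-12)
})

test_that("netcombo equals direct formula evaluation on random tables", {
  set.seed(21)
  proteins <- sprintf("N%02d", 1:5)
  mk <- function(x, alg) {
    structure(tibble::tibble(protein = proteins, score = x,
                             is_seed = c(TRUE, rep(FALSE, 4))),
              class = c("score_table", class(tibble::tibble())),
              phenotype_id = "P", algorithm = alg)
  }
  for (rep in 1:10) {
    xs <- replicate(3, stats::runif(5), simplify = FALSE)
    got <- scores_named(netcombo(mk(xs[[1]], "netscore"), mk(xs[[2]], "netzcore"),
                                 mk(xs[[3]], "netshort")))
    std <- function(v) if (stats::sd(v) == 0) rep(0, 5) else (v - mean(v)) / stats::sd(v)
    m <- (std(xs[[1]]) + std(xs[[2]]) + std(xs[[3]])) / 3
    want <- minmax_scale(stats::setNames(m, proteins))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # constant table contributes a zero vector
  got0 <- scores_named(netcombo(mk(rep(0.4, 5), "netscore"),
                                mk(1:5 / 5, "netzcore"),
                                mk(c(0.9, 0.1, 0.5, 0.2, 0.8), "netshort")))
  m0 <- (rep(0, 5) + scale01_helper(1:5 / 5) + scale01_helper(c(0.9, 0.1, 0.5, 0.2, 0.8))) / 3
  expect_equal(unname(got0), unname(minmax_scale(m0)), tolerance = 1e-12)
  # identical tables collapse to the min-max of the common table
  t1 <- mk(c(0.2, 0.4, 0.6, 0.8, 1.0), "netscore")
  expect_equal(scores_named(netcombo(t1, t1, t1)),
               minmax_scale(stats::setNames(t1$score, proteins)))
  expect_error(netcombo(t1, t1, mk(stats::runif(5), "x")[c(2, 1, 3, 4, 5), ]),
               "domain")
})

test_that("propagation is equivariant under node relabeling", {
  set.seed(31)
  for (rep in 1:10) {
    adj <- random_adj(7, 0.4)
    g <- graph_from_adj(adj)
    perm <- sample(rownames(adj))
    adj2 <- adj[perm, perm]
    rownames(adj2) <- colnames(adj2) <- sprintf("M%02d", seq_len(7))
    g2 <- graph_from_adj(adj2)
    relabel <- stats::setNames(rownames(adj2), perm)
    seeds <- sample(rownames(adj), 2)
    p <- propagation_params(null_replicates = 2L, rng_seed = 1)
    for (fn in list(function(gg, ss) netshort(gg, ss),
                    function(gg, ss) netscore(gg, ss, p))) {
      sv1 <- scores_named(fn(g, seeds))
      sv2 <- scores_named(fn(g2, unname(relabel[seeds])))
      expect_equal(unname(sv2[unname(relabel[names(sv1)])]), unname(sv1),
                   tolerance = 1e-12)
    }
  }
})

test_that("combined phenotype scoring is deterministic and well-scaled", {
  st <- small_study()
  p <- small_params()
  seeds <- seed_proteins(st$seed_sets, "CVD1")
  t1 <- score_phenotype(st$interactome, seeds, p, "CVD1")
  t2 <- score_phenotype(st$interactome, seeds, p, "CVD1")
  expect_identical(t1$score, t2$score)
  expect_equal(min(t1$score), 0)
  expect_equal(max(t1$score), 1)
  expect_identical(t1$protein, sort(igraph::V(st$interactome)$name, method = "radix"))
  expect_gt(mean(t1$score[t1$is_seed]), mean(t1$score[!t1$is_seed]))
})
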