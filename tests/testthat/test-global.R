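mk_pn2 <- function(graph, nodes, id, category, scores = NULL) {
  if (is.null(scores)) scores <- stats::setNames(rep(0.5, length(nodes)), nodes)
  structure(
    list(phenotype_id = id, category = category,
         graph = igraph::induced_subgraph(graph, nodes),
         nodes = tibble::tibble(protein = nodes,
                                role = rep("top", length(nodes)),
                                score = unname(scores[nodes]))),
    class = "phenotype_network")
}

test_that("merging unions nodes and edges and derives category labels", {
  g <- graph_from_spec("A-B B-C C-D D-A A-C B-D")
  n1 <- mk_pn2(g, c("A", "B"), "CVD1", "CVD")
  n2 <- mk_pn2(g, c("B", "C"), "CD1", "CD")
  n3 <- mk_pn2(g, c("C", "D"), "OS1", "OS")
  gl <- merge_networks(list(n1, n2, n3))
  expect_setequal(igraph::V(gl$graph)$name, c("A", "B", "C", "D"))
  expect_setequal(edge_key_for_test(gl$graph), c("A|B", "B|C", "C|D"))
  lab <- stats::setNames(gl$nodes$category_label, gl$nodes$protein)
  expect_identical(lab[["A"]], "CVD")
  expect_identical(lab[["B"]], "CVD&CD")
  expect_identical(lab[["C"]], "CD&OS")
  expect_identical(lab[["D"]], "OS")
  org <- gl$nodes$origin[gl$nodes$protein == "B"][[1]]
  expect_setequal(org, c("CVD1", "CD1"))
})

test_that("merge equals the set-theoretic union on random inputs", {
  set.seed(81)
  for (rep in 1:30) {
    adj <- random_adj(12, 0.35)
    g <- graph_from_adj(adj)
    nodes <- rownames(adj)
    parts <- lapply(1:3, function(i) sample(nodes, sample(3:8, 1)))
    cats <- c("CVD", "CD", "OS")
    nets <- lapply(1:3, function(i) mk_pn2(g, parts[[i]], paste0("P", i), cats[i]))
    gl <- merge_networks(nets)
    expect_setequal(igraph::V(gl$graph)$name, unique(unlist(parts)))
    want_edges <- sort(unique(unlist(lapply(nets, function(n)
      edge_key_for_test(n$graph)))), method = "radix")
    expect_identical(edge_key_for_test(gl$graph), want_edges)
    # labels partition: every node has exactly one label consistent with origin
    expect_false(any(is.na(gl$nodes$category_label)))
    expect_equal(anyDuplicated(gl$nodes$protein), 0L)
  }
})

test_that("a phenotype missing from the category map is an error", {
  g <- graph_from_spec("A-B B-C")
  n1 <- mk_pn2(g, c("A", "B"), "P1", "CVD")
  n2 <- mk_pn2(g, c("B", "C"), "P2", "CD")
  expect_error(merge_networks(list(n1, n2), c(P1 = "CVD")), "missing")
})

test_that("centralities match hand-enumerated small cases", {
  g <- graph_from_spec("A-B B-C")
  gl <- merge_networks(list(mk_pn2(g, c("A", "B"), "P1", "CVD"),
                            mk_pn2(g, c("B", "C"), "P2", "CD")))
  gl <- compute_centralities(gl)
  dc <- stats::setNames(gl$nodes$degree_centrality, gl$nodes$protein)
  bc <- stats::setNames(gl$nodes$betweenness_centrality, gl$nodes$protein)
  expect_equal(dc[["B"]], 1.0)
  expect_equal(bc[["B"]], 1.0)
  expect_equal(bc[["A"]], 0.0)
  star <- graph_from_spec("C-L1 C-L2 C-L3 C-L4")
  gs <- merge_networks(list(mk_pn2(star, c("C", "L1", "L2", "L3", "L4"), "P1", "CVD"),
                            mk_pn2(star, c("C", "L1"), "P2", "CD")))
  gs <- compute_centralities(gs)
  dcs <- stats::setNames(gs$nodes$degree_centrality, gs$nodes$protein)
  expect_equal(dcs[["C"]], 1.0)
  expect_equal(unname(dcs[paste0("L", 1:4)]), rep(0.25, 4))
})

test_that("centralities equal brute-force oracles on random graphs", {
  set.seed(82)
  for (rep in 1:60) {
    adj <- random_adj(sample(5:12, 1), 0.35)
    g <- graph_from_adj(adj)
    nodes <- rownames(adj)
    gl <- merge_networks(list(mk_pn2(g, nodes, "P1", "CVD"),
                              mk_pn2(g, nodes[1:3], "P2", "CD")))
    gl <- compute_centralities(gl)
    dc <- stats::setNames(gl$nodes$degree_centrality, gl$nodes$protein)
    bc <- stats::setNames(gl$nodes$betweenness_centrality, gl$nodes$protein)
    expect_equal(dc, oracle_degree_centrality(adj)[names(dc)], tolerance = 1e-12)
    expect_equal(bc, oracle_betweenness(adj)[names(bc)], tolerance = 1e-10)
  }
})

test_that("dual-score arithmetic matches the worked threshold example", {
  tabs <- list(
    CVD1 = structure(tibble::tibble(protein = "X", score = 0.6, is_seed = FALSE),
                     class = c("score_table", class(tibble::tibble())),
                     phenotype_id = "CVD1", algorithm = "netcombo"),
    CD1 = structure(tibble::tibble(protein = "X", score = 0.8, is_seed = FALSE),
                    class = c("score_table", class(tibble::tibble())),
                    phenotype_id = "CD1", algorithm = "netcombo"),
    OS1 = structure(tibble::tibble(protein = "X", score = 1.0, is_seed = FALSE),
                    class = c("score_table", class(tibble::tibble())),
                    phenotype_id = "OS1", algorithm = "netcombo"))
  cs <- crosstalk_scores(tabs, c(CVD1 = "CVD", CD1 = "CD", OS1 = "OS"), "X")
  expect_equal(cs$os_excluded, 0.7)
  expect_equal(cs$os_included, 0.8)
  expect_equal(cs$delta, 0.1)
})

test_that("category maxima and delta identities hold on random tables", {
  set.seed(83)
  proteins <- sprintf("N%02d", 1:20)
  mk <- function(id) {
    structure(tibble::tibble(protein = proteins,
                             score = stats::runif(20), is_seed = FALSE),
              class = c("score_table", class(tibble::tibble())),
              phenotype_id = id, algorithm = "netcombo")
  }
  tabs <- list(A1 = mk("A1"), A2 = mk("A2"), B1 = mk("B1"), O1 = mk("O1"))
  cmap <- c(A1 = "CVD", A2 = "CVD", B1 = "CD", O1 = "OS")
  cs <- crosstalk_scores(tabs, cmap, proteins)
  expect_equal(cs$cvd_max, pmax(tabs$A1$score, tabs$A2$score)[match(cs$protein, proteins)])
  expect_equal(cs$os_excluded, (cs$cvd_max + cs$cd_max) / 2, tolerance = 1e-15)
  expect_equal(cs$delta, (cs$os_score - cs$os_excluded) / 3, tolerance = 1e-12)
  expect_true(all(abs(cs$delta) <= 1 / 3 + 1e-15))
  expect_error(crosstalk_scores(tabs[c("A1", "O1")], cmap, proteins), "CVD")
})

test_that("central selection respects groups, k, restriction and ties", {
  g <- graph_from_spec("A-B B-C C-D D-E E-A A-C B-D")
  nets <- list(mk_pn2(g, c("A", "B", "C"), "P1", "CVD"),
               mk_pn2(g, c("C", "D"), "P2", "CD"),
               mk_pn2(g, c("A", "C", "E"), "P3", "OS"))
  gl <- compute_centralities(merge_networks(nets))
  cen <- select_central(gl, k = 2L, restrict = "os_related")
  expect_true(all(grepl("OS", cen$category_label)))
  expect_true(all(cen$rank <= 2L))
  all_cen <- select_central(gl, k = 5L, restrict = "all")
  # groups smaller than k return all members
  counts <- table(all_cen$category_label, all_cen$measure)
  expect_true(all(counts <= 5L))
  # lexicographic tie-break on equal centralities
  tied <- all_cen[all_cen$category_label == "OS" & all_cen$measure == "degree", ]
  if (nrow(tied) > 1L) {
    eq <- tied$centrality[1] == tied$centrality[2]
    if (eq) expect_lt(tied$protein[1], tied$protein[2])
  }
})

test_that("delta refinement is inclusive at the threshold", {
  cs <- tibble::tibble(protein = c("A", "B", "C"),
                       delta = c(0.1, 0.0999, -0.15))
  expect_setequal(filter_by_delta(cs, c("A", "B", "C"), 0.1), c("A", "C"))
  expect_identical(filter_by_delta(cs, character(0), 0.1), character(0))
})

test_that("interactor classification partitions the pooled neighbourhood", {
  g <- graph_from_spec("H1-A H1-B H2-C H1-D H2-D")
  nets <- list(mk_pn2(g, c("H1", "A", "D"), "P1", "CVD"),
               mk_pn2(g, c("H2", "B", "C", "D"), "P2", "CD"),
               mk_pn2(g, c("H1", "H2", "B"), "P3", "OS"))
  gl <- merge_networks(nets)
  cls <- classify_interactors(gl, c("H1", "H2"))
  got <- stats::setNames(cls$class, cls$protein)
  expect_identical(got[["A"]], "cvd_only")   # label CVD
  expect_identical(got[["B"]], "cd_only")    # label CD&OS
  expect_identical(got[["C"]], "cd_only")
  expect_identical(got[["D"]], "both")       # label CVD&CD
  # partition: disjoint and covering the pooled neighbourhood minus centrals
  expect_setequal(cls$protein, c("A", "B", "C", "D"))
  expect_equal(anyDuplicated(cls$protein), 0L)
})

test_that("classification is a partition on random networks", {
  set.seed(84)
  for (rep in 1:20) {
    adj <- random_adj(12, 0.35)
    g <- graph_from_adj(adj)
    nodes <- rownames(adj)
    nets <- list(mk_pn2(g, sample(nodes, 6), "P1", "CVD"),
                 mk_pn2(g, sample(nodes, 6), "P2", "CD"),
                 mk_pn2(g, sample(nodes, 6), "P3", "OS"))
    gl <- merge_networks(nets)
    present <- igraph::V(gl$graph)$name
    centrals <- sample(present, 2)
    cls <- classify_interactors(gl, centrals)
    pooled <- setdiff(unique(unlist(lapply(
      igraph::adjacent_vertices(gl$graph, centrals), function(v) v$name))),
      centrals)
    expect_setequal(cls$protein, pooled)
    expect_true(all(cls$class %in% c("cvd_only", "cd_only", "both", "os_only")))
  }
})

test_that("topology summary matches hand enumeration", {
  g <- graph_from_spec("A-B B-C")
  gl <- merge_networks(list(mk_pn2(g, c("A", "B"), "P1", "CVD"),
                            mk_pn2(g, c("B", "C"), "P2", "CD")))
  ts <- summarize_topology(gl)
  expect_equal(ts$average_shortest_path_length, 4 / 3)
  expect_equal(ts$average_clustering_coefficient, 0)
  tri <- graph_from_spec("A-B B-C C-A")
  expect_equal(summarize_topology(tri)$average_clustering_coefficient, 1.0)
  pair <- igraph::make_empty_graph(0, directed = FALSE) |>
    igraph::add_vertices(2, name = c("A", "B"))
  expect_warning(ts0 <- summarize_topology(pair), "no edges")
  expect_equal(ts0$average_shortest_path_length, 0)
})

test_that("delta distribution counts conserve and respect the bound", {
  set.seed(85)
  n <- 500
  cs <- tibble::tibble(
    protein = sprintf("N%03d", 1:n),
    cvd_max = stats::runif(n), cd_max = stats::runif(n),
    os_score = stats::runif(n))
  cs$os_excluded <- (cs$cvd_max + cs$cd_max) / 2
  cs$os_included <- (cs$cvd_max + cs$cd_max + cs$os_score) / 3
  cs$delta <- cs$os_included - cs$os_excluded
  dd <- delta_distribution(cs, 0.1)
  expect_equal(dd$n_increased + dd$n_decreased + dd$n_unaffected, n)
  expect_lt(max(abs(c(dd$min_delta, dd$max_delta))), 1 / 3)
  flat <- cs
  flat$delta <- 0
  dd0 <- delta_distribution(flat, 0.1)
  expect_equal(dd0$n_unaffected, n)
})
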