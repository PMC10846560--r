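#' Rank planted crosstalk bridges among non-seed candidates
#'
#' The pipeline's parameter-recovery statistic on synthetic data. For every
#' cardiovascular-by-cognitive phenotype pair, every interactome protein is
#' ranked by its overlap score (the mean of its two propagation scores;
#' propagation scores every node, so the ranking covers the full non-seed
#' universe, not only the overlap subnetwork). Proteins that are seeds of
#' either parent are excluded, and each planted bridge is assigned its best
#' rank across the pairs. A successful recovery places the bridges' median
#' relative rank deep in the top decile.
#'
#' @param score_tables Named list of `score_table`s covering all phenotypes.
#' @param seed_sets Seed tibble (supplies seeds and categories).
#' @param bridges Character vector of planted bridge proteins
#'   (`truth$bridge_proteins`).
#' @return Tibble `protein`, `best_pair`, `best_rank`, `n_candidates`,
#'   `relative_rank`, one row per bridge.
#' @export
rank_planted_bridges <- function(score_tables, seed_sets, bridges) {
  cats <- stats::setNames(seed_sets$category, seed_sets$phenotype_id)
  ids <- names(score_tables)
  cvd <- ids[cats[ids] == "CVD"]
  cd <- ids[cats[ids] == "CD"]
  if (length(cvd) == 0L || length(cd) == 0L) {
    stopf("need scored CVD and CD phenotypes")
  }
  best <- tibble(protein = bridges, best_pair = NA_character_,
                 best_rank = Inf, n_candidates = NA_integer_,
                 relative_rank = Inf)
  for (p1 in cvd) for (p2 in cd) {
    s1 <- scores_vector(score_tables[[p1]])
    s2 <- scores_vector(score_tables[[p2]])
    seeds <- union(seed_proteins(seed_sets, p1), seed_proteins(seed_sets, p2))
    univ <- setdiff(names(s1), seeds)
    osc <- overlap_score(s1[univ], s2[univ])
    rk <- rank(-osc, ties.method = "min")
    hit <- bridges %in% univ
    rr <- ifelse(hit, rk[bridges], Inf)
    better <- rr < best$best_rank
    best$best_rank[better] <- rr[better]
    best$best_pair[better] <- paste(p1, p2, sep = "~")
    best$n_candidates[better] <- length(univ)
    best$relative_rank[better] <- rr[better] / length(univ)
  }
  best
}

#' Hypergeometric enrichment of a planted module among the top fraction
#'
#' Tests whether a phenotype's planted module members are over-represented
#' among its top-scoring `fraction` of the interactome, against the
#' hypergeometric null of drawing the selection uniformly: a one-sided upper
#' tail on the selection/member overlap.
#'
#' @param score_table `score_table` for the phenotype.
#' @param members Character vector of planted module members.
#' @param fraction Top fraction (default 0.02).
#' @return Tibble `n_top`, `n_members`, `overlap`, `p_value`.
#' @export
module_recovery_pvalue <- function(score_table, members, fraction = 0.02) {
  top <- select_top_fraction(score_table, fraction)
  n <- nrow(score_table)
  members <- intersect(members, score_table$protein)
  ov <- length(intersect(top, members))
  p <- stats::phyper(ov - 1L, length(members), n - length(members),
                     length(top), lower.tail = FALSE)
  tibble(n_top = length(top), n_members = length(members),
         overlap = ov, p_value = p)
}
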