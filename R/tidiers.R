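#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a score table
#'
#' @param x A `score_table`.
#' @param ... Unused.
#' @return A plain tibble `phenotype_id`, `algorithm`, `protein`, `score`,
#'   `is_seed`.
#' @export
tidy.score_table <- function(x, ...) {
  tibble(phenotype_id = attr(x, "phenotype_id"),
         algorithm = attr(x, "algorithm"),
         protein = x$protein, score = x$score, is_seed = x$is_seed)
}

#' One-row summary of a score table
#'
#' @inheritParams tidy.score_table
#' @return Tibble with node counts and the seed / non-seed mean scores.
#' @export
glance.score_table <- function(x, ...) {
  tibble(phenotype_id = attr(x, "phenotype_id"),
         algorithm = attr(x, "algorithm"),
         n_proteins = nrow(x),
         n_seeds = sum(x$is_seed),
         mean_seed_score = mean(x$score[x$is_seed]),
         mean_nonseed_score = mean(x$score[!x$is_seed]))
}

#' @export
tidy.phenotype_network <- function(x, ...) {
  mutate(x$nodes, phenotype_id = x$phenotype_id, category = x$category,
         .before = 1L)
}

#' @export
glance.phenotype_network <- function(x, ...) {
  tibble(phenotype_id = x$phenotype_id, category = x$category,
         n_nodes = nrow(x$nodes),
         n_seeds = sum(x$nodes$role == "seed"),
         n_top = sum(x$nodes$role == "top"),
         n_linkers = sum(x$nodes$role == "linker"),
         n_edges = igraph::ecount(x$graph))
}

#' @export
tidy.overlap_network <- function(x, ...) {
  mutate(x$nodes, pair = paste(x$pair, collapse = "~"), .before = 1L)
}

#' @export
glance.overlap_network <- function(x, ...) {
  tibble(phenotype_1 = x$pair[1], phenotype_2 = x$pair[2],
         n_shared = nrow(x$nodes), n_edges = igraph::ecount(x$graph),
         max_overlap_score = if (nrow(x$nodes)) max(x$nodes$overlap_score)
                             else NA_real_)
}

#' @export
tidy.global_network <- function(x, ...) {
  mutate(x$nodes,
         origin = vapply(.data$origin, paste, character(1), collapse = ","))
}

#' @export
glance.global_network <- function(x, ...) {
  bind_cols(summarize_topology(x),
            tibble(n_category_labels = length(unique(x$nodes$category_label))))
}

#' Score distribution of a phenotype, seeds versus the rest
#'
#' @param object A `score_table`.
#' @param ... Unused.
#' @return A ggplot: score histograms faceted by seed status.
#' @export
autoplot.score_table <- function(object, ...) {
  df <- tidy(object) |>
    mutate(status = ifelse(.data$is_seed, "seed", "non-seed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    ggplot2::facet_wrap(~status, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      title = sprintf("%s scores, %s", attr(object, "algorithm"),
                      attr(object, "phenotype_id")),
      x = "propagation score", y = "proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Role-stratified scores of a phenotype subnetwork
#'
#' @param object A `phenotype_network`.
#' @param ... Unused.
#' @return A ggplot boxplot of scores by role.
#' @export
autoplot.phenotype_network <- function(object, ...) {
  ggplot2::ggplot(object$nodes,
                  ggplot2::aes(x = .data$role, y = .data$score,
                               fill = .data$role)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(title = sprintf("%s (%s) subnetwork",
                                  object$phenotype_id, object$category),
                  x = NULL, y = "propagation score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Centrality map of the Global Network
#'
#' @param object A `global_network` annotated by [compute_centralities()].
#' @param ... Unused.
#' @return A ggplot of betweenness against degree centrality, coloured by
#'   category label.
#' @export
autoplot.global_network <- function(object, ...) {
  if (is.null(object$nodes$degree_centrality)) {
    object <- compute_centralities(object)
  }
  ggplot2::ggplot(object$nodes,
                  ggplot2::aes(x = .data$degree_centrality,
                               y = .data$betweenness_centrality,
                               colour = .data$category_label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = "Global Network centralities",
                  x = "degree centrality (deg / (n-1))",
                  y = "betweenness centrality (normalized)",
                  colour = "categories") +
    ggplot2::theme_minimal()
}

#' Plot the stress-sensitivity delta distribution
#'
#' Histogram of the OS-included minus OS-excluded score difference with the
#' selection threshold marked.
#'
#' @param scores Crosstalk-score tibble from [crosstalk_scores()].
#' @param threshold Threshold drawn as vertical lines (default 0.1).
#' @return A ggplot.
#' @export
plot_delta_distribution <- function(scores, threshold = 0.1) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "delta = OS-included - OS-excluded score",
                  y = "proteins") +
    ggplot2::theme_minimal()
}
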