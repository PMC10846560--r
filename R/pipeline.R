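#' Default pipeline configuration
#'
#' A complete configuration for running the pipeline end-to-end on the
#' default synthetic study. Every constant of the analysis is surfaced here:
#' the top fraction (0.02), the stress-sensitivity threshold (0.1), the
#' per-measure central-protein count (5), and the propagation defaults.
#'
#' @param out_dir Output directory.
#' @param rng_seed Integer master seed (required).
#' @return A named list understood by [run_pipeline()].
#' @export
default_run_config <- function(out_dir, rng_seed) {
  if (missing(rng_seed)) stopf("rng_seed is required")
  list(
    out_dir = out_dir,
    rng_seed = as.integer(rng_seed),
    synthetic = list(
      n_nodes = 1000L, attach_m = 2L,
      phenotypes = c(CVD1 = "CVD", CVD2 = "CVD", CD1 = "CD", OS1 = "OS"),
      module_size = 40L, module_density = 0.3, seed_fraction = 0.4,
      inter_category_overlap = 0.1, n_bridges = 10L,
      n_random_gene_sets = 20L, random_gene_set_size = 40L
    ),
    fraction = 0.02,
    delta_threshold = 0.1,
    top_k = 5L,
    overlap_top = 3L,
    pairing = "all",
    min_seeds = 2L,
    propagation = list(repetitions = 3L, iterations = 2L, damping = 0.5,
                       null_replicates = 100L, swaps_per_edge = 10L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [default_run_config()]; file
#'   inputs go under `paths:` (`edges`, `seeds`, `categories`, `gene_sets`)
#'   as an alternative to the `synthetic:` block.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic$phenotypes)) {
    cfg$synthetic$phenotypes <- unlist(cfg$synthetic$phenotypes)
  }
  cfg
}

validate_config <- function(config) {
  if (is.null(config$rng_seed)) stopf("config$rng_seed is required")
  if (is.null(config$out_dir)) stopf("config$out_dir is required")
  has_paths <- !is.null(config$paths)
  has_synth <- !is.null(config$synthetic)
  if (!has_paths && !has_synth) {
    stopf("config needs either a 'paths' block or a 'synthetic' block")
  }
  if (has_paths) {
    for (f in c("edges", "seeds", "categories")) {
      p <- config$paths[[f]]
      if (is.null(p)) stopf("config$paths$%s is required", f)
      if (!file.exists(p)) stopf("config$paths$%s does not exist: %s", f, p)
    }
    if (!is.null(config$paths$gene_sets) &&
        !file.exists(config$paths$gene_sets)) {
      stopf("config$paths$gene_sets does not exist: %s", config$paths$gene_sets)
    }
  }
  defaults <- default_run_config(config$out_dir, config$rng_seed)
  for (f in c("fraction", "delta_threshold", "top_k", "overlap_top",
              "pairing", "min_seeds", "propagation")) {
    config[[f]] <- config[[f]] %||% defaults[[f]]
  }
  for (f in names(defaults$propagation)) {
    config$propagation[[f]] <- config$propagation[[f]] %||%
      defaults$propagation[[f]]
  }
  stopifnot(config$fraction > 0, config$fraction <= 1,
            config$delta_threshold > 0, config$top_k >= 1L,
            config$overlap_top >= 1L)
  config
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.12g", df[[j]])
    }
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) paste(x, collapse = ","),
                        character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Run the full crosstalk pipeline
#'
#' Executes every stage in order — simulate (or load), propagate, extract
#' phenotype subnetworks, overlap analysis, Global Network analysis, and
#' enrichment — writing plain-text outputs under `config$out_dir` and a
#' machine-readable `manifest.json` recording parameters, per-stage output
#' paths and MD5 checksums. Deterministic for a fixed `rng_seed`.
#'
#' @param config Configuration list (see [default_run_config()]) or a path
#'   to a YAML file.
#' @return Invisibly, a list with the manifest plus the in-memory stage
#'   results (`interactome`, `seed_sets`, `truth`, `score_tables`,
#'   `networks`, `overlaps`, `candidates`, `global`, `crosstalk`,
#'   `central`, `refined`, `interactors`, `topology`, `enrichment`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # -- stage 1: inputs ------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sim <- stage("simulate", {
      sc <- config$synthetic
      synthetic_crosstalk_study(
        n_nodes = sc$n_nodes, attach_m = sc$attach_m,
        phenotype_specs = sc$phenotypes,
        module_size = sc$module_size, module_density = sc$module_density,
        seed_fraction = sc$seed_fraction,
        inter_category_overlap = sc$inter_category_overlap,
        n_bridges = sc$n_bridges, rng_seed = config$rng_seed)
    })
    interactome <- sim$interactome
    seed_sets <- sim$seed_sets
    truth <- sim$truth
    fixture_dir <- file.path(out_dir, "fixtures")
    paths <- write_fixture_bundle(truth, interactome, seed_sets, fixture_dir)
    outputs <- c(outputs, unname(paths))
    collection <- synthetic_gene_sets(
      truth, interactome,
      n_random_sets = config$synthetic$n_random_gene_sets %||% 20L,
      random_set_size = config$synthetic$random_gene_set_size %||% 40L,
      rng_seed = derive_seed(config$rng_seed, "gene-sets"))
    gmt_path <- file.path(fixture_dir, "gene_sets.gmt")
    write_gmt(collection, gmt_path)
    outputs <- c(outputs, gmt_path)
  } else {
    interactome <- stage("load", read_edge_list(config$paths$edges))
    seed_sets <- stage("load", read_seed_sets(config$paths$seeds, interactome,
                                              config$paths$categories))
    truth <- NULL
    collection <- if (!is.null(config$paths$gene_sets)) {
      stage("load", read_gmt(config$paths$gene_sets))
    } else NULL
  }
  seed_sets <- filter_phenotypes_by_seed_count(seed_sets, config$min_seeds)

  # -- stage 2: propagation -------------------------------------------------
  params <- propagation_params(
    repetitions = config$propagation$repetitions,
    iterations = config$propagation$iterations,
    damping = config$propagation$damping,
    null_replicates = config$propagation$null_replicates,
    swaps_per_edge = config$propagation$swaps_per_edge,
    rng_seed = config$rng_seed)
  score_tables <- stage("propagation",
                        score_all_phenotypes(interactome, seed_sets, params))
  score_dir <- file.path(out_dir, "scores")
  if (!dir.exists(score_dir)) dir.create(score_dir)
  for (p in names(score_tables)) {
    outputs <- c(outputs, write_tsv_plain(
      score_tables[[p]], file.path(score_dir, paste0(p, ".tsv"))))
  }

  # -- stage 3: phenotype subnetworks ---------------------------------------
  networks <- stage("subnetworks", build_all_phenotype_networks(
    interactome, score_tables, seed_sets, fraction = config$fraction))
  net_dir <- file.path(out_dir, "networks")
  if (!dir.exists(net_dir)) dir.create(net_dir)
  for (p in names(networks)) {
    outputs <- c(outputs, write_tsv_plain(
      networks[[p]]$nodes, file.path(net_dir, paste0(p, "_nodes.tsv"))))
    outputs <- c(outputs, write_network(
      networks[[p]]$graph, file.path(net_dir, paste0(p, "_edges.tsv")), "tsv"))
  }

  # -- stage 4: overlap analysis --------------------------------------------
  overlaps <- stage("overlap",
                    all_pairwise_overlaps(networks, pairing = config$pairing))
  candidates <- bind_rows(lapply(names(overlaps), function(nm) {
    suppressWarnings(top_candidates(overlaps[[nm]], config$overlap_top)) |>
      mutate(pair = nm, .before = 1L)
  }))
  outputs <- c(outputs, write_tsv_plain(
    candidates, file.path(out_dir, "overlap_candidates.tsv")))

  # -- stage 5: global network ----------------------------------------------
  global <- stage("global", {
    merge_networks(networks) |> compute_centralities()
  })
  crosstalk <- stage("global", crosstalk_scores(
    score_tables,
    stats::setNames(seed_sets$category, seed_sets$phenotype_id),
    universe = igraph::V(global$graph)$name))
  central_tbl <- select_central(global, k = config$top_k,
                                restrict = "os_related")
  central_set <- lex_sort(unique(central_tbl$protein))
  refined <- filter_by_delta(crosstalk, central_set,
                             threshold = config$delta_threshold)
  interactors <- classify_interactors(global, refined)
  topology <- summarize_topology(global)
  deltas <- delta_distribution(crosstalk, threshold = config$delta_threshold)
  outputs <- c(outputs,
               write_tsv_plain(global$nodes, file.path(out_dir, "global_nodes.tsv")),
               write_network(global$graph, file.path(out_dir, "global_edges.tsv"), "tsv"),
               write_tsv_plain(crosstalk, file.path(out_dir, "crosstalk_scores.tsv")),
               write_tsv_plain(central_tbl, file.path(out_dir, "central_proteins.tsv")),
               write_tsv_plain(interactors, file.path(out_dir, "interactors.tsv")))
  writeLines(refined, file.path(out_dir, "refined_central_proteins.txt"))
  outputs <- c(outputs, file.path(out_dir, "refined_central_proteins.txt"))
  jsonlite::write_json(c(as.list(topology), as.list(deltas)),
                       file.path(out_dir, "topology.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- c(outputs, file.path(out_dir, "topology.json"))

  # -- stage 6: enrichment --------------------------------------------------
  enrichment <- NULL
  if (!is.null(collection) && length(refined) > 0L) {
    enrichment <- stage("enrichment", enrich_three_settings(
      global, refined, collection))
    enr_tbl <- bind_rows(enrichment)
    outputs <- c(outputs, write_tsv_plain(
      enr_tbl, file.path(out_dir, "enrichment.tsv")))
  }

  # -- manifest ------------------------------------------------------------
  rel <- ifelse(startsWith(outputs, paste0(out_dir, "/")),
                substring(outputs, nchar(out_dir) + 2L), outputs)
  manifest <- list(
    package = "netcrosstalk",
    version = as.character(utils::packageVersion("netcrosstalk")),
    parameters = config[setdiff(names(config), "out_dir")],
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))), rel)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest,
                 interactome = interactome, seed_sets = seed_sets,
                 truth = truth, score_tables = score_tables,
                 networks = networks, overlaps = overlaps,
                 candidates = candidates, global = global,
                 crosstalk = crosstalk, central = central_tbl,
                 refined = refined, interactors = interactors,
                 topology = topology, deltas = deltas,
                 enrichment = enrichment))
}
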