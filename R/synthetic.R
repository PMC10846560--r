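#' Generate a scale-free synthetic interactome
#'
#' Preferential-attachment growth emulating the heavy-tailed degree
#' distribution of real protein-protein interaction networks: starting from
#' `attach_m` unconnected founder proteins, each new protein attaches to
#' `attach_m` distinct existing proteins with probability proportional to
#' `degree + 1`. The result is a connected simple graph with exactly
#' `attach_m * (n_nodes - attach_m)` edges, deterministic per seed.
#'
#' @param n_nodes Number of proteins (> `attach_m`).
#' @param attach_m Edges added per new protein (>= 1).
#' @param rng_seed Integer seed.
#' @return An igraph interactome with vertex names `P0001`, `P0002`, ...
#' @export
generate_interactome <- function(n_nodes, attach_m = 2L, rng_seed) {
  stopifnot(n_nodes > attach_m, attach_m >= 1L)
  if (missing(rng_seed)) stopf("rng_seed is required")
  names_all <- sprintf(paste0("P%0", nchar(as.character(n_nodes)), "d"),
                       seq_len(n_nodes))
  deg <- integer(n_nodes)
  n_edges <- attach_m * (n_nodes - attach_m)
  from <- integer(n_edges)
  to <- integer(n_edges)
  k <- 0L
  with_seed(rng_seed, {
    for (v in (attach_m + 1L):n_nodes) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing, attach_m, prob = deg[existing] + 1)
      for (t in targets) {
        k <- k + 1L
        from[k] <- v
        to[k] <- t
      }
      deg[targets] <- deg[targets] + 1L
      deg[v] <- deg[v] + attach_m
    }
  })
  igraph::graph_from_data_frame(
    data.frame(from = names_all[from], to = names_all[to]),
    directed = FALSE, vertices = names_all)
}

new_synthetic_truth <- function(module_members, seeds, bridges, parameters) {
  structure(
    list(module_members = module_members, seeds = seeds,
         bridge_proteins = bridges, parameters = parameters),
    class = "synthetic_truth"
  )
}

#' Plant phenotype modules with seeds into an interactome
#'
#' For each phenotype, selects a member subset and densifies it by adding
#' edges until the intra-module density reaches `module_density` (edges are
#' added, never rewired, preserving the scale-free backbone). A fraction
#' `seed_fraction` of each module's members becomes that phenotype's seed
#' proteins. Membership overlap across disease categories is controlled by
#' `inter_category_overlap`: each CVD/CD module after the first draws that
#' fraction of its members from modules of the other category, and the OS
#' module draws from CVD and CD modules alike (oxidative stress straddles
#' both categories).
#'
#' @param interactome igraph interactome from [generate_interactome()].
#' @param phenotype_specs Named character vector phenotype id -> category
#'   (`CVD`, `CD` or `OS`).
#' @param module_size Members per module.
#' @param module_density Target intra-module edge density in `(0, 1]`.
#' @param seed_fraction Fraction of members sampled as seeds in `(0, 1]`.
#' @param inter_category_overlap Fraction of members shared with the other
#'   category's modules, in `[0, 1)`.
#' @param rng_seed Integer seed.
#' @return List with `interactome` (densified graph), `seed_sets` (tibble
#'   `phenotype_id`, `category`, `protein`) and `truth` (a
#'   `synthetic_truth`).
#' @export
plant_phenotype_modules <- function(interactome, phenotype_specs,
                                    module_size = 40L, module_density = 0.3,
                                    seed_fraction = 0.4,
                                    inter_category_overlap = 0.1,
                                    rng_seed) {
  if (missing(rng_seed)) stopf("rng_seed is required")
  assert_category(unname(phenotype_specs))
  stopifnot(module_density > 0, module_density <= 1,
            seed_fraction > 0, seed_fraction <= 1,
            inter_category_overlap >= 0, inter_category_overlap < 1)
  nodes <- igraph::V(interactome)$name
  if (length(phenotype_specs) * module_size > length(nodes)) {
    stopf("module sizes exceed the interactome size")
  }
  g <- interactome
  members <- list()
  seeds <- list()
  used <- character(0)
  with_seed(rng_seed, {
    for (p in names(phenotype_specs)) {
      cat_p <- phenotype_specs[[p]]
      pool_other <- switch(
        cat_p,
        CVD = unlist(members[names(phenotype_specs)[phenotype_specs == "CD"]]),
        CD = unlist(members[names(phenotype_specs)[phenotype_specs == "CVD"]]),
        OS = unlist(members[names(phenotype_specs)[phenotype_specs != "OS"]])
      )
      pool_other <- unique(pool_other %||% character(0))
      n_shared <- min(round(inter_category_overlap * module_size),
                      length(pool_other))
      shared <- if (n_shared > 0L) sample(pool_other, n_shared) else character(0)
      free <- setdiff(nodes, c(used, shared))
      n_fresh <- module_size - length(shared)
      if (n_fresh > length(free)) stopf("not enough free nodes for module %s", p)
      mem <- c(shared, sample(free, n_fresh))
      members[[p]] <- lex_sort(mem)
      used <- union(used, mem)

      # densify: add missing intra-module edges up to the target density
      target <- ceiling(module_density * choose(length(mem), 2))
      sub <- igraph::induced_subgraph(g, mem)
      have <- igraph::ecount(sub)
      if (target > have) {
        pairs <- t(utils::combn(lex_sort(mem), 2L))
        key <- paste(pairs[, 1L], pairs[, 2L], sep = "\t")
        existing <- edge_key(sub)
        avail <- which(!(key %in% existing))
        add <- avail[sample.int(length(avail), target - have)]
        g <- igraph::add_edges(
          g, as.vector(t(pairs[add, , drop = FALSE])))
      }
      n_seed <- max(2L, ceiling(seed_fraction * length(mem)))
      seeds[[p]] <- lex_sort(sample(members[[p]], n_seed))
    }
  })
  seed_sets <- bind_rows(lapply(names(phenotype_specs), function(p) {
    tibble(phenotype_id = p, category = phenotype_specs[[p]],
           protein = seeds[[p]])
  }))
  truth <- new_synthetic_truth(
    members, seeds, character(0),
    list(n_nodes = length(nodes), module_size = module_size,
         module_density = module_density, seed_fraction = seed_fraction,
         inter_category_overlap = inter_category_overlap,
         rng_seed = as.integer(rng_seed)))
  list(interactome = g, seed_sets = seed_sets, truth = truth)
}

#' Plant crosstalk bridge proteins
#'
#' Selects `n_bridges` proteins outside every module and wires each to two
#' seed members of a cardiovascular module and two seed members of a
#' cognitive module (seeds are module members, and being adjacent to two
#' nodes of each selected subnetwork makes every bridge an eligible linker in
#' both parents). These are the planted ground-truth crosstalk candidates.
#'
#' @param interactome igraph interactome (already carrying planted modules).
#' @param truth `synthetic_truth` from [plant_phenotype_modules()].
#' @param n_bridges Number of bridges (>= 0).
#' @param rng_seed Integer seed.
#' @return List with the augmented `interactome` and updated `truth`.
#' @export
plant_crosstalk_bridges <- function(interactome, truth, n_bridges = 10L,
                                    rng_seed) {
  if (missing(rng_seed)) stopf("rng_seed is required")
  if (n_bridges == 0L) return(list(interactome = interactome, truth = truth))
  cat_map <- truth$parameters$categories
  if (is.null(cat_map)) {
    stopf("truth$parameters$categories must map phenotype ids to categories")
  }
  cvd_mods <- names(cat_map)[cat_map == "CVD"]
  cd_mods <- names(cat_map)[cat_map == "CD"]
  if (length(cvd_mods) == 0L || length(cd_mods) == 0L) {
    stopf("need at least one CVD and one CD module to plant bridges")
  }
  all_members <- unique(unlist(truth$module_members))
  free <- setdiff(igraph::V(interactome)$name, all_members)
  if (length(free) < n_bridges) stopf("not enough free nodes for %d bridges",
                                      n_bridges)
  g <- interactome
  bridges <- character(0)
  with_seed(rng_seed, {
    bridges <- lex_sort(sample(lex_sort(free), n_bridges))
    for (b in bridges) {
      mv <- sample(cvd_mods, 1L)
      md <- sample(cd_mods, 1L)
      anchors <- c(sample(truth$seeds[[mv]], 2L), sample(truth$seeds[[md]], 2L))
      for (a in anchors) {
        if (!igraph::are_adjacent(g, b, a)) {
          g <- igraph::add_edges(g, c(b, a))
        }
      }
    }
  })
  truth$bridge_proteins <- bridges
  truth$parameters$n_bridges <- as.integer(n_bridges)
  list(interactome = g, truth = truth)
}

#' Generate the full synthetic crosstalk study
#'
#' One call producing the default study conditions the pipeline is validated
#' on: a scale-free interactome of 1000 proteins, two cardiovascular modules,
#' one cognitive module and one oxidative-stress module of 40 members each at
#' intra-module density 0.3, 40% of members seeded, and 10 planted crosstalk
#' bridges wired to both disease categories.
#'
#' @param n_nodes,attach_m Interactome size parameters.
#' @param phenotype_specs Named character vector phenotype id -> category.
#' @param module_size,module_density,seed_fraction,inter_category_overlap
#'   Module parameters (see [plant_phenotype_modules()]).
#' @param n_bridges Planted crosstalk bridges.
#' @param rng_seed Integer master seed (required).
#' @return List with `interactome`, `seed_sets`, `truth`.
#' @export
synthetic_crosstalk_study <- function(
    n_nodes = 1000L, attach_m = 2L,
    phenotype_specs = c(CVD1 = "CVD", CVD2 = "CVD", CD1 = "CD", OS1 = "OS"),
    module_size = 40L, module_density = 0.3, seed_fraction = 0.4,
    inter_category_overlap = 0.1, n_bridges = 10L, rng_seed) {
  if (missing(rng_seed)) stopf("rng_seed is required")
  g <- generate_interactome(n_nodes, attach_m,
                            rng_seed = derive_seed(rng_seed, "interactome"))
  planted <- plant_phenotype_modules(
    g, phenotype_specs, module_size, module_density, seed_fraction,
    inter_category_overlap, rng_seed = derive_seed(rng_seed, "modules"))
  planted$truth$parameters$categories <- phenotype_specs
  planted$truth$parameters$n_nodes <- n_nodes
  planted$truth$parameters$attach_m <- as.integer(attach_m)
  planted$truth$parameters$master_rng_seed <- as.integer(rng_seed)
  bridged <- plant_crosstalk_bridges(
    planted$interactome, planted$truth, n_bridges,
    rng_seed = derive_seed(rng_seed, "bridges"))
  list(interactome = bridged$interactome,
       seed_sets = planted$seed_sets,
       truth = bridged$truth)
}

#' Generate a synthetic gene-set collection
#'
#' Builds a collection for exercising the enrichment stage against known
#' ground truth: one set per planted module (its exact member list, id
#' `module_<phenotype>`) plus `n_random_sets` sets drawn uniformly from the
#' interactome. All sets are synthetic stand-ins for curated pathway
#' collections.
#'
#' @param truth `synthetic_truth` with planted modules.
#' @param interactome igraph interactome (supplies the universe for random
#'   sets).
#' @param n_random_sets Number of random decoy sets (default 20).
#' @param random_set_size Size of each decoy set (default 40).
#' @param rng_seed Integer seed.
#' @return Named list of gene sets with a `descriptions` attribute,
#'   writable with [write_gmt()].
#' @export
synthetic_gene_sets <- function(truth, interactome, n_random_sets = 20L,
                                random_set_size = 40L, rng_seed) {
  if (missing(rng_seed)) stopf("rng_seed is required")
  nodes <- igraph::V(interactome)$name
  sets <- stats::setNames(truth$module_members,
                          paste0("module_", names(truth$module_members)))
  with_seed(rng_seed, {
    for (i in seq_len(n_random_sets)) {
      sets[[sprintf("random_%02d", i)]] <- lex_sort(
        sample(nodes, min(random_set_size, length(nodes))))
    }
  })
  attr(sets, "descriptions") <- stats::setNames(
    c(paste("synthetic planted module for", names(truth$module_members)),
      rep("synthetic random decoy set", n_random_sets)),
    names(sets))
  sets
}

#' Write a synthetic study to plain-text fixture files
#'
#' Writes `edges.tsv` (sorted two-column edge list), `seeds.tsv`
#' (`phenotype_id`, `protein`, `category`), `categories.tsv` and
#' `truth.json`; all re-readable with the package's readers and byte-stable
#' for a fixed seed.
#'
#' @param truth `synthetic_truth`.
#' @param interactome igraph interactome.
#' @param seed_sets Seed tibble.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fixture_bundle <- function(truth, interactome, seed_sets, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory: %s", out_dir)
  }
  paths <- c(edges = file.path(out_dir, "edges.tsv"),
             seeds = file.path(out_dir, "seeds.tsv"),
             categories = file.path(out_dir, "categories.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_network(interactome, paths[["edges"]], "tsv")
  ss <- seed_sets[lex_order(seed_sets$phenotype_id, seed_sets$protein), ]
  writeLines(paste(ss$phenotype_id, ss$protein, ss$category, sep = "\t"),
             paths[["seeds"]])
  cmap <- unique(ss[, c("phenotype_id", "category")])
  writeLines(paste(cmap$phenotype_id, cmap$category, sep = "\t"),
             paths[["categories"]])
  jsonlite::write_json(
    list(module_members = truth$module_members,
         seeds = truth$seeds,
         bridge_proteins = truth$bridge_proteins,
         parameters = truth$parameters),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
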