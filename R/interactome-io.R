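#' Read an undirected interactome from an edge-list file
#'
#' Reads a protein-protein interaction network from a two-column TSV edge list
#' or a SIF file (`A <relation> B [B2 ...]`). The result is always a simple
#' undirected [igraph][igraph::igraph-package] graph: duplicate rows and
#' reversed duplicates collapse to a single edge, and self-loop rows are
#' dropped (and counted in a message), because the propagation algorithms
#' assume a simple graph.
#'
#' Node identifiers are opaque case-sensitive gene symbols; no identifier
#' mapping is attempted.
#'
#' @param path Path to the edge-list file.
#' @param format `"tsv"` (two tab-separated columns) or `"sif"`
#'   (`node relation node ...`; one row may carry several partners).
#' @return An undirected simple `igraph` graph whose vertex names are the
#'   protein identifiers.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tA", "A\tA", "B\tC"), tf)
#' g <- read_edge_list(tf)
#' igraph::vcount(g) # 3
#' igraph::ecount(g) # 2
#' @export
read_edge_list <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("edge-list file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty edge-list file: %s", path)

  pairs_from <- character(0)
  pairs_to <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (format == "sif" && length(fields) == 1L) {
      # SIF allows whitespace-delimited fields as well
      fields <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    }
    if (format == "tsv") {
      if (length(fields) != 2L) {
        stopf("malformed TSV edge row at line %d: expected 2 columns, got %d",
              i, length(fields))
      }
      pairs_from <- c(pairs_from, fields[[1]])
      pairs_to <- c(pairs_to, fields[[2]])
    } else {
      if (length(fields) == 1L) {
        stopf("malformed SIF row at line %d: expected 'node relation node'", i)
      }
      if (length(fields) == 2L) {
        stopf("malformed SIF row at line %d: relation with no target node", i)
      }
      src <- fields[[1]]
      targets <- fields[-(1:2)]
      pairs_from <- c(pairs_from, rep(src, length(targets)))
      pairs_to <- c(pairs_to, targets)
    }
  }

  build_interactome(pairs_from, pairs_to, source = path)
}

# Shared constructor: enforces the simple-graph invariants.
build_interactome <- function(from, to, source = "<edges>") {
  loops <- from == to
  if (any(loops)) {
    message(sprintf("dropped %d self-loop row(s) while reading %s",
                    sum(loops), source))
    from <- from[!loops]
    to <- to[!loops]
  }
  if (length(from) == 0L) stopf("no edges remain in %s", source)
  ce <- canonical_edges(from, to)
  key <- paste(ce[, 1L], ce[, 2L], sep = "\t")
  ce <- ce[!duplicated(key), , drop = FALSE]
  nodes <- lex_sort(unique(c(ce[, 1L], ce[, 2L])))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ce[, 1L], to = ce[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = nodes
  )
  g
}

#' Read per-phenotype seed proteins
#'
#' Reads a 2-3 column TSV of `phenotype_id`, `gene` (and optionally
#' `category`). Seeds absent from the interactome are excluded (and reported
#' in a message); duplicated (phenotype, gene) rows are collapsed. Phenotypes
#' left with zero mapped seeds are dropped with a warning.
#'
#' @param path Path to the seed TSV (no header).
#' @param interactome Interactome graph from [read_edge_list()].
#' @param categories Optional path to a 2-column TSV mapping
#'   `phenotype_id` to a category (`CVD`, `CD` or `OS`), used when the seed
#'   file has only two columns.
#' @return A tibble with columns `phenotype_id`, `category`, `protein`,
#'   one row per mapped seed.
#' @export
read_seed_sets <- function(path, interactome, categories = NULL) {
  if (!file.exists(path)) stopf("seed file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (!ncol(raw) %in% c(2L, 3L)) {
    stopf("seed file must have 2 or 3 tab-separated columns, got %d", ncol(raw))
  }
  seeds <- tibble(phenotype_id = raw[[1]], protein = raw[[2]])
  if (ncol(raw) == 3L) {
    seeds$category <- raw[[3]]
  } else {
    if (is.null(categories)) {
      stopf("seed file has no category column and no category map was given")
    }
    cmap <- read_category_map(categories)
    missing <- setdiff(unique(seeds$phenotype_id), names(cmap))
    if (length(missing) > 0L) {
      stopf("phenotype(s) missing from the category map: %s",
            paste(missing, collapse = ", "))
    }
    seeds$category <- unname(cmap[seeds$phenotype_id])
  }
  assert_category(seeds$category)

  nodes <- igraph::V(interactome)$name
  unmapped <- !(seeds$protein %in% nodes)
  if (any(unmapped)) {
    message(sprintf("excluded %d seed(s) absent from the interactome",
                    sum(unmapped)))
  }
  seeds <- seeds[!unmapped, , drop = FALSE]
  seeds <- distinct(seeds, .data$phenotype_id, .data$protein, .keep_all = TRUE)

  empty <- setdiff(unique(raw[[1]]), seeds$phenotype_id)
  if (length(empty) > 0L) {
    warnf("dropped phenotype(s) with zero mapped seeds: %s",
          paste(empty, collapse = ", "))
  }
  seeds |>
    select("phenotype_id", "category", "protein") |>
    arrange(.data$phenotype_id, .data$protein)
}

#' Read a phenotype-to-category map
#'
#' @param path 2-column TSV `phenotype_id`, `category`.
#' @return Named character vector mapping phenotype id to category.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) stopf("category map not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) != 2L) stopf("category map must have 2 columns, got %d", ncol(raw))
  assert_category(raw[[2]])
  stats::setNames(raw[[2]], raw[[1]])
}

#' Keep phenotypes with enough mapped seeds
#'
#' Guilt-by-association scoring is uninformative for phenotypes with a single
#' literature seed, so phenotypes are retained only when their mapped-seed
#' count is at least `min_seeds`. With the default `min_seeds = 2` this is the
#' "more than one seed protein" rule used to select representative
#' subphenotypes.
#'
#' @param seed_sets Seed tibble from [read_seed_sets()].
#' @param min_seeds Minimum mapped-seed count (>= 1).
#' @return The filtered seed tibble, input order preserved.
#' @export
filter_phenotypes_by_seed_count <- function(seed_sets, min_seeds = 2L) {
  stopifnot(min_seeds >= 1L)
  counts <- table(seed_sets$phenotype_id)
  keep <- names(counts)[counts >= min_seeds]
  seed_sets[seed_sets$phenotype_id %in% keep, , drop = FALSE]
}

#' Extract one phenotype's seed proteins as a character vector
#'
#' @param seed_sets Seed tibble.
#' @param phenotype_id Phenotype to extract.
#' @return Character vector of seed proteins (lexicographically sorted).
#' @export
seed_proteins <- function(seed_sets, phenotype_id) {
  s <- seed_sets$protein[seed_sets$phenotype_id == phenotype_id]
  if (length(s) == 0L) stopf("no seeds for phenotype '%s'", phenotype_id)
  lex_sort(unique(s))
}

#' Write a network to SIF, TSV or GraphML
#'
#' TSV and SIF rows are written with the lexicographically smaller endpoint
#' first and sorted, so outputs diff reproducibly. GraphML (via igraph)
#' preserves scalar node attributes; TSV writes the bare edge list.
#'
#' @param network An igraph graph (node attributes must be scalars).
#' @param path Output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stopf("unsupported format: %s",
                                               format[[1]]))
  et <- edge_tibble(network)
  if (format == "tsv") {
    writeLines(paste(et$from, et$to, sep = "\t"), path)
  } else if (format == "sif") {
    writeLines(paste(et$from, "pp", et$to, sep = "\t"), path)
  } else {
    igraph::write_graph(network, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path GraphML file path.
#' @return An igraph graph with its node attributes.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (!is.null(igraph::V(g)$name)) g else g
}

#' Read a gene-set collection in GMT format
#'
#' GMT rows are `set_id<TAB>description<TAB>member1<TAB>member2...`. Member
#' lists are de-duplicated; duplicate set ids are an error.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (`set_id` -> members), with a
#'   `descriptions` attribute carrying the per-set description.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stopf("malformed GMT row at line %d: need set_id, description, >=1 member",
          bad[[1]])
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stopf("duplicate gene-set id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(descs, ids)
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors, optionally with a
#'   `descriptions` attribute.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  rows <- vapply(names(sets), function(id) {
    paste(c(id, descs[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
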