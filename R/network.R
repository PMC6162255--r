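#' Read a protein-protein interaction edge list
#'
#' Tab-delimited `id_a<tab>id_b[<tab>source_db]` rows, as exported from
#' interactome databases (BIND/HPRD/BioGRID/MINT style). Malformed rows
#' (missing endpoints) are skipped with a message.
#'
#' @param path Edge-list path.
#' @return A tibble: `a`, `b`, `source_db`.
#' @export
read_edge_list <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, na = "NA",
                         show_col_types = FALSE)
  if (ncol(raw) < 2) {
    abort("edge list needs at least two columns", class = "mitoamt_input_error")
  }
  edges <- tibble::tibble(a = as.character(raw[[1]]),
                          b = as.character(raw[[2]]),
                          source_db = if (ncol(raw) >= 3)
                            as.character(raw[[3]]) else NA_character_)
  bad <- is.na(edges$a) | is.na(edges$b) | edges$a == "" | edges$b == ""
  if (any(bad)) {
    inform(sprintf("skipped %d malformed edge row(s)", sum(bad)))
    edges <- edges[!bad, ]
  }
  edges
}

#' Assemble the DEP interaction network
#'
#' Seed nodes are DEPs annotated to at least one enriched term; an
#' interactor of a seed is retained only if it is itself a DEP or
#' annotated to one of the selected terms. The induced edges among
#' retained nodes are kept (self-loops dropped, duplicates merged with
#' their provenance tags collapsed), and each node carries its log2 fold
#' change, DEP status and the enriched-term group labels it belongs to
#' ("unassigned" when none).
#'
#' @param proteins Protein results tibble from [dep_test()]
#'   (`protein_id`, `protein_log2fc`, `is_dep`).
#' @param enriched An [enrich_terms()] result (or any tibble with
#'   `term_id`, `term_name`, `significant`); only significant terms are
#'   used for grouping and retention.
#' @param edges Interaction tibble (`a`, `b`, optional `source_db`), e.g.
#'   from [read_edge_list()].
#' @param annotations Annotation tibble (`term_id`, `term_name`, `gene`).
#' @return A `ppi_network` list: `$nodes` (`id`, `log2fc`, `is_dep`,
#'   `groups`), `$edges` (`a`, `b`, `source_db`).
#' @export
build_network <- function(proteins, enriched, edges, annotations) {
  assert_columns(proteins, c("protein_id", "is_dep"), "proteins")
  assert_columns(enriched, c("term_id", "term_name"), "enriched")
  assert_columns(annotations, c("term_id", "term_name", "gene"),
                 "annotations")
  if (!"source_db" %in% names(edges)) edges$source_db <- NA_character_
  assert_columns(edges, c("a", "b"), "edges")

  sel_terms <- if ("significant" %in% names(enriched)) {
    dplyr::filter(enriched, .data$significant)
  } else {
    enriched
  }
  ann_sel <- dplyr::filter(annotations, .data$term_id %in% sel_terms$term_id)

  deps <- proteins$protein_id[proteins$is_dep]
  annotated <- unique(ann_sel$gene)
  seeds <- intersect(deps, annotated)

  # clean edge list: drop self-loops and malformed rows, canonicalize
  ed <- edges |>
    dplyr::filter(!is.na(.data$a), !is.na(.data$b), .data$a != "",
                  .data$b != "", .data$a != .data$b) |>
    dplyr::mutate(lo = pmin(.data$a, .data$b), hi = pmax(.data$a, .data$b))

  touching <- ed$lo %in% seeds | ed$hi %in% seeds
  partners <- unique(c(ed$lo[touching], ed$hi[touching]))
  neighbors <- setdiff(partners, seeds)
  retained <- neighbors[neighbors %in% deps | neighbors %in% annotated]
  candidates <- unique(c(seeds, retained))

  induced <- ed$lo %in% candidates & ed$hi %in% candidates
  # an interaction network: only nodes participating in retained edges
  node_ids <- sort(unique(c(ed$lo[induced], ed$hi[induced])))

  net_edges <- ed[induced, ] |>
    dplyr::group_by(a = .data$lo, b = .data$hi) |>
    dplyr::summarise(source_db = paste(sort(unique(
      .data$source_db[!is.na(.data$source_db)])), collapse = ";"),
      .groups = "drop") |>
    dplyr::mutate(source_db = dplyr::na_if(.data$source_db, "")) |>
    dplyr::arrange(.data$a, .data$b)

  groups <- ann_sel |>
    dplyr::filter(.data$gene %in% node_ids) |>
    dplyr::group_by(id = .data$gene) |>
    dplyr::summarise(groups = paste(sort(unique(.data$term_name)),
                                    collapse = ";"))
  nodes <- tibble::tibble(id = node_ids) |>
    dplyr::left_join(groups, by = "id") |>
    dplyr::mutate(
      groups = dplyr::coalesce(.data$groups, "unassigned"),
      log2fc = if ("protein_log2fc" %in% names(proteins)) {
        proteins$protein_log2fc[match(.data$id, proteins$protein_id)]
      } else {
        NA_real_
      },
      is_dep = .data$id %in% deps) |>
    dplyr::select("id", "log2fc", "is_dep", "groups")

  structure(list(nodes = nodes, edges = net_edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes (%d DEPs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_dep), nrow(x$edges)))
  invisible(x)
}

#' Convert a network model to an igraph object
#'
#' @param x A [build_network()] result.
#' @return An undirected `igraph` graph with node attributes.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "ppi_network"))
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = x$nodes)
}

#' Write a network as SIF plus a node-attribute table
#'
#' @param x A `ppi_network`.
#' @param sif_path Output SIF path (`a<tab>pp<tab>b`).
#' @param nodes_path Output node-attribute TSV path (default: SIF path
#'   with a `.nodes.tsv` suffix).
#' @export
write_sif <- function(x, sif_path,
                      nodes_path = sub("\\.sif$", ".nodes.tsv", sif_path)) {
  stopifnot(inherits(x, "ppi_network"))
  readr::write_tsv(tibble::tibble(a = x$edges$a, interaction = "pp",
                                  b = x$edges$b),
                   sif_path, col_names = FALSE)
  readr::write_tsv(x$nodes, nodes_path, na = "NA")
  invisible(c(sif_path, nodes_path))
}
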