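#' Read gene sets from a GMT file
#'
#' Standard GMT layout: `term_id<tab>description<tab>member1<tab>...`.
#' Lines with fewer than three fields are skipped with a message.
#'
#' @param path GMT file path.
#' @return A long tibble: `term_id`, `term_name`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) {
    inform(sprintf("skipped %d malformed GMT line(s)", sum(bad)))
    fields <- fields[!bad]
  }
  purrr::map_dfr(fields, function(f) {
    tibble::tibble(term_id = f[1], term_name = f[2],
                   gene = unique(f[-(1:2)]))
  })
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term, the one-sided upper-tail hypergeometric probability of
#' observing at least the query/term overlap given the universe
#' (Fisher's exact test for enrichment). `mode = "ease"` applies the
#' EASE-score correction: one is subtracted from the overlap (floored at
#' zero) before the tail computation, a conservative variant of the
#' Fisher statistic. No multiple-testing correction is applied to the
#' significance call (`p <= p_cutoff`); a Storey q-value column is
#' emitted for information only.
#'
#' @param query Character vector of query protein/gene ids (e.g. the up-
#'   or downregulated DEPs); intersected with the universe.
#' @param annotations Annotation tibble (`term_id`, `term_name`, `gene`),
#'   e.g. from [read_gmt()].
#' @param universe Character vector of background ids (the measured
#'   proteome).
#' @param mode `"fisher"` (default) or `"ease"`.
#' @param p_cutoff Significance threshold on the raw p (default 0.05).
#' @return An `enrichment_tbl` tibble sorted by p: `term_id`,
#'   `term_name`, `n_overlap`, `term_size`, `query_size`,
#'   `universe_size`, `p_value`, `q_value`, `significant`.
#' @export
enrich_terms <- function(query, annotations, universe,
                         mode = c("fisher", "ease"), p_cutoff = 0.05) {
  mode <- match.arg(mode)
  assert_columns(annotations, c("term_id", "term_name", "gene"),
                 "annotations")
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query) || !length(universe)) {
    abort("query and universe must be non-empty",
          class = "mitoamt_input_error")
  }
  extra <- setdiff(query, universe)
  if (length(extra)) {
    inform(sprintf("%d query id(s) outside the universe were dropped",
                   length(extra)))
    query <- intersect(query, universe)
  }
  ann <- dplyr::filter(annotations, .data$gene %in% universe)
  N <- length(universe)
  n <- length(query)

  res <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      term_size = dplyr::n_distinct(.data$gene),
      n_overlap = dplyr::n_distinct(intersect(.data$gene, query)),
      .groups = "drop") |>
    dplyr::mutate(
      query_size = n,
      universe_size = N,
      k_eff = if (mode == "ease") pmax(.data$n_overlap - 1L, 0L)
              else .data$n_overlap,
      p_value = phyper(.data$k_eff - 1, .data$term_size,
                       N - .data$term_size, n, lower.tail = FALSE)) |>
    dplyr::select(-"k_eff") |>
    dplyr::arrange(.data$p_value, .data$term_id)

  res$q_value <- if (nrow(res)) storey_fdr(res$p_value) else numeric(0)
  res$significant <- res$p_value <= p_cutoff
  attr(res, "mode") <- mode
  structure(res, class = c("enrichment_tbl", class(res)))
}
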