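ann_tbl <- function(...) {
  sets <- list(...)
  purrr::imap_dfr(sets, function(genes, id)
    tibble::tibble(term_id = id, term_name = paste0("name_", id),
                   gene = genes))
}

test_that("hypergeometric enrichment matches exact combinatorial enumeration", {
  universe <- sprintf("g%02d", 1:20)
  ann <- ann_tbl(T1 = universe[1:5])
  query <- c(universe[1:3], universe[10])  # overlap 3 of term size 5

  res <- enrich_terms(query, ann, universe)
  # (C(5,3) C(15,1) + C(5,4) C(15,0)) / C(20,4) = 155 / 4845
  expect_equal(res$p_value, 155 / 4845, tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.032)
  expect_true(res$significant)

  # zero overlap -> p = 1
  res0 <- enrich_terms(universe[10:12], ann_tbl(T1 = universe[1:5]), universe)
  expect_equal(res0$p_value, 1)

  # term covering the whole universe -> p = 1 regardless of query
  resU <- enrich_terms(universe[1:4], ann_tbl(T1 = universe), universe)
  expect_equal(resU$p_value, 1)

  # randomized agreement with the enumeration oracle, universe <= 25
  set.seed(9)
  for (i in 1:20) {
    N <- sample(8:25, 1)
    uni <- sprintf("u%02d", 1:N)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    term <- sample(uni, K)
    q <- sample(uni, n)
    k <- length(intersect(term, q))
    got <- enrich_terms(q, ann_tbl(TX = term), uni)
    expect_equal(got$p_value, oracle_hyper_tail(N, K, n, k),
                 tolerance = 1e-12)
    expect_equal(got$n_overlap, k)
  }
})

test_that("EASE mode is conservative and overlap is monotone in p", {
  universe <- sprintf("g%02d", 1:20)
  ann <- ann_tbl(T1 = universe[1:6])
  query <- universe[1:5]
  fisher <- enrich_terms(query, ann, universe, mode = "fisher")
  ease <- enrich_terms(query, ann, universe, mode = "ease")
  expect_gt(ease$p_value, fisher$p_value)
  # EASE subtracts one from the overlap before the tail
  expect_equal(ease$p_value,
               oracle_hyper_tail(20, 6, 5, fisher$n_overlap - 1))

  # increasing overlap at fixed sizes never increases p
  ps <- sapply(0:5, function(k) {
    q <- c(universe[seq_len(k)], universe[7:(11 - k)])[1:5]
    enrich_terms(q, ann, universe)$p_value
  })
  expect_true(all(diff(ps) <= 1e-12))

  expect_error(enrich_terms(character(0), ann, universe),
               class = "mitoamt_input_error")
})

test_that("GMT files parse into long annotation tables", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:1\tresp chain\tg1\tg2\tg3",
               "GO:2\ttransport\tg2\tg4",
               "short\tline"), path)
  expect_message(read_gmt(path), "malformed")
  ann <- suppressMessages(read_gmt(path))
  expect_equal(dplyr::n_distinct(ann$term_id), 2)
  expect_equal(sort(ann$gene[ann$term_id == "GO:1"]), c("g1", "g2", "g3"))
  expect_equal(ann$term_name[ann$term_id == "GO:2"][1], "transport")
})

test_that("network assembly keeps seeds and qualifying interactors only", {
  proteins <- tibble::tibble(
    protein_id = c("A", "B", "C", "D", "E", "F"),
    protein_log2fc = c(1, -1, 0.8, NA, NA, NA),
    is_dep = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ann <- ann_tbl(T1 = c("A", "B", "D"), T2 = c("C", "E"))
  enriched <- tibble::tibble(term_id = c("T1", "T2"),
                             term_name = c("name_T1", "name_T2"),
                             significant = TRUE)

  # two seed DEPs with one edge between them
  net2 <- build_network(proteins, enriched,
                        tibble::tibble(a = "A", b = "B"), ann)
  expect_equal(nrow(net2$nodes), 2)
  expect_equal(nrow(net2$edges), 1)

  # a neighbor that is neither a DEP nor annotated is excluded
  edges <- tibble::tibble(a = c("A", "A"), b = c("B", "Z"))
  netz <- build_network(proteins, enriched, edges, ann)
  expect_false("Z" %in% netz$nodes$id)

  # hand-drawn fixture: 6 proteins, 5 edges, 2 terms
  # seeds: A, B (T1-annotated DEPs), C (T2). D: non-DEP but T1-annotated
  # neighbor -> retained. E: non-DEP T2-annotated neighbor -> retained.
  # F: unannotated non-DEP neighbor -> dropped.
  edges6 <- tibble::tibble(a = c("A", "B", "C", "C", "F"),
                           b = c("B", "D", "E", "F", "D"),
                           source_db = c("hprd", "bind", "biogrid",
                                         "mint", "hprd"))
  net6 <- build_network(proteins, enriched, edges6, ann)
  expect_setequal(net6$nodes$id, c("A", "B", "C", "D", "E"))
  expect_equal(nrow(net6$edges), 3)  # A-B, B-D, C-E survive induction
  expect_setequal(paste(net6$edges$a, net6$edges$b),
                  c("A B", "B D", "C E"))
  expect_equal(net6$nodes$groups[net6$nodes$id == "A"], "name_T1")
  expect_equal(net6$nodes$log2fc[net6$nodes$id == "A"], 1)
  expect_false(net6$nodes$is_dep[net6$nodes$id == "D"])

  # invariance to edge order and duplicated/reversed edges
  shuffled <- dplyr::bind_rows(edges6[c(4, 2, 5, 1, 3), ],
                               tibble::tibble(a = "B", b = "A",
                                              source_db = "hprd"))
  net6b <- build_network(proteins, enriched, shuffled, ann)
  expect_equal(net6b$nodes, net6$nodes)
  expect_equal(net6b$edges[c("a", "b")], net6$edges[c("a", "b")])

  # self-loops are never emitted
  loop <- build_network(proteins, enriched,
                        tibble::tibble(a = c("A", "A"), b = c("A", "B")), ann)
  expect_true(all(loop$edges$a != loop$edges$b))

  # igraph conversion and SIF export
  g <- as_igraph(net6)
  expect_equal(igraph::vcount(g), 5)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net6, sif)
  expect_true(file.exists(sif))
  expect_equal(nrow(readr::read_tsv(sif, col_names = FALSE,
                                    show_col_types = FALSE)), 3)
})
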