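#' Tidy a differential-expression fit
#'
#' @param x A [dep_test()] result.
#' @param level `"peptides"` (per-peptide statistics) or `"proteins"`
#'   (DEP calls).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dep_fit <- function(x, level = c("peptides", "proteins"), ...) {
  level <- match.arg(level)
  x[[level]]
}

#' One-row summary of a differential-expression fit
#'
#' @param x A [dep_test()] result.
#' @param ... Unused.
#' @return A one-row tibble: peptide/protein counts, DEP split, the
#'   estimated null proportion and the number of relabelings used.
#' @export
glance.dep_fit <- function(x, ...) {
  deps <- dplyr::filter(x$proteins, .data$is_dep)
  tibble::tibble(
    n_peptides = nrow(x$peptides),
    n_significant_peptides = sum(x$peptides$significant),
    n_proteins = nrow(x$proteins),
    n_deps = nrow(deps),
    n_up = sum(deps$direction == "up"),
    n_down = sum(deps$direction == "down"),
    n_mixed = sum(deps$direction == "mixed"),
    pi0 = x$pi0,
    n_perm_used = x$n_perm_used,
    enumerated = x$enumerated)
}

#' @export
tidy.amt_db <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.amt_db <- function(x, ...) {
  tibble::tibble(n_entries = nrow(x),
                 n_runs = length(attr(x, "provenance")),
                 median_observations = median(x$n_observations))
}

#' @export
tidy.net_calibration <- function(x, ...) {
  x$fits
}

#' Tidy a PPI network model
#'
#' @param x A [build_network()] result.
#' @param level `"nodes"` or `"edges"`.
#' @param ... Unused.
#' @export
tidy.ppi_network <- function(x, level = c("nodes", "edges"), ...) {
  level <- match.arg(level)
  x[[level]]
}

#' @export
glance.ppi_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes),
                 n_deps = sum(x$nodes$is_dep),
                 n_edges = nrow(x$edges))
}
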