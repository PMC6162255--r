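#' Build the peptide x run alignment table
#'
#' Collects assigned UMC intensities into a wide table with one row per
#' peptide and one column per run. When several UMCs in one run carry the
#' same peptide identity their intensities are summed (UMC intensity is
#' itself a sum of component abundances, so summation extends that
#' contract). A peptide absent from a run is missing (`NA`), never zero.
#'
#' @param features Assigned feature tibble (`run_id`, `umc_id`,
#'   `peptide_id`, `intensity`); rows with `peptide_id` NA are ignored.
#' @return A tibble: `peptide_id` column followed by one raw-intensity
#'   column per run (runs in first-appearance order).
#' @export
build_alignment <- function(features) {
  assert_columns(features, c("run_id", "umc_id", "peptide_id", "intensity"),
                 "features")
  if (anyDuplicated(features[c("run_id", "umc_id")])) {
    abort("duplicate (run_id, umc_id) records in input",
          class = "mitoamt_input_integrity")
  }
  run_order <- unique(features$run_id)
  features |>
    dplyr::filter(!is.na(.data$peptide_id)) |>
    dplyr::group_by(.data$peptide_id, .data$run_id) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "run_id", values_from = "intensity") |>
    dplyr::select("peptide_id", dplyr::any_of(run_order)) |>
    dplyr::arrange(.data$peptide_id)
}

#' Quantile-normalize an alignment table on the log2 scale
#'
#' Forces every column to a common empirical distribution (the
#' across-column mean of order statistics) while preserving within-column
#' rank order; ties receive the mean of the quantile values they span.
#' Missing cells stay missing and are excluded from the quantile
#' computation: each column's observed quantiles are interpolated to a
#' shared grid (the `limma::normalizeQuantiles` algorithm with
#' `ties = TRUE`).
#'
#' @param table Alignment tibble from [build_alignment()] (raw
#'   intensities) or any `peptide_id` + numeric-columns tibble.
#' @param log2_transform Take log2 first (default TRUE; set FALSE if the
#'   table is already on the log2 scale).
#' @return The normalized table on the log2 scale.
#' @export
quantile_normalize <- function(table, log2_transform = TRUE) {
  assert_columns(table, "peptide_id", "table")
  mat <- as.matrix(table[-match("peptide_id", names(table))])
  if (ncol(mat) < 2) {
    abort("quantile normalization needs at least 2 columns",
          class = "mitoamt_input_error")
  }
  if (log2_transform) {
    if (any(mat <= 0, na.rm = TRUE)) {
      abort("intensities must be positive for log2 transformation",
            class = "mitoamt_input_error")
    }
    mat <- log2(mat)
  }
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2)) {
    abort(paste0("column(s) with fewer than 2 observed values: ",
                 paste(colnames(mat)[n_obs < 2], collapse = ", ")),
          class = "mitoamt_degenerate_column")
  }
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  out <- tibble::as_tibble(as.data.frame(norm))
  dplyr::bind_cols(table["peptide_id"], out)
}

#' Collapse technical replicates to subject-level abundances
#'
#' Each subject's cell is the mean of that subject's observed replicate
#' log2 values; it is missing only if all replicates are missing. The
#' result is invariant to replicate order.
#'
#' @param table Run-level log2 alignment tibble (`peptide_id` + run
#'   columns).
#' @param samples Sample sheet tibble (`run_id`, `subject_id`, `group`).
#' @return A tibble: `peptide_id` + one column per subject (ordered as in
#'   `samples`).
#' @export
collapse_replicates <- function(table, samples) {
  assert_columns(table, "peptide_id", "table")
  assert_columns(samples, c("run_id", "subject_id"), "samples")
  run_cols <- setdiff(names(table), "peptide_id")
  unmapped <- setdiff(run_cols, samples$run_id)
  if (length(unmapped)) {
    abort(paste0("run column(s) not in the sample sheet: ",
                 paste(unmapped, collapse = ", ")),
          class = "mitoamt_sample_sheet")
  }
  subjects <- unique(samples$subject_id)
  mat <- as.matrix(table[run_cols])
  out <- lapply(subjects, function(s) {
    cols <- intersect(samples$run_id[samples$subject_id == s], run_cols)
    v <- rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  })
  names(out) <- subjects
  dplyr::bind_cols(table["peptide_id"], tibble::as_tibble(out))
}

#' Subject-level metadata from a sample sheet
#'
#' @param samples Sample sheet tibble (`run_id`, `subject_id`, `group`).
#' @return Distinct tibble of `subject_id`, `group`.
#' @export
subject_sheet <- function(samples) {
  assert_columns(samples, c("subject_id", "group"), "samples")
  dplyr::distinct(samples, .data$subject_id, .data$group)
}

#' Write / read an alignment table as TSV ("NA" missing convention)
#'
#' @param table Alignment tibble.
#' @param path TSV path.
#' @export
write_alignment <- function(table, path) {
  readr::write_tsv(table, path, na = "NA")
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE)
}
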