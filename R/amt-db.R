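#' Compute normalized elution times (NET) per run
#'
#' Rescales each run's elution axis (scan number or time) to the unit
#' interval by min-max normalization: `net = (elution - min) / (max - min)`
#' within the run. Elution order is preserved exactly.
#'
#' @param features UMC feature tibble with `run_id` and `elution`.
#' @return The same tibble with a `net` column in `[0, 1]`.
#' @export
#' @examples
#' f <- tibble::tibble(run_id = "r1", umc_id = as.character(1:3),
#'                     mass = 1000, elution = c(100, 200, 300),
#'                     intensity = 1)
#' compute_net(f)$net  # 0.0 0.5 1.0
compute_net <- function(features) {
  assert_columns(features, c("run_id", "elution"), "features")
  degenerate <- features |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(n_distinct_elution = dplyr::n_distinct(.data$elution)) |>
    dplyr::filter(.data$n_distinct_elution < 2)
  if (nrow(degenerate)) {
    abort(paste0("run(s) with fewer than 2 distinct elution values: ",
                 paste(degenerate$run_id, collapse = ", ")),
          class = "mitoamt_degenerate_run")
  }
  features |>
    dplyr::group_by(.data$run_id) |>
    dplyr::mutate(net = (.data$elution - min(.data$elution)) /
                    (max(.data$elution) - min(.data$elution))) |>
    dplyr::ungroup()
}

reference_nets <- function(reference) {
  if (inherits(reference, "amt_db")) {
    tibble::tibble(peptide_id = reference$peptide_id,
                   ref_net = reference$median_net)
  } else {
    assert_columns(reference, c("peptide_id", "net"), "reference")
    reference |>
      dplyr::filter(!is.na(.data$peptide_id)) |>
      dplyr::group_by(.data$peptide_id) |>
      dplyr::summarise(ref_net = median(.data$net))
  }
}

#' Calibrate per-run NETs against a reference
#'
#' Fits, per run, a least-squares affine map from the run's NETs to the
#' reference median NETs using the identified peptides shared with the
#' reference as anchors, with one pass of outlier rejection at
#' |residual| > 3 x residual SD followed by a refit. The fitted map is
#' applied to **all** the run's features (identified or not) and the
#' result is clipped to `[0, 1]`. Runs with fewer than `min_anchors`
#' shared identified peptides raise a classed warning
#' (`mitoamt_calibration_failure`) and are kept uncalibrated, flagged in
#' the fit report.
#'
#' @param features Feature tibble with `run_id`, `peptide_id`, `net`
#'   (from [compute_net()]).
#' @param reference An [build_amt_db()] database, or a pooled tibble of
#'   identified features with `peptide_id` and `net` (median taken per
#'   peptide).
#' @param min_anchors Minimum shared identified peptides per run
#'   (default 3).
#' @return A `net_calibration` list: `$features` (calibrated `net`) and
#'   `$fits` (tibble: `run_id`, `slope`, `intercept`, `residual_sd`,
#'   `n_anchors`, `calibrated`).
#' @export
calibrate_net <- function(features, reference, min_anchors = 3L) {
  assert_columns(features, c("run_id", "peptide_id", "net"), "features")
  ref <- reference_nets(reference)

  runs <- split(features, features$run_id)
  fits <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    anchors <- run |>
      dplyr::filter(!is.na(.data$peptide_id)) |>
      dplyr::inner_join(ref, by = "peptide_id")
    if (nrow(anchors) < min_anchors) {
      warn(sprintf("run '%s': only %d anchor peptide(s) shared with the reference (need >= %d); kept uncalibrated",
                   run$run_id[1], nrow(anchors), min_anchors),
           class = "mitoamt_calibration_failure")
      fits[[i]] <- tibble::tibble(run_id = run$run_id[1], slope = NA_real_,
                                  intercept = NA_real_, residual_sd = NA_real_,
                                  n_anchors = nrow(anchors),
                                  calibrated = FALSE)
      next
    }
    fit <- lm(ref_net ~ net, data = anchors)
    res <- stats::resid(fit)
    s <- sd(res)
    if (is.finite(s) && s > 0) {
      keep <- abs(res) <= 3 * s
      if (sum(keep) >= min_anchors && any(!keep)) {
        fit <- lm(ref_net ~ net, data = anchors[keep, ])
        res <- stats::resid(fit)
      }
    }
    cf <- coef(fit)
    runs[[i]]$net <- pmin(1, pmax(0, cf[1] + cf[2] * run$net))
    fits[[i]] <- tibble::tibble(run_id = run$run_id[1],
                                slope = unname(cf[2]),
                                intercept = unname(cf[1]),
                                residual_sd = sd(res),
                                n_anchors = nrow(anchors),
                                calibrated = TRUE)
  }
  structure(list(features = dplyr::bind_rows(runs),
                 fits = dplyr::bind_rows(fits)),
            class = "net_calibration")
}

#' @export
print.net_calibration <- function(x, ...) {
  cat(sprintf("<net_calibration> %d run(s), %d calibrated\n",
              nrow(x$fits), sum(x$fits$calibrated)))
  print(x$fits)
  invisible(x)
}

#' Compile the master AMT database
#'
#' One entry per distinct identified peptide: the arithmetic mean of its
#' observed monoisotopic masses (`avg_mass`) and the median of its
#' observed calibrated NETs (`median_net`; midpoint of the central pair
#' for even counts), with the number of contributing observations.
#'
#' @param features Identified, NET-calibrated feature tibble
#'   (`peptide_id`, `mass`, `net`, `run_id`). Rows with `peptide_id` NA
#'   are ignored.
#' @param peptide_map Optional tibble (`peptide_id`, `protein_id`) to
#'   attach protein identifiers.
#' @return An `amt_db` tibble: `peptide_id`, `avg_mass`, `median_net`,
#'   `n_observations`, `protein_ids`; attribute `provenance` lists the
#'   contributing run ids.
#' @export
build_amt_db <- function(features, peptide_map = NULL) {
  assert_columns(features, c("run_id", "peptide_id", "mass", "net"),
                 "features")
  identified <- dplyr::filter(features, !is.na(.data$peptide_id))
  if (!nrow(identified)) {
    abort("no identified features: cannot build an AMT database",
          class = "mitoamt_empty_db")
  }
  db <- identified |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::summarise(avg_mass = mean(.data$mass),
                     median_net = median(.data$net),
                     n_observations = dplyr::n()) |>
    dplyr::arrange(.data$peptide_id)
  db$protein_ids <- if (!is.null(peptide_map)) {
    assert_columns(peptide_map, c("peptide_id", "protein_id"), "peptide_map")
    pm <- peptide_map |>
      dplyr::group_by(.data$peptide_id) |>
      dplyr::summarise(protein_ids = paste(sort(unique(.data$protein_id)),
                                           collapse = ";"))
    pm$protein_ids[match(db$peptide_id, pm$peptide_id)]
  } else {
    NA_character_
  }
  structure(db, class = c("amt_db", class(db)),
            provenance = sort(unique(identified$run_id)))
}

#' Build a drift-calibrated AMT database (two-pass workflow)
#'
#' The standard database-construction workflow: per-run NETs are computed
#' by min-max normalization, a first-pass database provides reference
#' median NETs, every run is affine-calibrated against it, and the
#' database is recompiled once from the calibrated NETs.
#'
#' @inheritParams build_amt_db
#' @param min_anchors Passed to [calibrate_net()].
#' @return A list: `$db` (the calibrated `amt_db`), `$features`
#'   (calibrated features for all runs), `$fits` (calibration report).
#' @export
build_calibrated_amt_db <- function(features, peptide_map = NULL,
                                    min_anchors = 3L) {
  feats <- compute_net(features)
  db0 <- build_amt_db(feats, peptide_map)
  cal <- calibrate_net(feats, db0, min_anchors = min_anchors)
  list(db = build_amt_db(cal$features, peptide_map),
       features = cal$features,
       fits = cal$fits)
}

#' @export
print.amt_db <- function(x, ...) {
  cat(sprintf("<amt_db> %d AMT entries from %d run(s)\n", nrow(x),
              length(attr(x, "provenance"))))
  NextMethod()
}

#' Write / read an AMT database as TSV
#'
#' @param db An `amt_db`.
#' @param path Output TSV path.
#' @return `write_amt_db` invisibly returns `path`; `read_amt_db` returns
#'   an `amt_db` tibble.
#' @export
write_amt_db <- function(db, path) {
  stopifnot(inherits(db, "amt_db"))
  readr::write_tsv(tibble::as_tibble(db), path, na = "NA")
  invisible(path)
}

#' @rdname write_amt_db
#' @export
read_amt_db <- function(path) {
  db <- readr::read_tsv(path, na = "NA", show_col_types = FALSE)
  assert_columns(db, c("peptide_id", "avg_mass", "median_net",
                       "n_observations"), "AMT database")
  structure(db, class = c("amt_db", class(db)), provenance = character(0))
}
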