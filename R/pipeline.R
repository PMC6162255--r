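#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Input features
#' come either from the synthetic generator (`generator` settings) or
#' from per-run TSV files (`run_paths` + `samples_path`). All referenced
#' paths are checked at validation time, before any stage runs.
#'
#' @param generator List of [generate_ground_truth()] arguments
#'   (`n_proteins`, `peptides_per_protein`, `de_fraction`,
#'   `fold_change_range`) for synthetic mode; `NULL` for external input.
#' @param run_paths,samples_path External per-run feature TSVs and sample
#'   sheet (ignored in synthetic mode).
#' @param design A [cohort_design()] (synthetic mode).
#' @param noise A [noise_model()] (synthetic mode; its seed is derived
#'   from the pipeline seed).
#' @param tolerances A [match_tolerances()].
#' @param filter A [filter_config()].
#' @param test A [test_config()] (its seed is derived from the pipeline
#'   seed).
#' @param enrich_mode `"fisher"` or `"ease"`.
#' @param annotations Annotation tibble or GMT path, or `NULL` to skip
#'   enrichment/network stages.
#' @param edges Interaction tibble or edge-list path, or `NULL` to skip
#'   the network stage.
#' @param drop_ambiguous Passed to [assign_peptides()].
#' @param outdir Directory for intermediate artifacts, or `NULL` to keep
#'   everything in memory.
#' @param seed Single global seed; per-stage seeds are derived from it
#'   with [derive_seed()] so stages can be re-run in isolation.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(generator = list(n_proteins = 100),
                            run_paths = NULL, samples_path = NULL,
                            design = cohort_design(),
                            noise = noise_model(),
                            tolerances = match_tolerances(),
                            filter = filter_config(),
                            test = test_config(),
                            enrich_mode = c("fisher", "ease"),
                            annotations = NULL, edges = NULL,
                            drop_ambiguous = FALSE,
                            outdir = NULL, seed = 1L) {
  enrich_mode <- match.arg(enrich_mode)
  if (is.null(generator)) {
    if (is.null(run_paths) || !length(run_paths)) {
      abort("external mode requires `run_paths`",
            class = "mitoamt_config_error")
    }
    if (is.null(samples_path)) {
      abort("external mode requires `samples_path` (sample sheet)",
            class = "mitoamt_config_error")
    }
    missing <- c(run_paths, samples_path)
    missing <- missing[!file.exists(missing)]
    if (length(missing)) {
      abort(paste0("input path(s) not found: ",
                   paste(missing, collapse = ", ")),
            class = "mitoamt_config_error")
    }
  }
  for (p in c(if (is.character(annotations)) annotations,
              if (is.character(edges)) edges)) {
    if (!file.exists(p)) {
      abort(paste0("input path not found: ", p),
            class = "mitoamt_config_error")
    }
  }
  structure(list(generator = generator, run_paths = run_paths,
                 samples_path = samples_path, design = design,
                 noise = noise, tolerances = tolerances, filter = filter,
                 test = test, enrich_mode = enrich_mode,
                 annotations = annotations, edges = edges,
                 drop_ambiguous = drop_ambiguous,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_record <- function(stage, n_in, n_out, seed = NA_integer_) {
  tibble::tibble(stage = stage, n_in = n_in, n_out = n_out, seed = seed)
}

#' Run the full AMT differential-expression pipeline
#'
#' Executes simulate/ingest, NET calibration + AMT database construction
#' (two-pass), AMT peptide assignment, alignment + quantile normalization
#' + replicate collapsing, the composite permutation test with protein
#' rollup, and (when annotations/edges are configured) enrichment and
#' network assembly. A single global seed deterministically derives every
#' stage seed, so re-running an identical config reproduces identical
#' results.
#'
#' @param cfg A [pipeline_config()].
#' @return A `mitoamt_manifest` list: `$stages` (per-stage in/out counts
#'   and seeds), `$assignment_summary`, `$fit` (the `dep_fit`),
#'   `$enrichment` (list `up`/`down` or NULL), `$network`, `$recovery`
#'   (DEP recovery vs the planted truth, synthetic mode only),
#'   `$outputs` (paths written), `$config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- list()
  outputs <- character(0)
  emit <- function(name, obj, writer) {
    if (!is.null(cfg$outdir)) {
      dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(cfg$outdir, name)
      writer(obj, path)
      outputs <<- c(outputs, path)
    }
  }

  # -- stage 1: simulate or ingest ------------------------------------
  cohort <- NULL
  if (!is.null(cfg$generator)) {
    sim_seed <- derive_seed(cfg$seed, "simulate")
    truth <- do.call(generate_ground_truth,
                     c(cfg$generator, list(seed = sim_seed)))
    noise <- cfg$noise
    noise$seed <- derive_seed(cfg$seed, "noise")
    cohort <- simulate_cohort(truth, cfg$design, noise)
    features <- cohort$features
    samples <- cohort$samples
    peptide_map <- truth$peptides[c("peptide_id", "protein_id")]
    stages$simulate <- stage_record("simulate", nrow(truth$peptides),
                                    nrow(features), sim_seed)
  } else {
    features <- read_umc_runs(cfg$run_paths)
    samples <- readr::read_tsv(cfg$samples_path, na = "NA",
                               show_col_types = FALSE)
    peptide_map <- NULL
    stages$ingest <- stage_record("ingest", length(cfg$run_paths),
                                  nrow(features))
  }
  emit("samples.tsv", samples, function(x, p) readr::write_tsv(x, p, na = "NA"))

  # -- stage 2: NET calibration + AMT DB (two-pass) -------------------
  dbres <- build_calibrated_amt_db(features, peptide_map)
  stages$build_db <- stage_record("build_db", nrow(features),
                                  nrow(dbres$db))
  emit("amt_db.tsv", dbres$db, write_amt_db)

  # -- stage 3: AMT assignment ----------------------------------------
  assigned <- assign_peptides(dbres$features, dbres$db, cfg$tolerances,
                              drop_ambiguous = cfg$drop_ambiguous)
  asum <- attr(assigned, "summary")
  stages$assign <- stage_record("assign", nrow(assigned),
                                asum$n_with_id)
  emit("assignments.tsv", assigned,
       function(x, p) readr::write_tsv(tibble::as_tibble(x), p, na = "NA"))

  # -- stage 4: align + normalize + collapse --------------------------
  aligned <- build_alignment(assigned)
  normed <- quantile_normalize(aligned)
  subject_tbl <- collapse_replicates(normed, samples)
  stages$align <- stage_record("align", nrow(assigned), nrow(subject_tbl))
  emit("aligned_subjects.tsv", subject_tbl, write_alignment)

  # -- stage 5: composite test + rollup -------------------------------
  if (is.null(peptide_map)) {
    abort("external mode requires a peptide-to-protein map; none ingested",
          class = "mitoamt_config_error")
  }
  subjects <- subject_sheet(samples)
  test_cfg <- cfg$test
  test_cfg$seed <- derive_seed(cfg$seed, "test")
  fit <- dep_test(subject_tbl, subjects, peptide_map,
                  filter = cfg$filter, test = test_cfg)
  stages$test <- stage_record("test", nrow(subject_tbl),
                              nrow(fit$peptides), test_cfg$seed)
  emit("peptide_results.tsv", fit$peptides,
       function(x, p) readr::write_tsv(x, p, na = "NA"))
  emit("protein_results.tsv", fit$proteins,
       function(x, p) readr::write_tsv(x, p, na = "NA"))

  # -- stage 6/7: enrichment + network --------------------------------
  enrichment <- NULL
  network <- NULL
  if (!is.null(cfg$annotations)) {
    ann <- if (is.character(cfg$annotations)) read_gmt(cfg$annotations)
           else cfg$annotations
    universe <- unique(fit$proteins$protein_id)
    up <- fit$proteins$protein_id[fit$proteins$is_dep &
                                    fit$proteins$direction %in% "up"]
    down <- fit$proteins$protein_id[fit$proteins$is_dep &
                                      fit$proteins$direction %in% "down"]
    enrichment <- list(
      up = if (length(up)) enrich_terms(up, ann, universe,
                                        mode = cfg$enrich_mode) else NULL,
      down = if (length(down)) enrich_terms(down, ann, universe,
                                            mode = cfg$enrich_mode) else NULL)
    n_terms <- sum(vapply(enrichment, function(e)
      if (is.null(e)) 0L else sum(e$significant), 0L))
    stages$enrich <- stage_record("enrich", length(c(up, down)), n_terms)

    if (!is.null(cfg$edges)) {
      ed <- if (is.character(cfg$edges)) read_edge_list(cfg$edges)
            else cfg$edges
      enr_all <- dplyr::bind_rows(enrichment$up, enrichment$down)
      network <- build_network(fit$proteins, enr_all, ed, ann)
      stages$network <- stage_record("network", nrow(ed),
                                     nrow(network$nodes))
      emit("network.sif", network, function(x, p) write_sif(x, p))
    }
  }

  # -- recovery vs planted truth (synthetic mode) ---------------------
  recovery <- NULL
  if (!is.null(cohort)) {
    recovery <- score_recovery(fit, cohort$de_proteins)
  }

  structure(list(stages = dplyr::bind_rows(stages),
                 assignment_summary = asum,
                 calibration = dbres$fits,
                 fit = fit, enrichment = enrichment, network = network,
                 recovery = recovery, outputs = outputs, config = cfg),
            class = "mitoamt_manifest")
}

#' Score DEP recovery against planted truth
#'
#' @param fit A [dep_test()] result.
#' @param de_proteins Planted DE proteins tibble (`protein_id`,
#'   `log2fc`).
#' @return One-row tibble: `n_planted`, `n_recovered`,
#'   `n_correct_direction`, `recovery_rate`, `n_false_deps`.
#' @export
score_recovery <- function(fit, de_proteins) {
  called <- dplyr::filter(fit$proteins, .data$is_dep)
  hit <- dplyr::inner_join(called, de_proteins, by = "protein_id")
  tibble::tibble(
    n_planted = nrow(de_proteins),
    n_recovered = nrow(hit),
    n_correct_direction = sum(
      (hit$direction == "up" & hit$log2fc > 0) |
        (hit$direction == "down" & hit$log2fc < 0)),
    recovery_rate = if (nrow(de_proteins)) nrow(hit) / nrow(de_proteins)
                    else NA_real_,
    n_false_deps = sum(!called$protein_id %in% de_proteins$protein_id))
}

#' @export
print.mitoamt_manifest <- function(x, ...) {
  cat("<mitoamt_manifest>\n")
  print(x$stages)
  invisible(x)
}

#' Human- and machine-readable run summary
#'
#' Dataset-level counts of the completed run: peptides tested, proteins,
#' DEPs and their up/down/mixed split (`n_deps = n_up + n_down +
#' n_mixed`), with percentages to one decimal.
#'
#' @param x A `mitoamt_manifest` from [run_pipeline()] or a `dep_fit`.
#' @return A one-row tibble of counts and percentages.
#' @export
report_summary <- function(x) {
  fit <- if (inherits(x, "mitoamt_manifest")) x$fit
         else if (inherits(x, "dep_fit")) x
         else abort("report_summary needs a manifest or dep_fit",
                    class = "mitoamt_report_error")
  if (is.null(fit)) {
    abort("incomplete manifest: no test results",
          class = "mitoamt_report_error")
  }
  deps <- dplyr::filter(fit$proteins, .data$is_dep)
  dep_counts(n_up = sum(deps$direction == "up"),
             n_down = sum(deps$direction == "down"),
             n_mixed = sum(deps$direction == "mixed"),
             n_peptides = nrow(fit$peptides),
             n_significant_peptides = sum(fit$peptides$significant),
             n_proteins = nrow(fit$proteins))
}

#' DEP count bookkeeping
#'
#' The reporting arithmetic used in run summaries:
#' `n_deps = n_up + n_down + n_mixed`, with up/down percentages of the
#' DEP total computed to one decimal (zero-safe).
#'
#' @param n_up,n_down,n_mixed DEP counts by direction.
#' @param n_peptides,n_significant_peptides,n_proteins Optional
#'   dataset-level counts carried through.
#' @return A one-row tibble.
#' @export
#' @examples
#' dep_counts(135, 200)  # n_deps 335
dep_counts <- function(n_up, n_down, n_mixed = 0L, n_peptides = NA_integer_,
                       n_significant_peptides = NA_integer_,
                       n_proteins = NA_integer_) {
  n_deps <- n_up + n_down + n_mixed
  tibble::tibble(
    n_peptides = n_peptides,
    n_significant_peptides = n_significant_peptides,
    n_proteins = n_proteins,
    n_deps = n_deps, n_up = n_up, n_down = n_down, n_mixed = n_mixed,
    pct_up = fraction_pct(n_up, n_deps),
    pct_down = fraction_pct(n_down, n_deps))
}

#' Percentage to one decimal
#'
#' `round(100 * n / total, 1)`; returns 0 for an empty total rather than
#' dividing by zero.
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @return The percentage rounded to one decimal place.
#' @export
#' @examples
#' fraction_pct(455, 1150)  # 39.6
fraction_pct <- function(n, total) {
  ifelse(total > 0, round(100 * n / total, 1), 0)
}
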