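#' Generate a ground-truth peptide/protein population
#'
#' Creates the hidden truth for a synthetic label-free LC-MS study: a set
#' of proteins, each represented by several tryptic peptides with a
#' theoretical monoisotopic mass, a true normalized elution time (NET) and
#' a baseline log2 abundance, plus a planted subset of differentially
#' expressed (DE) proteins carrying a signed log2 fold change. All sibling
#' peptides of a DE protein share its fold change, so peptide-level calls
#' can be rolled up and scored against the truth.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param peptides_per_protein Integer range `c(min, max)`; each protein's
#'   peptide count is drawn uniformly from this range.
#' @param de_fraction Fraction of proteins planted as DE; exactly
#'   `round(de_fraction * n_proteins)` proteins receive a nonzero fold
#'   change.
#' @param fold_change_range Linear fold-change interval `c(lo, hi)` with
#'   `lo >= 1.5`; planted magnitudes are uniform on this interval, signs
#'   are random, so every planted `|log2 fold change| >= log2(1.5)`.
#' @param seed Integer seed; identical seeds give identical truth.
#' @return A `ground_truth` object: list with `$peptides` (tibble:
#'   `peptide_id`, `protein_id`, `theo_mass`, `true_net`, `base_log2`) and
#'   `$proteins` (tibble: `protein_id`, `log2fc`, `is_de`).
#' @export
#' @examples
#' truth <- generate_ground_truth(20, de_fraction = 0.2, seed = 1)
#' sum(truth$proteins$is_de)
generate_ground_truth <- function(n_proteins,
                                  peptides_per_protein = c(3L, 8L),
                                  de_fraction = 0.15,
                                  fold_change_range = c(1.5, 2.5),
                                  seed = 1L) {
  assert_scalar_number(n_proteins, "n_proteins", lower = 1)
  assert_scalar_number(de_fraction, "de_fraction", lower = 0, upper = 1)
  if (length(peptides_per_protein) != 2L ||
      any(peptides_per_protein < 1) ||
      peptides_per_protein[1] > peptides_per_protein[2]) {
    abort("`peptides_per_protein` must be an increasing range of counts >= 1",
          class = "mitoamt_config_error")
  }
  if (length(fold_change_range) != 2L ||
      fold_change_range[1] < 1.5 ||
      fold_change_range[1] > fold_change_range[2]) {
    abort("`fold_change_range` must be increasing with lower bound >= 1.5",
          class = "mitoamt_config_error")
  }
  n_proteins <- as.integer(n_proteins)

  with_seed(seed, {
    protein_id <- sprintf("PROT%04d", seq_len(n_proteins))
    pep_range <- seq(peptides_per_protein[1], peptides_per_protein[2])
    n_pep <- pep_range[sample.int(length(pep_range), n_proteins,
                                  replace = TRUE)]
    n_total <- sum(n_pep)

    peptides <- tibble::tibble(
      peptide_id = sprintf("PEP%05d", seq_len(n_total)),
      protein_id = rep(protein_id, n_pep),
      theo_mass  = runif(n_total, 800, 3500),
      true_net   = runif(n_total, 0, 1),
      base_log2  = rnorm(n_total, 23, 2)
    )

    n_de <- round(de_fraction * n_proteins)
    de_idx <- if (n_de > 0) sample.int(n_proteins, n_de) else integer(0)
    log2fc <- numeric(n_proteins)
    if (n_de > 0) {
      mag <- log2(runif(n_de, fold_change_range[1], fold_change_range[2]))
      log2fc[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    }
    proteins <- tibble::tibble(protein_id = protein_id,
                               log2fc = log2fc,
                               is_de = log2fc != 0)

    structure(list(peptides = peptides, proteins = proteins,
                   seed = as.integer(seed)),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d proteins, %d peptides, %d planted DE\n",
              nrow(x$proteins), nrow(x$peptides), sum(x$proteins$is_de)))
  invisible(x)
}

#' Two-group cohort design
#'
#' @param n_per_group Subjects per group (default 9, a 9 vs 9 cohort).
#' @param n_replicates Technical replicate LC-MS runs per subject
#'   (default 3).
#' @param groups Length-2 character vector of group labels; the first is
#'   the "case" group whose positive fold changes mean upregulation.
#' @return A `cohort_design` list with a `$subjects` tibble
#'   (`subject_id`, `group`).
#' @export
cohort_design <- function(n_per_group = 9L, n_replicates = 3L,
                          groups = c("T2DM", "control")) {
  assert_scalar_number(n_per_group, "n_per_group", lower = 2)
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  stopifnot(is.character(groups), length(groups) == 2L,
            !anyDuplicated(groups))
  n_per_group <- as.integer(n_per_group)
  subjects <- tibble::tibble(
    subject_id = paste0(rep(make.names(groups), each = n_per_group), "_",
                        sprintf("%02d", rep(seq_len(n_per_group), 2L))),
    group = rep(groups, each = n_per_group)
  )
  structure(list(n_per_group = n_per_group,
                 n_replicates = as.integer(n_replicates),
                 groups = groups, subjects = subjects),
            class = "cohort_design")
}

#' Measurement-noise model for simulated LC-MS runs
#'
#' Bundles every stochastic element of a simulated run: mass accuracy,
#' run-specific affine elution drift, NET jitter, intensity noise, the
#' MS/MS identification (undersampling) rate, and intensity-dependent
#' dropout.
#'
#' @param mass_error_ppm_sd SD of the relative mass error in ppm.
#' @param net_drift_slope_sd Lognormal SD of the run-specific elution
#'   slope (multiplicative, around `net_drift_slope_mean`).
#' @param net_drift_intercept_sd SD of the run-specific elution intercept,
#'   expressed as a fraction of the slope (NET units).
#' @param net_noise_sd SD of per-feature elution jitter on the NET scale.
#' @param log2_intensity_sd SD of per-feature log2 intensity noise.
#' @param id_rate Probability that a feature carries its MS/MS peptide
#'   identity (the undersampling rate; default 0.104, i.e. about 10.4% of
#'   features identified per run).
#' @param dropout_midpoint True log2 intensity at which detection
#'   probability is 50%.
#' @param dropout_steepness Slope of the logistic detection curve;
#'   `0` disables dropout entirely.
#' @param net_drift_slope_mean,net_drift_intercept_mean Baseline affine
#'   map from true NET to scan units (elution = a + b * (net + jitter)).
#' @param seed Integer seed; per-run streams are derived from it.
#' @return A validated `noise_model` list.
#' @export
noise_model <- function(mass_error_ppm_sd = 3,
                        net_drift_slope_sd = 0.1,
                        net_drift_intercept_sd = 0.02,
                        net_noise_sd = 0.005,
                        log2_intensity_sd = 0.5,
                        id_rate = 0.104,
                        dropout_midpoint = 19,
                        dropout_steepness = 0.8,
                        net_drift_slope_mean = 2000,
                        net_drift_intercept_mean = 500,
                        seed = 1L) {
  assert_scalar_number(mass_error_ppm_sd, "mass_error_ppm_sd", lower = 0)
  assert_scalar_number(net_drift_slope_sd, "net_drift_slope_sd", lower = 0)
  assert_scalar_number(net_drift_intercept_sd, "net_drift_intercept_sd",
                       lower = 0)
  assert_scalar_number(net_noise_sd, "net_noise_sd", lower = 0)
  assert_scalar_number(log2_intensity_sd, "log2_intensity_sd", lower = 0)
  assert_scalar_number(id_rate, "id_rate", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(dropout_steepness, "dropout_steepness", lower = 0)
  assert_scalar_number(dropout_midpoint, "dropout_midpoint")
  structure(list(mass_error_ppm_sd = mass_error_ppm_sd,
                 net_drift_slope_sd = net_drift_slope_sd,
                 net_drift_intercept_sd = net_drift_intercept_sd,
                 net_noise_sd = net_noise_sd,
                 log2_intensity_sd = log2_intensity_sd,
                 id_rate = id_rate,
                 dropout_midpoint = dropout_midpoint,
                 dropout_steepness = dropout_steepness,
                 net_drift_slope_mean = net_drift_slope_mean,
                 net_drift_intercept_mean = net_drift_intercept_mean,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate one LC-MS run of UMC features
#'
#' Emits one unique-mass-class (UMC) feature per detected peptide:
#' observed mass = theoretical * (1 + eps/1e6) with ppm-scale error,
#' elution = a + b * (true NET + jitter) under a run-specific affine
#' drift, and a log-normal intensity around the baseline abundance plus
#' the subject group's planted fold change. Each feature carries its
#' MS/MS peptide identity with probability `id_rate` (undersampling);
#' low-abundance features are dropped by a logistic detection curve.
#'
#' The returned table keeps the hidden truth in `true_peptide_id`; run
#' tables fed to the analysis stages must not use it (see
#' [simulate_cohort()], which strips it into the manifest).
#'
#' @param truth A [generate_ground_truth()] object.
#' @param subject_id Subject identifier.
#' @param group Group label of the subject (first design group = "case").
#' @param replicate Replicate index.
#' @param noise A [noise_model()].
#' @param design Optional [cohort_design()]; when given, `subject_id`
#'   must belong to it.
#' @return A tibble with columns `run_id`, `umc_id`, `mass`, `elution`,
#'   `intensity`, `charge`, `peptide_id` (NA when unidentified),
#'   `true_peptide_id`.
#' @export
simulate_run <- function(truth, subject_id, group, replicate,
                         noise = noise_model(), design = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_model"))
  if (!is.null(design) && !subject_id %in% design$subjects$subject_id) {
    abort(sprintf("subject '%s' is not part of the cohort design", subject_id),
          class = "mitoamt_design_error")
  }
  case_group <- if (!is.null(design)) design$groups[1] else "T2DM"
  run_id <- paste0(subject_id, "_r", replicate)

  pep <- truth$peptides
  lfc <- truth$proteins$log2fc[match(pep$protein_id,
                                     truth$proteins$protein_id)]
  effect <- if (identical(group, case_group)) lfc else 0

  with_seed(derive_seed(noise$seed, run_id), {
    true_log2 <- pep$base_log2 + effect

    keep <- if (noise$dropout_steepness > 0) {
      runif(nrow(pep)) < plogis(noise$dropout_steepness *
                                  (true_log2 - noise$dropout_midpoint))
    } else {
      rep(TRUE, nrow(pep))
    }

    # run-specific affine elution drift (scan units)
    b <- noise$net_drift_slope_mean *
      exp(rnorm(1, 0, noise$net_drift_slope_sd))
    a <- noise$net_drift_intercept_mean +
      noise$net_drift_slope_mean * rnorm(1, 0, noise$net_drift_intercept_sd)

    n <- nrow(pep)
    eps_ppm <- rnorm(n, 0, noise$mass_error_ppm_sd)
    elution <- a + b * (pep$true_net + rnorm(n, 0, noise$net_noise_sd))
    log2_int <- true_log2 + rnorm(n, 0, noise$log2_intensity_sd)
    identified <- runif(n) < noise$id_rate
    charge <- sample(2:3, n, replace = TRUE, prob = c(0.7, 0.3))

    out <- tibble::tibble(
      run_id = run_id,
      umc_id = sprintf("%s_umc%05d", run_id, seq_len(n)),
      mass = pep$theo_mass * (1 + eps_ppm / 1e6),
      elution = elution,
      intensity = 2 ^ log2_int,
      charge = charge,
      peptide_id = ifelse(identified, pep$peptide_id, NA_character_),
      true_peptide_id = pep$peptide_id
    )
    out[keep, ]
  })
}

#' Simulate a full two-group cohort of LC-MS runs
#'
#' Runs [simulate_run()] for every subject x replicate in the design
#' (54 runs for the default 9 vs 9 x 3 design) and splits the output into
#' the analyst-visible feature tables and a hidden truth manifest used
#' only for scoring.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param design A [cohort_design()].
#' @param noise A [noise_model()].
#' @return A `umc_cohort` list: `$features` (all runs, no truth column),
#'   `$samples` (run_id, subject_id, group, replicate), `$manifest`
#'   (run_id, umc_id, true_peptide_id, true_protein_id), `$de_proteins`
#'   (planted DE proteins with their log2 fold changes), `$truth`.
#' @export
#' @examples
#' truth <- generate_ground_truth(10, seed = 1)
#' cohort <- simulate_cohort(truth, cohort_design(2, 1))
#' dplyr::n_distinct(cohort$features$run_id)  # 4 runs
simulate_cohort <- function(truth, design = cohort_design(),
                            noise = noise_model()) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(design, "cohort_design"))
  grid <- tidyr::expand_grid(design$subjects,
                             replicate = seq_len(design$n_replicates))
  runs <- purrr::pmap(grid, function(subject_id, group, replicate) {
    simulate_run(truth, subject_id, group, replicate, noise, design)
  })
  all_feat <- dplyr::bind_rows(runs)

  samples <- grid |>
    dplyr::mutate(run_id = paste0(.data$subject_id, "_r", .data$replicate)) |>
    dplyr::select("run_id", "subject_id", "group", "replicate")

  manifest <- all_feat |>
    dplyr::select("run_id", "umc_id", "true_peptide_id") |>
    dplyr::mutate(true_protein_id = truth$peptides$protein_id[
      match(.data$true_peptide_id, truth$peptides$peptide_id)])

  structure(list(
    features = dplyr::select(all_feat, -"true_peptide_id"),
    samples = samples,
    manifest = manifest,
    de_proteins = dplyr::filter(truth$proteins, .data$is_de),
    truth = truth
  ), class = "umc_cohort")
}

#' @export
print.umc_cohort <- function(x, ...) {
  cat(sprintf(
    "<umc_cohort> %d runs, %d subjects, %d features (%.1f%% identified)\n",
    dplyr::n_distinct(x$samples$run_id),
    dplyr::n_distinct(x$samples$subject_id),
    nrow(x$features),
    100 * mean(!is.na(x$features$peptide_id))))
  invisible(x)
}

#' Write a simulated cohort to tab-delimited fixture files
#'
#' One TSV per run (`<run_id>.tsv`), a `samples.tsv` sample sheet and a
#' `manifest.tsv` truth manifest, all with "NA" for missing values.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "umc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_run <- split(cohort$features, cohort$features$run_id)
  paths <- purrr::imap_chr(by_run, function(df, rid) {
    p <- file.path(dir, paste0(rid, ".tsv"))
    readr::write_tsv(df, p, na = "NA")
    p
  })
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"), na = "NA")
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"), na = "NA")
  invisible(c(paths, file.path(dir, c("samples.tsv", "manifest.tsv"))))
}

#' Read per-run UMC feature tables
#'
#' @param paths TSV paths as written by [write_cohort()] (columns
#'   `run_id`, `umc_id`, `mass` or `monoisotopic_mass_da`, `elution` or
#'   `elution_scan`, `intensity`, optional `charge`, `peptide_id`).
#' @return One tibble of features across runs.
#' @export
read_umc_runs <- function(paths) {
  feats <- purrr::map(paths, readr::read_tsv, na = "NA",
                      show_col_types = FALSE) |>
    dplyr::bind_rows()
  nm <- names(feats)
  nm[nm == "monoisotopic_mass_da"] <- "mass"
  nm[nm == "elution_scan"] <- "elution"
  names(feats) <- nm
  assert_columns(feats, c("run_id", "umc_id", "mass", "elution", "intensity"),
                 "run tables")
  if (!"peptide_id" %in% names(feats)) feats$peptide_id <- NA_character_
  feats
}
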