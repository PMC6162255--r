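#' Peptide filtering configuration
#'
#' @param min_sibling_peptides Minimum distinct peptides a protein must
#'   retain for its peptides to be kept (default 2, i.e. proteins with
#'   two or more sibling peptides).
#' @param min_detect_fraction Peptides must be detected in strictly more
#'   than this fraction of subjects in *each* group (default 0.5: more
#'   than 50% of subjects per group, i.e. >= 5 of 9).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_sibling_peptides = 2L,
                          min_detect_fraction = 0.5) {
  assert_scalar_number(min_sibling_peptides, "min_sibling_peptides", lower = 1)
  if (!is.numeric(min_detect_fraction) || min_detect_fraction < 0 ||
      min_detect_fraction >= 1) {
    abort("`min_detect_fraction` must be in [0, 1)",
          class = "mitoamt_config_error")
  }
  structure(list(min_sibling_peptides = as.integer(min_sibling_peptides),
                 min_detect_fraction = min_detect_fraction),
            class = "filter_config")
}

#' Composite-test configuration
#'
#' @param n_permutations Number of balanced group relabelings for the
#'   empirical null (minimum 100; exhaustive enumeration is used
#'   automatically when fewer distinct relabelings exist).
#' @param seed Seed for the relabeling sample.
#' @param fdr_threshold Storey q-value cutoff (default 0.1).
#' @param fold_threshold Linear fold-change cutoff (default 1.5), applied
#'   two-sided as `|log2 median ratio| >= log2(fold_threshold)`.
#' @param storey_lambda Tuning parameter for the null-proportion estimate
#'   (default 0.5).
#' @return A `test_config` list.
#' @export
test_config <- function(n_permutations = 1000L, seed = 1L,
                        fdr_threshold = 0.1, fold_threshold = 1.5,
                        storey_lambda = 0.5) {
  assert_scalar_number(n_permutations, "n_permutations", lower = 100)
  assert_scalar_number(fdr_threshold, "fdr_threshold", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (fdr_threshold >= 1) {
    abort("`fdr_threshold` must be in (0, 1)", class = "mitoamt_config_error")
  }
  assert_scalar_number(fold_threshold, "fold_threshold", lower = 1)
  assert_scalar_number(storey_lambda, "storey_lambda", lower = 0, upper = 1,
                       strict_lower = TRUE)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 fdr_threshold = fdr_threshold,
                 fold_threshold = fold_threshold,
                 storey_lambda = storey_lambda),
            class = "test_config")
}

#' Filter peptides for statistical power
#'
#' Retains peptides that (a) are detected in strictly more than
#' `min_detect_fraction` of subjects in each group and (b) belong to
#' proteins with at least `min_sibling_peptides` distinct retained
#' peptides; protein membership is recomputed after the detection filter
#' and iterated until stable.
#'
#' @param table Subject-level log2 alignment tibble (`peptide_id` +
#'   subject columns).
#' @param peptide_map Tibble (`peptide_id`, `protein_id`); unique mapping
#'   assumed.
#' @param subjects Tibble (`subject_id`, `group`), e.g.
#'   [subject_sheet()].
#' @param cfg A [filter_config()].
#' @return The filtered alignment tibble; a classed warning
#'   (`mitoamt_all_filtered`) if nothing survives.
#' @export
filter_peptides <- function(table, peptide_map, subjects,
                            cfg = filter_config()) {
  assert_columns(table, "peptide_id", "table")
  assert_columns(peptide_map, c("peptide_id", "protein_id"), "peptide_map")
  assert_columns(subjects, c("subject_id", "group"), "subjects")

  groups <- unique(subjects$group)
  detected <- rep(TRUE, nrow(table))
  for (g in groups) {
    cols <- intersect(subjects$subject_id[subjects$group == g], names(table))
    frac <- rowMeans(!is.na(as.matrix(table[cols])))
    detected <- detected & frac > cfg$min_detect_fraction
  }
  kept <- table[detected, ]

  prot <- peptide_map$protein_id[match(kept$peptide_id,
                                       peptide_map$peptide_id)]
  repeat {
    counts <- table(prot)
    ok <- !is.na(prot) & counts[prot] >= cfg$min_sibling_peptides
    if (all(ok)) break
    kept <- kept[ok, ]
    prot <- prot[ok]
    if (!nrow(kept)) break
  }
  if (!nrow(kept)) {
    warn("all peptides removed by filtering", class = "mitoamt_all_filtered")
  }
  kept
}

#' Pooled-variance Student t statistic
#'
#' Two-sample t on observed log2 values with the pooled variance
#' estimate. The sign convention is positive when the first group (the
#' case group) is higher. Zero pooled variance gives `t = 0` when the
#' means are equal and signed infinity otherwise.
#'
#' @param x,y Numeric log2 abundances for group 1 (case) and group 2;
#'   NAs dropped; at least 2 observed values per group.
#' @return The t statistic.
#' @export
#' @examples
#' t_statistic(c(1, 2, 3), c(4, 5, 6))  # -3.6742
t_statistic <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("t_statistic needs >= 2 observed values per group",
          class = "mitoamt_input_error")
  }
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  d <- mean(x) - mean(y)
  if (sp2 <= 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Log2-median ratio
#'
#' Difference of group medians on the log2 scale:
#' `median(x) - median(y)` over observed values (inputs are log2
#' abundances).
#'
#' @param x,y Numeric log2 abundances; NAs dropped; at least 1 observed
#'   value per group.
#' @return The log2-median ratio (positive: higher in the case group).
#' @export
#' @examples
#' log2_median_ratio(log2(c(8, 8, 32)), log2(c(4, 4, 4)))  # 1
log2_median_ratio <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    abort("log2_median_ratio needs >= 1 observed value per group",
          class = "mitoamt_input_error")
  }
  median(x) - median(y)
}

# Distinct balanced relabelings of n subjects into groups of size k and
# n - k, as 1-based group-1 column index rows. When the groups have equal
# size, a labeling and its complement define the same partition and are
# deduplicated (canonical form contains column 1). The identity labeling
# (the observed grouping, given by `identity_idx`) is excluded.
balanced_relabelings <- function(n, k, identity_idx, B, seed) {
  equal <- (2L * k == n)
  canonical <- function(s) {
    if (equal && !(1L %in% s)) sort(setdiff(seq_len(n), s)) else sort(s)
  }
  id_key <- paste(canonical(identity_idx), collapse = ",")
  n_total <- choose(n, k) / (if (equal) 2 else 1)
  n_avail <- n_total - 1  # identity excluded

  if (n_avail <= B) {
    combs <- combn(n, k)
    keys <- character(0)
    rows <- list()
    for (j in seq_len(ncol(combs))) {
      s <- canonical(combs[, j])
      key <- paste(s, collapse = ",")
      if (key == id_key || key %in% keys) next
      keys <- c(keys, key)
      rows[[length(rows) + 1L]] <- s
    }
    mat <- do.call(rbind, rows)
    return(list(assignments = mat, enumerated = TRUE, n_used = nrow(mat)))
  }

  with_seed(seed, {
    seen <- character(0)
    rows <- list()
    while (length(rows) < B) {
      need <- B - length(rows)
      for (d in seq_len(max(2L * need, 10L))) {
        s <- canonical(sample.int(n, k))
        key <- paste(s, collapse = ",")
        if (key == id_key || key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- s
        if (length(rows) == B) break
      }
    }
    list(assignments = do.call(rbind, rows), enumerated = FALSE, n_used = B)
  })
}

# Pooled empirical-null p-values: two-sided via absolute values,
# p_i = (1 + #{|null| >= |obs_i|}) / (1 + N_null).
pooled_null_p <- function(observed, null_values) {
  nv <- abs(null_values[!is.na(null_values)])
  nv <- sort(nv)
  n_null <- length(nv)
  obs <- abs(observed)
  cnt <- n_null - findInterval(obs, nv, left.open = TRUE)
  p <- (1 + cnt) / (1 + n_null)
  p[is.na(observed)] <- NA_real_
  p
}

# Core permutation engine: observed and null t / ratio statistics plus
# pooled-null adjusted p-values for a subject-level table.
perm_engine <- function(table, subjects, cfg) {
  subj <- intersect(subjects$subject_id, setdiff(names(table), "peptide_id"))
  if (!length(subj)) {
    abort("no subject columns found in table", class = "mitoamt_input_error")
  }
  groups <- unique(subjects$group[match(subj, subjects$subject_id)])
  if (length(groups) != 2) {
    abort("exactly two groups are required", class = "mitoamt_input_error")
  }
  g <- subjects$group[match(subj, subjects$subject_id)]
  g1 <- which(g == groups[1])
  if (length(g1) < 2 || sum(g == groups[2]) < 2) {
    abort("both groups need >= 2 subjects", class = "mitoamt_input_error")
  }
  mat <- as.matrix(table[subj])
  rownames(mat) <- table$peptide_id

  obs <- perm_stats_cpp(mat, matrix(as.integer(g1), nrow = 1))
  rel <- balanced_relabelings(length(subj), length(g1), g1,
                              cfg$n_permutations, cfg$seed)
  if (rel$n_used < cfg$n_permutations) {
    inform(sprintf(
      "only %d distinct balanced relabelings available (%d requested); using all of them",
      rel$n_used, cfg$n_permutations))
  }
  null <- perm_stats_cpp(mat, matrix(as.integer(rel$assignments),
                                     nrow = nrow(rel$assignments)))
  list(
    peptide_id = table$peptide_id,
    t = drop(obs$t), ratio = drop(obs$ratio),
    p_t = pooled_null_p(drop(obs$t), null$t),
    p_ratio = pooled_null_p(drop(obs$ratio), null$ratio),
    null_t = as.numeric(null$t), null_ratio = as.numeric(null$ratio),
    n_perm_used = rel$n_used, enumerated = rel$enumerated,
    case_group = groups[1]
  )
}

#' Permutation empirical null for one statistic
#'
#' Permutes group labels over balanced relabelings (sampled without
#' replacement from the distinct relabelings, identity excluded;
#' exhaustive when few exist), recomputes the statistic for every
#' peptide in every relabeling, pools the null values across peptides
#' and permutations, and returns two-sided adjusted p-values
#' `p_i = (1 + #\{|null| >= |obs_i|\}) / (1 + N_null)`.
#'
#' @param table Subject-level log2 alignment tibble.
#' @param subjects Tibble (`subject_id`, `group`).
#' @param statistic `"t"` (pooled-variance Student t) or `"ratio"`
#'   (log2-median ratio).
#' @param cfg A [test_config()].
#' @return A list: `$results` tibble (`peptide_id`, `observed`, `p`),
#'   `$null` (pooled null values), `$n_perm_used`, `$enumerated`.
#' @export
permutation_null <- function(table, subjects, statistic = c("t", "ratio"),
                             cfg = test_config()) {
  statistic <- match.arg(statistic)
  eng <- perm_engine(table, subjects, cfg)
  if (statistic == "t") {
    res <- tibble::tibble(peptide_id = eng$peptide_id, observed = eng$t,
                          p = eng$p_t)
    null <- eng$null_t
  } else {
    res <- tibble::tibble(peptide_id = eng$peptide_id, observed = eng$ratio,
                          p = eng$p_ratio)
    null <- eng$null_ratio
  }
  list(results = res, null = null, n_perm_used = eng$n_perm_used,
       enumerated = eng$enumerated)
}

#' Combine two signed p-values with Stouffer's method
#'
#' Each two-sided p is mapped to a signed normal score
#' `z_i = sign_i * qnorm(1 - p_i / 2)`, the scores are averaged as
#' `z_c = (z_t + z_ratio) / sqrt(2)`, and a two-sided combined p is
#' reconstructed: `p = 2 * (1 - pnorm(|z_c|))`, clamped into (0, 1].
#' Concordant signs reinforce; exactly opposed equal evidence cancels to
#' `p = 1`.
#'
#' @param p_t,p_ratio Two-sided adjusted p-values in (0, 1]; zeros are
#'   clamped to the smallest positive double with a warning.
#' @param sign_t,sign_ratio Directions (+1 / -1; 0 allowed).
#' @return Combined two-sided p-values.
#' @export
#' @examples
#' stouffer_combine(0.05, 1, 0.05, 1)  # ~0.0056
stouffer_combine <- function(p_t, sign_t, p_ratio, sign_ratio) {
  clamp <- function(p, name) {
    if (any(p <= 0, na.rm = TRUE)) {
      warn(sprintf("%s contains p <= 0; clamped to the machine minimum", name),
           class = "mitoamt_p_clamped")
      p[!is.na(p) & p <= 0] <- .Machine$double.xmin
    }
    p
  }
  p_t <- clamp(p_t, "p_t")
  p_ratio <- clamp(p_ratio, "p_ratio")
  z1 <- sign(sign_t) * qnorm(1 - p_t / 2)
  z2 <- sign(sign_ratio) * qnorm(1 - p_ratio / 2)
  zc <- (z1 + z2) / sqrt(2)
  p <- 2 * pnorm(abs(zc), lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) * m))` and converts
#' p-values to q-values by the step-down rule
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, clamped into (0, 1].
#'
#' @param p P-values in (0, 1].
#' @param lambda Null-proportion tuning parameter (default 0.5).
#' @return Q-values in the original order, monotone nondecreasing in p.
#' @export
storey_fdr <- function(p, lambda = 0.5) {
  stopifnot(length(p) >= 1)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]", class = "mitoamt_input_error")
  }
  assert_scalar_number(lambda, "lambda", lower = 0, upper = 1,
                       strict_lower = TRUE)
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  o <- order(p)
  q_sorted <- rev(cummin(rev(pi0 * m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- q_sorted
  pmin(1, pmax(q, .Machine$double.xmin))
}

#' Roll peptide-level calls up to proteins
#'
#' A peptide is significant iff `q <= fdr_threshold` **and**
#' `|log2 median ratio| >= log2(fold_threshold)`; a protein is a
#' differentially expressed protein (DEP) iff it has at least one
#' significant sibling peptide. The protein log2 fold change is the
#' median of its significant siblings' ratios (all siblings when none is
#' significant), and the direction is `up`/`down` by sign, `mixed` when
#' significant siblings disagree in sign.
#'
#' @param results Peptide results tibble with `peptide_id`,
#'   `log2_median_ratio`, `q_value` (as produced by [dep_test()]).
#' @param peptide_map Tibble (`peptide_id`, `protein_id`).
#' @param cfg A [test_config()].
#' @return Protein tibble: `protein_id`, `n_sibling_peptides`,
#'   `n_significant_peptides`, `protein_log2fc`, `direction`, `is_dep`.
#' @export
select_and_rollup <- function(results, peptide_map, cfg = test_config()) {
  assert_columns(results, c("peptide_id", "log2_median_ratio", "q_value"),
                 "results")
  res <- results
  if (!"significant" %in% names(res)) {
    res$significant <- !is.na(res$q_value) &
      res$q_value <= cfg$fdr_threshold &
      abs(res$log2_median_ratio) >= log2(cfg$fold_threshold)
  }
  res$protein_id <- peptide_map$protein_id[match(res$peptide_id,
                                                 peptide_map$peptide_id)]
  res |>
    dplyr::filter(!is.na(.data$protein_id)) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_sibling_peptides = dplyr::n(),
      n_significant_peptides = sum(.data$significant),
      protein_log2fc = if (any(.data$significant)) {
        median(.data$log2_median_ratio[.data$significant])
      } else {
        median(.data$log2_median_ratio)
      },
      direction = {
        s <- sign(.data$log2_median_ratio[.data$significant])
        if (!length(s)) NA_character_
        else if (all(s > 0)) "up"
        else if (all(s < 0)) "down"
        else "mixed"
      },
      .groups = "drop") |>
    dplyr::mutate(is_dep = .data$n_significant_peptides >= 1L)
}

#' Composite permutation test for differential expression
#'
#' The full peptide-level testing stage: filter for statistical power,
#' compute pooled-variance Student t and log2-median ratio per peptide,
#' derive two-sided adjusted p-values for both from pooled permutation
#' nulls, combine them with signed Stouffer weighting, convert to Storey
#' q-values, call significant peptides at `q <= fdr_threshold` and
#' `|ratio| >= log2(fold_threshold)`, and roll up to proteins.
#'
#' @param table Subject-level log2 alignment tibble (`peptide_id` +
#'   subject columns).
#' @param subjects Tibble (`subject_id`, `group`); the first group in
#'   column order is the case group (positive = up in case).
#' @param peptide_map Tibble (`peptide_id`, `protein_id`).
#' @param filter A [filter_config()].
#' @param test A [test_config()].
#' @return A `dep_fit` object: `$peptides` (per-peptide statistics, p's,
#'   q, significance), `$proteins` (DEP calls), `$n_perm_used`,
#'   `$enumerated`, `$pi0`, `$config`.
#' @export
dep_test <- function(table, subjects, peptide_map,
                     filter = filter_config(), test = test_config()) {
  filtered <- filter_peptides(table, peptide_map, subjects, filter)
  if (!nrow(filtered)) {
    abort("no peptides left after filtering", class = "mitoamt_all_filtered")
  }
  eng <- perm_engine(filtered, subjects, test)
  p_comb <- stouffer_combine(eng$p_t, sign(eng$t), eng$p_ratio,
                             sign(eng$ratio))
  q <- storey_fdr(p_comb, test$storey_lambda)
  m <- length(p_comb)
  pi0 <- min(1, sum(p_comb > test$storey_lambda) /
               ((1 - test$storey_lambda) * m))

  peptides <- tibble::tibble(
    peptide_id = eng$peptide_id,
    protein_id = peptide_map$protein_id[match(eng$peptide_id,
                                              peptide_map$peptide_id)],
    t_value = eng$t,
    log2_median_ratio = eng$ratio,
    p_t = eng$p_t,
    p_ratio = eng$p_ratio,
    p_combined = p_comb,
    q_value = q,
    significant = !is.na(q) & q <= test$fdr_threshold &
      abs(eng$ratio) >= log2(test$fold_threshold)
  )
  proteins <- select_and_rollup(peptides, peptide_map, test)

  structure(list(peptides = peptides, proteins = proteins,
                 n_perm_used = eng$n_perm_used, enumerated = eng$enumerated,
                 pi0 = pi0, case_group = eng$case_group,
                 config = list(filter = filter, test = test)),
            class = "dep_fit")
}

#' @export
print.dep_fit <- function(x, ...) {
  cat(sprintf(
    "<dep_fit> %d peptides tested (%d significant), %d proteins (%d DEPs); %d relabelings%s\n",
    nrow(x$peptides), sum(x$peptides$significant), nrow(x$proteins),
    sum(x$proteins$is_dep), x$n_perm_used,
    if (x$enumerated) " (exhaustive)" else ""))
  invisible(x)
}
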