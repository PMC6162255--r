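test_that("pooled-variance t and log2-median ratio match hand computation", {
  expect_equal(t_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  # pooled sd = 1, se = sqrt(2/3): t = -3 / 0.8165 = -3.6742
  expect_equal(t_statistic(c(1, 2, 3), c(4, 5, 6)), -3 / sqrt(2 / 3),
               tolerance = 1e-9)
  expect_equal(round(t_statistic(c(1, 2, 3), c(4, 5, 6)), 4), -3.6742)
  # antisymmetry
  expect_equal(t_statistic(c(4, 5, 6), c(1, 2, 3)),
               -t_statistic(c(1, 2, 3), c(4, 5, 6)))
  # zero pooled variance
  expect_equal(t_statistic(c(2, 2), c(2, 2)), 0)
  expect_equal(t_statistic(c(3, 3), c(2, 2)), Inf)
  expect_error(t_statistic(1, c(1, 2)), class = "mitoamt_input_error")

  expect_equal(log2_median_ratio(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_equal(log2_median_ratio(log2(c(8, 8, 32)), log2(c(4, 4, 4))), 1)
  expect_equal(log2_median_ratio(log2(c(2, 4, 8)), log2(c(1, 2, 4))), 1)
})

test_that("detection and sibling filters follow the cohort rules", {
  subjects <- two_group_subjects(9, 9)
  t2dm <- subjects$subject_id[1:9]
  ctrl <- subjects$subject_id[10:18]
  pmap <- tibble::tibble(peptide_id = c("a1", "a2", "a3", "b1", "c1", "c2"),
                         protein_id = c("A", "A", "A", "B", "C", "C"))
  full <- matrix(1, nrow = 6, ncol = 18,
                 dimnames = list(NULL, subjects$subject_id))
  # a3: detected in only 4 of 9 T2DM subjects -> removed (needs >= 5)
  full[3, t2dm[5:9]] <- NA
  tab <- make_subject_table(full, pmap$peptide_id)

  kept <- filter_peptides(tab, pmap, subjects)
  # a1, a2 survive (protein A keeps 2 siblings); b1 is a lone peptide;
  # c1, c2 survive fully detected
  expect_setequal(kept$peptide_id, c("a1", "a2", "c1", "c2"))

  # 5 of 9 per group is strictly more than 50% -> retained
  m2 <- matrix(1, nrow = 2, ncol = 18,
               dimnames = list(NULL, subjects$subject_id))
  m2[1, c(t2dm[6:9])] <- NA  # 5/9 T2DM, 9/9 control
  tab2 <- make_subject_table(m2, c("c1", "c2"))
  kept2 <- filter_peptides(tab2, pmap, subjects)
  expect_setequal(kept2$peptide_id, c("c1", "c2"))

  # everything filtered -> classed warning, empty result
  lonely <- make_subject_table(matrix(1, 1, 18,
                                      dimnames = list(NULL, subjects$subject_id)),
                               "b1")
  expect_warning(none <- filter_peptides(lonely, pmap, subjects),
                 class = "mitoamt_all_filtered")
  expect_equal(nrow(none), 0)
})

test_that("permutation p-values equal full enumeration on a tiny design", {
  set.seed(4)
  mat <- matrix(rnorm(12), nrow = 2,
                dimnames = list(NULL, sprintf("S%02d", 1:6)))
  mat[1, 1:3] <- mat[1, 1:3] + 3  # one shifted peptide
  tab <- make_subject_table(mat)
  subjects <- two_group_subjects(3, 3)
  cfg <- test_config(n_permutations = 100, seed = 1)

  for (stat in c("t", "ratio")) {
    fun <- if (stat == "t") oracle_t else oracle_ratio
    got <- suppressMessages(permutation_null(tab, subjects, stat, cfg))
    oracle <- oracle_perm_p(mat, 1:3, fun)
    expect_equal(got$results$observed, oracle$observed, tolerance = 1e-12)
    expect_equal(got$results$p, oracle$p, tolerance = 1e-12)
    expect_equal(length(got$null), oracle$n_null)
    expect_true(got$enumerated)
  }
})

test_that("permutation p-values hit the boundary and center correctly", {
  # observed far beyond every null value -> p = 1 / (N_null + 1)
  mat <- matrix(c(100, 101, 102, 0, 1, 2), nrow = 1,
                dimnames = list(NULL, sprintf("S%02d", 1:6)))
  tab <- make_subject_table(mat, "pep01")
  subjects <- two_group_subjects(3, 3)
  got <- suppressMessages(
    permutation_null(tab, subjects, "t", test_config(n_permutations = 100)))
  expect_equal(got$results$p, 1 / (length(got$null) + 1))

  # observed 0 on a symmetric null -> p = 1
  mat0 <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 1,
                 dimnames = list(NULL, sprintf("S%02d", 1:6)))
  got0 <- suppressMessages(
    permutation_null(make_subject_table(mat0, "pep01"), subjects, "ratio",
                     test_config(n_permutations = 100)))
  expect_equal(got0$results$observed, 0)
  expect_equal(got0$results$p, 1)

  # reproducibility under a fixed seed at sampled (non-enumerated) scale
  subjects18 <- two_group_subjects(9, 9)
  set.seed(8)
  big <- make_subject_table(matrix(rnorm(5 * 18), nrow = 5,
                                   dimnames = list(NULL, subjects18$subject_id)))
  p1 <- permutation_null(big, subjects18, "t", test_config(200, seed = 3))
  p2 <- permutation_null(big, subjects18, "t", test_config(200, seed = 3))
  expect_identical(p1$results, p2$results)
  expect_false(p1$enumerated)
  expect_equal(p1$n_perm_used, 200)
  # p-values live in [1/(N+1), 1]
  expect_true(all(p1$results$p >= 1 / (length(p1$null) + 1)))
  expect_true(all(p1$results$p <= 1))
})

test_that("Stouffer combination reproduces the normal-CDF oracle", {
  # p = 0.5 each, same sign: z = qnorm(0.75), z_c = 2 z / sqrt(2)
  z <- qnorm(0.75)
  expect_equal(stouffer_combine(0.5, 1, 0.5, 1),
               2 * (1 - pnorm(2 * z / sqrt(2))), tolerance = 1e-12)
  expect_equal(stouffer_combine(0.5, 1, 0.5, 1), 0.3401482, tolerance = 1e-6)

  # p = 0.05 each, same sign
  z5 <- qnorm(1 - 0.05 / 2)
  expect_equal(stouffer_combine(0.05, 1, 0.05, 1),
               2 * (1 - pnorm(2 * z5 / sqrt(2))), tolerance = 1e-12)
  expect_equal(stouffer_combine(0.05, 1, 0.05, 1), 0.0055746, tolerance = 1e-5)

  # equal evidence with opposite signs cancels
  expect_equal(stouffer_combine(0.05, 1, 0.05, -1), 1)

  # monotone nonincreasing in each p at fixed concordant signs
  ps <- seq(0.01, 0.99, by = 0.01)
  comb <- stouffer_combine(ps, 1, 0.2, 1)
  expect_true(all(diff(comb) >= 0))

  # p = 0 is clamped with a classed warning
  expect_warning(out <- stouffer_combine(0, 1, 0.5, 1),
                 class = "mitoamt_p_clamped")
  expect_true(out > 0 && out <= 1)
})

test_that("Storey q-values equal the brute-force step-down computation", {
  expect_equal(storey_fdr(rep(1, 5)), rep(1, 5))

  p4 <- c(0.01, 0.02, 0.8, 0.9)
  expect_equal(storey_fdr(p4), oracle_storey(p4))
  expect_equal(storey_fdr(p4)[1:2], c(0.04, 0.04))

  set.seed(5)
  for (i in 1:10) {
    m <- sample(1:20, 1)
    p <- runif(m)
    q <- storey_fdr(p)
    expect_equal(q, oracle_storey(p), tolerance = 1e-12)
    # q monotone nondecreasing in p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q > 0 & q <= 1))
  }

  # uniform null p-values give pi0 near 1
  set.seed(6)
  p <- runif(1e4)
  m <- length(p)
  pi0 <- min(1, sum(p > 0.5) / (0.5 * m))
  expect_gte(pi0, 0.9)
  expect_lte(pi0, 1.0)

  expect_error(storey_fdr(c(0.5, 0)), class = "mitoamt_input_error")
})

test_that("protein rollup applies the conjunction rule and direction logic", {
  pmap <- tibble::tibble(peptide_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
                         protein_id = c("A", "A", "B", "B", "C", "C"))
  res <- tibble::tibble(
    peptide_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    log2_median_ratio = c(1.2, 0.2, 1.0, -0.9, 0.3, 0.1),
    q_value = c(0.05, 0.5, 0.02, 0.03, 0.09, 0.9))
  prot <- select_and_rollup(res, pmap)

  a <- prot[prot$protein_id == "A", ]
  expect_true(a$is_dep)
  expect_equal(a$direction, "up")
  expect_equal(a$protein_log2fc, 1.2)  # median of significant siblings

  b <- prot[prot$protein_id == "B", ]
  expect_true(b$is_dep)
  expect_equal(b$direction, "mixed")   # significant siblings disagree

  # q = 0.09 passes FDR but |ratio| = 0.3 < log2(1.5): not significant
  c_ <- prot[prot$protein_id == "C", ]
  expect_false(c_$is_dep)
  expect_true(is.na(c_$direction))
  expect_equal(c_$protein_log2fc, 0.2)  # median of all siblings
})

test_that("the composite test recovers a strong planted signal end to end", {
  subjects <- two_group_subjects(4, 4)
  set.seed(7)
  mat <- matrix(rnorm(20 * 8, 20, 0.3), nrow = 20,
                dimnames = list(NULL, subjects$subject_id))
  mat[1:2, 1:4] <- mat[1:2, 1:4] + 2  # protein P01 strongly up in cases
  peps <- sprintf("pep%02d", 1:20)
  pmap <- tibble::tibble(peptide_id = peps,
                         protein_id = rep(sprintf("P%02d", 1:10), each = 2))
  fit <- suppressMessages(
    dep_test(make_subject_table(mat, peps), subjects, pmap,
             test = test_config(n_permutations = 100, seed = 2)))
  expect_true(fit$proteins$is_dep[fit$proteins$protein_id == "P01"])
  expect_equal(fit$proteins$direction[fit$proteins$protein_id == "P01"], "up")
  expect_s3_class(glance(fit), "tbl_df")
  expect_identical(tidy(fit, "proteins"), fit$proteins)
})
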