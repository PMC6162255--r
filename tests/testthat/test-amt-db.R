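make_features <- function(run_id, elution, peptide_id = NA_character_,
                          mass = 1000, intensity = 1) {
  tibble::tibble(run_id = run_id,
                 umc_id = paste0(run_id, "_", seq_along(elution)),
                 mass = mass, elution = elution, intensity = intensity,
                 peptide_id = peptide_id)
}

test_that("compute_net rescales each run to [0, 1] preserving order", {
  f <- make_features("r1", c(100, 200, 300))
  expect_equal(compute_net(f)$net, c(0, 0.5, 1))

  expect_error(compute_net(make_features("r1", c(5, 5))),
               class = "mitoamt_degenerate_run")

  # property: min 0, max 1, strictly monotone in elution
  set.seed(1)
  for (i in 1:5) {
    e <- sample(1:1000, 50)
    net <- compute_net(make_features("rX", e))$net
    expect_equal(min(net), 0)
    expect_equal(max(net), 1)
    expect_identical(order(net), order(e))
  }
})

test_that("affine NET drift is inverted exactly on noiseless anchors", {
  ref_net <- seq(0.05, 0.95, by = 0.05)
  peps <- sprintf("p%02d", seq_along(ref_net))
  ref <- tibble::tibble(peptide_id = peps, net = ref_net, run_id = "ref",
                        mass = 1000 + seq_along(ref_net))

  # identity: features already on the reference scale are unchanged
  run0 <- tibble::tibble(run_id = "runA", peptide_id = peps, net = ref_net,
                         mass = 1000 + seq_along(ref_net))
  cal0 <- calibrate_net(run0, ref)
  expect_equal(cal0$fits$slope, 1, tolerance = 1e-9)
  expect_equal(cal0$fits$intercept, 0, tolerance = 1e-9)
  expect_equal(cal0$features$net, ref_net, tolerance = 1e-12)

  # run nets = 0.5 * reference + 0.1 -> recovered slope 2.0 on inversion
  run1 <- dplyr::mutate(run0, run_id = "runB", net = 0.5 * ref_net + 0.1)
  cal1 <- calibrate_net(run1, ref)
  expect_equal(cal1$fits$slope, 2, tolerance = 1e-9)
  expect_equal(cal1$fits$intercept, -0.2, tolerance = 1e-9)
  expect_lt(max(abs(cal1$features$net - ref_net)), 1e-9)

  # the fitted map applies to unidentified features too
  run2 <- dplyr::bind_rows(
    run1,
    tibble::tibble(run_id = "runB", peptide_id = NA, net = 0.35, mass = 500))
  cal2 <- calibrate_net(run2, ref)
  expect_equal(cal2$features$net[nrow(cal2$features)],
               -0.2 + 2 * 0.35, tolerance = 1e-9)

  # one anchor pair only -> calibration failure, run kept uncalibrated
  run3 <- run0[1, ]
  expect_warning(cal3 <- calibrate_net(run3, ref),
                 class = "mitoamt_calibration_failure")
  expect_false(cal3$fits$calibrated)
  expect_equal(cal3$features$net, run3$net)
})

test_that("outlier anchors are rejected once before the refit", {
  ref_net <- seq(0.05, 0.95, by = 0.05)
  peps <- sprintf("p%02d", seq_along(ref_net))
  ref <- tibble::tibble(peptide_id = peps, net = ref_net, run_id = "ref")
  run <- tibble::tibble(run_id = "r", peptide_id = peps, net = ref_net,
                        mass = 1000)
  run$net[10] <- run$net[10] + 0.4  # one gross mismatch
  cal <- calibrate_net(run, ref)
  expect_equal(cal$fits$slope, 1, tolerance = 1e-6)
  expect_equal(cal$fits$intercept, 0, tolerance = 1e-6)
})

test_that("AMT entries record average mass and median NET", {
  f <- tibble::tibble(
    run_id = c("r1", "r2", "r1", "r2", "r3", "r1"),
    umc_id = as.character(1:6),
    peptide_id = c("a", "a", "b", "b", "b", "c"),
    mass = c(1000.0000, 1000.0020, 500, 500, 500, 800),
    net = c(0.5, 0.6, 0.10, 0.20, 0.40, 0.33),
    intensity = 1)
  db <- build_amt_db(f)
  expect_equal(db$avg_mass[db$peptide_id == "a"], 1000.0010)
  expect_equal(db$median_net[db$peptide_id == "b"], 0.20)
  # even count -> midpoint of the central pair
  expect_equal(db$median_net[db$peptide_id == "a"], 0.55)
  # singleton entry equals its only observation
  expect_equal(db$n_observations[db$peptide_id == "c"], 1L)
  expect_equal(db$avg_mass[db$peptide_id == "c"], 800)
  expect_equal(db$median_net[db$peptide_id == "c"], 0.33)

  expect_error(build_amt_db(dplyr::mutate(f, peptide_id = NA_character_)),
               class = "mitoamt_empty_db")
})

test_that("database construction is idempotent and matches brute force", {
  set.seed(2)
  n <- 100
  f <- tibble::tibble(
    run_id = sample(paste0("r", 1:5), n, replace = TRUE),
    umc_id = as.character(seq_len(n)),
    peptide_id = sample(sprintf("p%02d", 1:20), n, replace = TRUE),
    mass = runif(n, 800, 3000),
    net = runif(n),
    intensity = runif(n))
  db1 <- build_amt_db(f)
  db2 <- build_amt_db(f)
  expect_identical(tibble::as_tibble(db1), tibble::as_tibble(db2))

  # brute-force recomputation per peptide
  for (p in unique(f$peptide_id)) {
    obs <- f[f$peptide_id == p, ]
    i <- match(p, db1$peptide_id)
    expect_equal(db1$avg_mass[i], sum(obs$mass) / nrow(obs),
                 tolerance = 1e-9)
    expect_equal(db1$median_net[i], sort(obs$net)[ceiling(nrow(obs) / 2)] /
                   2 + sort(obs$net)[floor(nrow(obs) / 2 + 1)] / 2,
                 tolerance = 1e-9)
    # entry invariants
    expect_gte(db1$avg_mass[i], min(obs$mass))
    expect_lte(db1$avg_mass[i], max(obs$mass))
    expect_gte(db1$median_net[i], min(obs$net))
    expect_lte(db1$median_net[i], max(obs$net))
  }
})

test_that("AMT databases round-trip through TSV", {
  f <- tibble::tibble(run_id = "r1", umc_id = as.character(1:3),
                      peptide_id = c("a", "a", "b"),
                      mass = c(1000, 1000.002, 750), net = c(0.4, 0.5, 0.9),
                      intensity = 1)
  db <- build_amt_db(f, peptide_map = tibble::tibble(
    peptide_id = c("a", "b"), protein_id = c("P1", "P2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_amt_db(db, path)
  back <- read_amt_db(path)
  expect_equal(back$avg_mass, db$avg_mass)
  expect_equal(back$median_net, db$median_net)
  expect_equal(back$protein_ids, db$protein_ids)
})
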