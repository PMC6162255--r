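# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals.

# Exhaustive pairwise AMT matching: for every feature, scan every DB
# entry, apply both tolerance gates, pick the minimal scaled distance.
oracle_match_bruteforce <- function(mass, net, db, mass_ppm = 10,
                                    net_tol = 0.025) {
  out <- data.frame(matched_peptide_id = rep(NA_character_, length(mass)),
                    n_candidates = 0L, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mass)) {
    best <- Inf; best_pep <- NA_character_; k <- 0L
    for (j in seq_len(nrow(db))) {
      dppm <- 1e6 * (mass[i] - db$avg_mass[j]) / db$avg_mass[j]
      dnet <- net[i] - db$median_net[j]
      if (abs(dppm) > mass_ppm || abs(dnet) > net_tol) next
      k <- k + 1L
      d <- sqrt((dppm / mass_ppm)^2 + (dnet / net_tol)^2)
      if (d < best || (d == best && db$peptide_id[j] < best_pep)) {
        best <- d; best_pep <- db$peptide_id[j]
      }
    }
    out$matched_peptide_id[i] <- best_pep
    out$n_candidates[i] <- k
    out$ambiguous[i] <- k >= 2L
  }
  out
}

# Step-down Storey q-values by direct double loop.
oracle_storey <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) pi0 * m * p[o[j]] / j)
    q[o[i]] <- min(vals)
  }
  pmin(q, 1)
}

# Full enumeration of the pooled permutation null for a small two-group
# design: all distinct balanced partitions (complements deduplicated for
# equal group sizes), identity excluded, statistics pooled across
# peptides, two-sided p via absolute values.
oracle_perm_p <- function(mat, g1_cols, stat_fun) {
  n <- ncol(mat)
  k <- length(g1_cols)
  combs <- combn(n, k)
  canonical <- function(s) {
    if (2 * k == n && !(1 %in% s)) sort(setdiff(seq_len(n), s)) else sort(s)
  }
  keys <- apply(combs, 2, function(s) paste(canonical(s), collapse = ","))
  id_key <- paste(canonical(g1_cols), collapse = ",")
  use <- !duplicated(keys) & keys != id_key
  null_vals <- c()
  for (j in which(use)) {
    s <- canonical(combs[, j])
    for (i in seq_len(nrow(mat))) {
      null_vals <- c(null_vals,
                     stat_fun(mat[i, s], mat[i, setdiff(seq_len(n), s)]))
    }
  }
  obs <- sapply(seq_len(nrow(mat)), function(i)
    stat_fun(mat[i, g1_cols], mat[i, setdiff(seq_len(n), g1_cols)]))
  null_abs <- abs(null_vals[!is.na(null_vals)])
  p <- sapply(obs, function(o) (1 + sum(null_abs >= abs(o))) /
                (1 + length(null_abs)))
  list(observed = obs, p = p, n_null = length(null_abs))
}

# Plain two-group statistics for the oracle above.
oracle_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  d <- mean(x) - mean(y)
  if (sp2 <= 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sqrt(sp2 * (1 / n1 + 1 / n2))
}
oracle_ratio <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  median(x) - median(y)
}

# Exact hypergeometric upper tail by combinatorial summation.
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Small two-group subject table for statistics tests.
make_subject_table <- function(mat, peptide_ids = NULL) {
  if (is.null(peptide_ids)) peptide_ids <- sprintf("pep%02d", seq_len(nrow(mat)))
  colnames(mat) <- colnames(mat) %||% sprintf("S%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(peptide_id = peptide_ids),
                   tibble::as_tibble(as.data.frame(mat)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

two_group_subjects <- function(n1, n2, groups = c("T2DM", "control")) {
  tibble::tibble(subject_id = sprintf("S%02d", seq_len(n1 + n2)),
                 group = rep(groups, c(n1, n2)))
}
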