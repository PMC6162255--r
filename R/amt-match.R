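#' Mass and NET matching tolerances
#'
#' @param mass_ppm Mass tolerance in parts per million (default +/-10).
#' @param net_tol NET tolerance (default +/-0.025).
#' @return A `match_tolerances` list.
#' @export
match_tolerances <- function(mass_ppm = 10, net_tol = 0.025) {
  assert_scalar_number(mass_ppm, "mass_ppm", lower = 0, strict_lower = TRUE)
  assert_scalar_number(net_tol, "net_tol", lower = 0, strict_lower = TRUE)
  structure(list(mass_ppm = mass_ppm, net_tol = net_tol),
            class = "match_tolerances")
}

# Vectorised matcher: mass-sorted index + binary-search windowing.
# ppm deviation is computed relative to the database entry's avg_mass.
amt_match_engine <- function(mass, net, db, tol) {
  ord <- order(db$avg_mass)
  dbm <- db$avg_mass[ord]
  dbn <- db$median_net[ord]
  dbp <- db$peptide_id[ord]
  mp <- tol$mass_ppm
  nt <- tol$net_tol

  n <- length(mass)
  out_pep <- rep(NA_character_, n)
  out_ppm <- rep(NA_real_, n)
  out_net <- rep(NA_real_, n)
  out_ncand <- integer(n)
  out_amb <- rep(FALSE, n)

  lo <- findInterval(mass / (1 + mp / 1e6), dbm, left.open = TRUE) + 1L
  hi <- findInterval(mass / (1 - mp / 1e6), dbm)
  for (i in seq_len(n)) {
    if (hi[i] < lo[i]) next
    j <- lo[i]:hi[i]
    dppm <- 1e6 * (mass[i] - dbm[j]) / dbm[j]
    dnet <- net[i] - dbn[j]
    ok <- abs(dppm) <= mp & abs(dnet) <= nt
    k <- sum(ok)
    out_ncand[i] <- k
    if (k == 0) next
    j <- j[ok]; dppm <- dppm[ok]; dnet <- dnet[ok]
    dist <- sqrt((dppm / mp)^2 + (dnet / nt)^2)
    w <- order(dist, dbp[j])[1]  # nearest; ties broken by peptide id
    out_pep[i] <- dbp[j][w]
    out_ppm[i] <- dppm[w]
    out_net[i] <- dnet[w]
    out_amb[i] <- k >= 2
  }
  tibble::tibble(matched_peptide_id = out_pep, delta_ppm = out_ppm,
                 delta_net = out_net, n_candidates = out_ncand,
                 ambiguous = out_amb)
}

#' Match one UMC against the AMT database
#'
#' Candidates are database entries within both tolerances
#' (`|1e6 * (mass - avg_mass) / avg_mass| <= mass_ppm` and
#' `|net - median_net| <= net_tol`); the winner minimizes the scaled
#' distance `sqrt((dppm/mass_ppm)^2 + (dnet/net_tol)^2)`. `ambiguous` is
#' set whenever two or more candidates lie within tolerance.
#'
#' @param umc One-row feature tibble with `mass` and calibrated `net`.
#' @param db An [build_amt_db()] database.
#' @param tol [match_tolerances()].
#' @return One-row tibble: `matched_peptide_id` (NA if no candidate),
#'   `delta_ppm`, `delta_net`, `n_candidates`, `ambiguous`.
#' @export
match_umc <- function(umc, db, tol = match_tolerances()) {
  stopifnot(nrow(umc) == 1L, nrow(db) >= 1L)
  assert_columns(umc, c("mass", "net"), "umc")
  amt_match_engine(umc$mass, umc$net, db, tol)
}

#' Assign peptide identities to unidentified UMCs
#'
#' Features that already carry a database-search identity are never
#' reassigned (`source = "searched"`); every unidentified feature is
#' matched against the AMT database with [match_umc()] semantics
#' (`source = "amt"` when a match is found). With
#' `drop_ambiguous = TRUE`, matches with two or more in-tolerance
#' candidates are discarded instead of being assigned to the nearest.
#'
#' @param features Calibrated feature tibble (`run_id`, `umc_id`, `mass`,
#'   `net`, `intensity`, `peptide_id`).
#' @param db An `amt_db`.
#' @param tol [match_tolerances()].
#' @param drop_ambiguous Discard ambiguous matches (default FALSE:
#'   nearest candidate assigned, flagged).
#' @return The feature tibble with `peptide_id` filled where matched plus
#'   columns `source` ("searched", "amt" or NA), `delta_ppm`, `delta_net`,
#'   `n_candidates`, `ambiguous`. The assignment summary is attached as
#'   attribute `"summary"` (see [assignment_summary()]).
#' @export
assign_peptides <- function(features, db, tol = match_tolerances(),
                            drop_ambiguous = FALSE) {
  if (!nrow(features)) {
    abort("no features to assign", class = "mitoamt_empty_input")
  }
  assert_columns(features, c("run_id", "umc_id", "mass", "net", "peptide_id"),
                 "features")
  out <- features
  out$source <- ifelse(is.na(out$peptide_id), NA_character_, "searched")
  out$delta_ppm <- NA_real_
  out$delta_net <- NA_real_
  out$n_candidates <- NA_integer_
  out$ambiguous <- NA

  un <- which(is.na(out$peptide_id))
  if (length(un)) {
    m <- amt_match_engine(out$mass[un], out$net[un], db, tol)
    if (drop_ambiguous) {
      m$matched_peptide_id[m$ambiguous] <- NA_character_
    }
    hit <- !is.na(m$matched_peptide_id)
    out$peptide_id[un] <- m$matched_peptide_id
    out$source[un][hit] <- "amt"
    out$delta_ppm[un] <- m$delta_ppm
    out$delta_net[un] <- m$delta_net
    out$n_candidates[un] <- m$n_candidates
    out$ambiguous[un] <- m$ambiguous
  }
  attr(out, "summary") <- assignment_summary(out)
  out
}

#' Assignment bookkeeping summary
#'
#' Totals for an assignment table, or the same arithmetic from bare
#' counts: `n_with_id = n_identified + n_amt_assigned` and
#' `id_fraction = n_identified / n_total` (the MS/MS identification
#' a.k.a. undersampling rate).
#'
#' @param x An [assign_peptides()] result, or the total feature count
#'   `n_total` when used with the two count arguments.
#' @param n_identified,n_amt_assigned Counts of search-identified and
#'   AMT-assigned features (count mode only).
#' @return One-row tibble: `n_total`, `n_identified`, `n_amt_assigned`,
#'   `n_with_id`, `id_fraction`.
#' @export
#' @examples
#' assignment_summary(54077, 5602, 3363)  # n_with_id 8965, id_fraction 0.104
assignment_summary <- function(x, n_identified = NULL,
                               n_amt_assigned = NULL) {
  if (is.data.frame(x)) {
    n_total <- nrow(x)
    n_id <- sum(x$source == "searched", na.rm = TRUE)
    n_amt <- sum(x$source == "amt", na.rm = TRUE)
  } else {
    stopifnot(is.numeric(x), !is.null(n_identified), !is.null(n_amt_assigned))
    n_total <- x
    n_id <- n_identified
    n_amt <- n_amt_assigned
  }
  tibble::tibble(n_total = n_total, n_identified = n_id,
                 n_amt_assigned = n_amt, n_with_id = n_id + n_amt,
                 id_fraction = n_id / n_total)
}
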