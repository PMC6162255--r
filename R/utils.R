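`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so simulation helpers are reproducible without
#' clobbering the session stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stage- or run-specific seed from a global seed
#'
#' Deterministic integer hash of `label` folded into `seed`, kept below
#' 2^31 so it is always a valid R seed. Used so a single pipeline seed
#' yields independent, individually reproducible streams per stage/run.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the stage or run.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "simulate")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 7919 + h) %% m)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%s, %s]", name,
                  if (strict_lower) "(" else "[", lower, upper),
          class = "mitoamt_config_error")
  }
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s", name,
                  paste(missing, collapse = ", ")),
          class = "mitoamt_input_error")
  }
  invisible(df)
}
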