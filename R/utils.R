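#' @keywords internal
"_PACKAGE"

# Outcome rate columns, in canonical order (ED attendances, unplanned
# admissions, unplanned readmissions), all per 100 registered patients/month.
OUTCOME_COLS <- c("ed_rate", "adm_rate", "readm_rate")

# Fixed panel CSV header: identifiers, outcomes, then covariates.
COVARIATE_COLS <- c(
  "gp_count", "nurse_count", "bme_pct",
  "f0_19_pct", "f20_64_pct", "f65_pct",
  "m0_19_pct", "m20_64_pct", "m65_pct",
  "imd", "urban_pct",
  "prev_chd_pct", "prev_diabetes_pct", "prev_copd_pct"
)
PANEL_COLS <- c("practice_id", "month_index", "list_size",
                OUTCOME_COLS, "em_los", COVARIATE_COLS)

#' Round half away from zero
#'
#' Commercial rounding used for event counts and whole-currency unit costs,
#' where R's default round-half-to-even would disagree on exact halves.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one top-level seed, so that every
# stage of a pipeline run is independently reproducible. Kept below 2^31.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) * 7919 + salt * 104729 + seq_len(n) * 613) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
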