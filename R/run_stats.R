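# Many-run sign statistics in the shape of the published 32-run table:
# per-run fractional left/right "expert" scores plus a signed per-run
# chirality value classified by its sign.

#' Classify runs by the sign of the chirality formula value
#'
#' A positive per-run index means a right-handed (D) helix, a negative one a
#' left-handed (L) helix; exact zeros are counted in their own bucket rather
#' than assigned a side.  Display percentages are rounded half away from
#' zero to integer percent (so 6/32 prints as 19).
#'
#' @param outcomes a data.frame with a numeric `formula_value` (or
#'   `chirality_value`) column, one row per run; or a bare numeric vector.
#' @return A list: `n_left`, `n_right`, `n_zero`, `pct_left`, `pct_right`
#'   (integer display percent), `n`.
#' @export
classify_by_formula <- function(outcomes) {
  v <- if (is.numeric(outcomes)) outcomes
       else outcomes[["formula_value"]] %||% outcomes[["chirality_value"]]
  if (is.null(v)) stop("no formula_value / chirality_value column")
  if (anyNA(v)) stop("formula_value must be present for every run")
  n <- length(v)
  n_right <- sum(v > 0); n_left <- sum(v < 0); n_zero <- sum(v == 0)
  list(n_left = n_left, n_right = n_right, n_zero = n_zero,
       pct_left = .display_pct(n_left / n),
       pct_right = .display_pct(n_right / n), n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero, as the printed table does (18.75 -> 19)
.display_pct <- function(frac) floor(100 * frac + 0.5)

#' Aggregate fractional expert-style scores
#'
#' Sums the per-run fractional left/right scores (mixed structures carry
#' e.g. 0.5/0.5) and reports display percentages over the number of runs.
#'
#' @param outcomes a data.frame with numeric `left_score` and `right_score`
#'   columns in [0, 1].
#' @return A list: `sum_left`, `sum_right`, `pct_left`, `pct_right`, `n`.
#' @export
aggregate_fractional <- function(outcomes) {
  ls <- outcomes$left_score; rs <- outcomes$right_score
  if (any(ls < 0 | ls > 1 | rs < 0 | rs > 1, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  ls[is.na(ls)] <- 0; rs[is.na(rs)] <- 0
  n <- nrow(outcomes)
  list(sum_left = sum(ls), sum_right = sum(rs),
       pct_left = .display_pct(sum(ls) / n),
       pct_right = .display_pct(sum(rs) / n), n = n)
}

#' Fractional left/right scores from a chirality profile
#'
#' Operationalizes the human expert assessment: the left (right) score is
#' the fraction of sliding windows with negative (positive) Calpha index,
#' renormalized over signed windows, optionally snapped to the display grid
#' {0, 0.2, 0.5, 0.8, 1} used in the published table.
#'
#' @param report a `ChiralityReport` carrying a `profile` (see
#'   [calpha_chirality()] with `window` set), or a profile list itself.
#' @param snap snap scores to the display grid (default TRUE).
#' @return A list: `left_score`, `right_score`, `label`.
#' @export
score_run <- function(report, snap = TRUE) {
  prof <- if (!is.null(report$profile)) report$profile else report
  if (is.null(prof$frac_positive))
    stop("report carries no chirality profile")
  tot <- prof$frac_positive + prof$frac_negative
  if (tot == 0) {
    right <- 0.5; left <- 0.5
  } else {
    right <- prof$frac_positive / tot
    left <- prof$frac_negative / tot
  }
  if (snap) {
    grid <- c(0, 0.2, 0.5, 0.8, 1)
    left <- grid[which.min(abs(grid - left))]
    right <- 1 - left
  }
  list(left_score = left, right_score = right, label = prof$label)
}

#' The published 32-run statistics table (transcribed fixture)
#'
#' Returns the packaged transcription of the published per-run outcomes for
#' the L-monomer and D-monomer series: fractional expert scores and the
#' signed per-run chirality value.  The TSV ships with an md5 checksum that
#' is verified on load.
#'
#' @return A data.frame with columns `run`, `monomer`, `left_score`,
#'   `right_score`, `formula_value`.
#' @export
table1_runs <- function() {
  path <- system.file("extdata", "table1_runs.tsv", package = "pnthelix",
                      mustWork = TRUE)
  md5 <- system.file("extdata", "table1_runs.tsv.md5", package = "pnthelix",
                     mustWork = TRUE)
  expect <- strsplit(readLines(md5, n = 1), " ")[[1]][1]
  got <- unname(tools::md5sum(path))
  if (!identical(got, expect))
    stop("table1_runs.tsv checksum mismatch: fixture corrupted")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab
}

#' Aggregate a batch into the published table shape
#'
#' @param outcomes data.frame with `left_score`, `right_score` and a signed
#'   value column (`formula_value` or `chirality_value`).
#' @return A list with `formula` (=[classify_by_formula()]) and `expert`
#'   (=[aggregate_fractional()]) aggregates.
#' @export
stats_table <- function(outcomes) {
  list(formula = classify_by_formula(outcomes),
       expert = aggregate_fractional(outcomes))
}
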