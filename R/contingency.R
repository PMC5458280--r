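#' Build yearly 2x2 contingency tables
#'
#' For every year of the study window, cohort reports are cross-classified
#' by drug exposure (the drug generic name is / is not in the report's drug
#' set) and event status (the reaction preferred term is / is not in the
#' reaction set), giving the cells
#' \describe{
#'   \item{a}{exposed, event reported}
#'   \item{b}{exposed, event not reported}
#'   \item{c}{unexposed, event reported}
#'   \item{d}{unexposed, event not reported}
#' }
#' Years with no cohort reports yield all-zero rows so the stratum list
#' always matches `spec$years`.
#'
#' @param cohort a [safety_reports()] collection already restricted to the
#'   indication and year window (see [select_cohort()]).
#' @param spec a [cohort_spec()].
#' @return a `stratum_tables` data frame with columns `stratum`, `a`, `b`,
#'   `c`, `d`, `corrected` (one row per year, in `spec$years` order).
#' @export
build_yearly_tables <- function(cohort, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  exposed <- has_term(cohort, spec$drug_term, "drugs")
  event <- has_term(cohort, spec$event_term, "reactions")
  cell <- function(e, v) vapply(spec$years, function(y)
    sum(cohort$year == y & exposed == e & event == v), integer(1L))
  out <- data.frame(stratum = spec$years,
                    a = cell(TRUE, TRUE), b = cell(TRUE, FALSE),
                    c = cell(FALSE, TRUE), d = cell(FALSE, FALSE),
                    corrected = FALSE)
  class(out) <- c("stratum_tables", "data.frame")
  out
}

#' Haldane-Anscombe continuity correction
#'
#' The log odds ratio and its Woolf variance are undefined when any cell of
#' a 2x2 table is zero. For each uncorrected stratum containing a zero
#' cell, 0.5 is added to all four cells and the stratum is flagged
#' `corrected`; strata without zero cells pass through unchanged.
#'
#' @param tables a `stratum_tables` data frame (see [build_yearly_tables()]).
#' @return the corrected `stratum_tables`.
#' @export
continuity_correct <- function(tables) {
  if (any(tables$corrected)) stop("tables already corrected")
  hit <- tables$a == 0 | tables$b == 0 | tables$c == 0 | tables$d == 0
  for (col in c("a", "b", "c", "d"))
    tables[[col]] <- tables[[col]] + 0.5 * hit
  tables$corrected <- hit
  tables
}

# Strata whose raw table has an empty exposure arm (a+b=0) or control arm
# (c+d=0) carry no information about the odds ratio: their corrected
# estimate would be pure artifact, so pooling excludes them.
usable_strata <- function(tables) {
  tables$a + tables$b > 0 & tables$c + tables$d > 0
}
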