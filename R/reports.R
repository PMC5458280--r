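#' Normalize an index term
#'
#' Safety-report databases match fixed uppercase index terms (drug generic
#' names, indication terms, MedDRA-style reaction preferred terms such as
#' `"ANAEMIA"`). This canonicalises free text to that convention: uppercase,
#' trimmed, with internal whitespace runs collapsed to single spaces.
#'
#' @param raw character vector.
#' @return character vector of normalized terms; empty strings pass through.
#' @examples
#' normalize_term("carboplatin")
#' normalize_term("  Non-small   cell lung cancer ")
#' @export
normalize_term <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  gsub("[[:space:]]+", " ", trimws(toupper(raw)))
}

normalize_set <- function(x) {
  x <- normalize_term(as.character(x))
  sort(unique(x[nzchar(x)]))
}

#' Construct a collection of safety reports
#'
#' The central container: one row per spontaneous adverse-event report, with
#' an opaque unique `report_id`, the calendar `year` of receipt, and three
#' list-columns of normalized term sets (`drugs`, `indications`,
#' `reactions`). Term sets are stored sorted and deduplicated so that two
#' collections with the same content are identical objects.
#'
#' @param report_id character vector of non-empty unique identifiers.
#' @param year integer vector of receipt years.
#' @param drugs,indications,reactions lists of character vectors (or a single
#'   character vector recycled to all reports).
#' @return a `safety_reports` data frame.
#' @export
safety_reports <- function(report_id, year, drugs, indications, reactions) {
  report_id <- as.character(report_id)
  n <- length(report_id)
  as_set_col <- function(x, what) {
    if (is.character(x)) x <- rep(list(x), n)
    if (!is.list(x) || length(x) != n)
      stop(sprintf("'%s' must be a list of length %d", what, n))
    # normalize in one vectorized pass, then split back per report
    u <- normalize_term(unlist(x, use.names = FALSE))
    sets <- split(u, factor(rep.int(seq_len(n), lengths(x)),
                            levels = seq_len(n)))
    unname(lapply(sets, function(s) sort(unique(s[nzchar(s)]))))
  }
  year <- as.integer(year)
  if (length(year) != n) stop("'year' must match length of 'report_id'")
  if (any(!nzchar(report_id))) stop("report_id must be non-empty")
  if (anyDuplicated(report_id)) stop("report_id must be unique")
  if (any(is.na(year))) stop("year must not be NA")
  out <- data.frame(report_id = report_id, year = year,
                    stringsAsFactors = FALSE)
  out$drugs <- as_set_col(drugs, "drugs")
  out$indications <- as_set_col(indications, "indications")
  out$reactions <- as_set_col(reactions, "reactions")
  class(out) <- c("safety_reports", "data.frame")
  out
}

#' @export
print.safety_reports <- function(x, ...) {
  cat(sprintf("<safety_reports> %d reports, years %s\n", nrow(x),
              if (nrow(x)) paste(range(x$year), collapse = "-") else "-"))
  if (nrow(x)) {
    show <- utils::head(x, 5L)
    fmt <- function(l) vapply(l, function(s) paste(s, collapse = "|"), "")
    print(data.frame(report_id = show$report_id, year = show$year,
                     drugs = fmt(show$drugs),
                     indications = fmt(show$indications),
                     reactions = fmt(show$reactions)), row.names = FALSE)
    if (nrow(x) > 5) cat(sprintf("... and %d more\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Cohort specification
#'
#' Bundles the three index terms and the year window that define one
#' disproportionality analysis: the indication that selects the cohort, the
#' drug generic name that defines exposure, and the reaction preferred term
#' that defines the event.
#'
#' @param indication_term,drug_term,event_term index terms (normalized on
#'   construction).
#' @param years strictly increasing integer vector, default 2004:2015.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(indication_term, drug_term, event_term,
                        years = 2004:2015) {
  years <- as.integer(years)
  if (length(years) == 0L) stop("'years' must be non-empty")
  if (any(diff(years) <= 0L)) stop("'years' must be strictly increasing")
  terms <- normalize_term(c(indication_term, drug_term, event_term))
  if (any(!nzchar(terms))) stop("all three terms must be non-empty")
  structure(list(indication_term = terms[[1L]], drug_term = terms[[2L]],
                 event_term = terms[[3L]], years = years),
            class = "cohort_spec")
}

parse_year <- function(receipt_date) {
  y <- suppressWarnings(as.integer(substr(as.character(receipt_date), 1L, 4L)))
  y[!grepl("^[0-9]{4}", as.character(receipt_date))] <- NA_integer_
  y
}

# One openFDA-dialect record (an already-parsed JSON list) -> flat pieces.
openfda_record <- function(rec, lineno) {
  id <- rec$safetyreportid
  if (is.null(id)) stop(sprintf("line %d: missing safetyreportid", lineno))
  drugs <- character(); inds <- character()
  for (d in rec$patient$drug) {
    g <- d$openfda$generic_name
    if (is.null(g)) g <- d$medicinalproduct
    drugs <- c(drugs, unlist(g, use.names = FALSE))
    inds <- c(inds, unlist(d$drugindication, use.names = FALSE))
  }
  reacts <- unlist(lapply(rec$patient$reaction, function(r) r$reactionmeddrapt),
                   use.names = FALSE)
  list(report_id = as.character(id),
       receipt_date = as.character(rec$receiptdate %||% ""),
       drugs = as.character(drugs), indications = as.character(inds),
       reactions = as.character(reacts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_multi <- function(x) strsplit(as.character(x), "|", fixed = TRUE)

#' Read safety reports from a file
#'
#' Two dialects are supported. `"openfda"` is JSON lines, one report per
#' line, with the field paths `safetyreportid`, `receiptdate` (8-digit
#' `YYYYMMDD`; the year is its first four digits), `patient.drug[].openfda.
#' generic_name` (falling back to `medicinalproduct`),
#' `patient.drug[].drugindication` and `patient.reaction[].reactionmeddrapt`.
#' `"csv"` is a flat table with columns `report_id`, `receipt_date`,
#' `drugs`, `indications`, `reactions`, multi-valued cells delimited by
#' `"|"`.
#'
#' Records sharing a `report_id` are deduplicated keeping the last
#' occurrence in stream order (a superseding case version replaces earlier
#' ones). Records whose receipt year cannot be parsed are dropped. Both
#' events are counted in the load summary attached to the result
#' (see [load_summary()]).
#'
#' @param path file to read.
#' @param dialect `"openfda"` (JSON lines) or `"csv"`.
#' @return a [safety_reports()] collection with a `load_summary` attribute.
#' @export
read_reports <- function(path, dialect = c("openfda", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "openfda") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                      error = function(e)
                        stop(sprintf("malformed JSON at line %d of %s: %s",
                                     i, path, conditionMessage(e))))
      recs[[i]] <- openfda_record(rec, i)
    }
    ids <- vapply(recs, `[[`, "", "report_id")
    dates <- vapply(recs, `[[`, "", "receipt_date")
    drugs <- lapply(recs, `[[`, "drugs")
    inds <- lapply(recs, `[[`, "indications")
    reacts <- lapply(recs, `[[`, "reactions")
  } else {
    df <- tryCatch(read.csv(path, colClasses = "character"),
                   error = function(e)
                     stop(sprintf("malformed CSV in %s: %s", path,
                                  conditionMessage(e))))
    need <- c("report_id", "receipt_date", "drugs", "indications", "reactions")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols))
      stop(sprintf("CSV %s lacks column(s): %s", path,
                   paste(missing_cols, collapse = ", ")))
    ids <- df$report_id
    dates <- df$receipt_date
    drugs <- split_multi(df$drugs)
    inds <- split_multi(df$indications)
    reacts <- split_multi(df$reactions)
  }
  n_read <- length(ids)
  years <- parse_year(dates)
  ok <- !is.na(years)
  n_dropped <- sum(!ok)
  ids <- ids[ok]; years <- years[ok]
  drugs <- drugs[ok]; inds <- inds[ok]; reacts <- reacts[ok]
  keep <- !duplicated(ids, fromLast = TRUE)   # last case version wins
  n_dup <- sum(!keep)
  out <- safety_reports(ids[keep], years[keep], drugs[keep], inds[keep],
                        reacts[keep])
  attr(out, "load_summary") <- list(n_read = n_read, n_duplicates = n_dup,
                                    n_dropped_year = n_dropped,
                                    n_kept = nrow(out))
  out
}

#' Load summary of a read
#'
#' @param reports a collection returned by [read_reports()].
#' @return list with `n_read`, `n_duplicates`, `n_dropped_year`, `n_kept`.
#' @export
load_summary <- function(reports) attr(reports, "load_summary")

#' Write safety reports to a file
#'
#' Inverse of [read_reports()]. Term sets are written sorted, so output is
#' byte-deterministic for a given collection. Because only the year is
#' retained in memory, the receipt date is serialised as `YYYY0701`.
#'
#' @param reports a [safety_reports()] collection.
#' @param path destination file.
#' @param dialect `"openfda"` (JSON lines) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, dialect = c("openfda", "csv")) {
  dialect <- match.arg(dialect)
  date <- sprintf("%04d0701", reports$year)
  if (dialect == "openfda") {
    lines <- vapply(seq_len(nrow(reports)), function(i) {
      # the reader takes unions across drug records, so drugs and
      # indications may each occupy their own record
      drug_recs <- c(
        lapply(reports$drugs[[i]],
               function(d) list(openfda = list(generic_name = list(d)))),
        lapply(reports$indications[[i]],
               function(x) list(drugindication = x)))
      rec <- list(
        safetyreportid = reports$report_id[[i]],
        receiptdate = date[[i]],
        patient = list(
          drug = drug_recs,
          reaction = lapply(reports$reactions[[i]],
                            function(r) list(reactionmeddrapt = r))))
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, "")
    writeLines(lines, path)
  } else {
    join <- function(l) vapply(l, paste, "", collapse = "|")
    df <- data.frame(report_id = reports$report_id, receipt_date = date,
                     drugs = join(reports$drugs),
                     indications = join(reports$indications),
                     reactions = join(reports$reactions))
    write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Select the indication cohort
#'
#' Keeps exactly the reports whose indication set contains `indication_term`
#' as an element (exact match on normalized strings — never substring, so
#' e.g. `"ANAEMIA"` inside `"HAEMOLYTIC ANAEMIA"` does not match) and whose
#' receipt year lies in `years`. Order is preserved.
#'
#' @param reports a [safety_reports()] collection.
#' @param indication_term normalized indication string.
#' @param years integer vector of admissible years.
#' @return the filtered `safety_reports` collection.
#' @export
select_cohort <- function(reports, indication_term, years) {
  if (length(years) == 0L) stop("'years' must be non-empty")
  term <- normalize_term(indication_term)
  keep <- has_term(reports, term, "indications") & reports$year %in% years
  out <- reports[keep, , drop = FALSE]
  attr(out, "load_summary") <- NULL
  class(out) <- c("safety_reports", "data.frame")
  out
}

#' Term membership per report
#'
#' Exposure and event classification: a report is drug-exposed iff the drug
#' generic name is an element of its drug set, and is an event case iff the
#' reaction preferred term is an element of its reaction set.
#'
#' @param reports a [safety_reports()] collection.
#' @param term normalized term to test.
#' @param field one of `"drugs"`, `"reactions"`, `"indications"`.
#' @return logical vector, one element per report.
#' @export
has_term <- function(reports, term, field = c("drugs", "reactions",
                                              "indications")) {
  field <- match.arg(field)
  term <- normalize_term(term)
  vapply(reports[[field]], function(s) term %in% s, logical(1L))
}
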