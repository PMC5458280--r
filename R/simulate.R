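# Decoy vocabularies: other systemic therapies used in non-small cell lung
# cancer, and common non-hematologic reaction preferred terms. Fixed lists
# keep fixtures reproducible.
decoy_drugs <- c("PACLITAXEL", "CISPLATIN", "GEMCITABINE", "DOCETAXEL",
                 "PEMETREXED", "ERLOTINIB", "GEFITINIB", "BEVACIZUMAB",
                 "VINORELBINE", "ETOPOSIDE")
decoy_reactions <- c("NAUSEA", "VOMITING", "FATIGUE", "DYSPNOEA", "PYREXIA",
                     "RASH", "DIARRHOEA", "COUGH", "DECREASED APPETITE",
                     "ALOPECIA")

#' Configuration for the synthetic report stream
#'
#' Defaults emulate the structure of the motivating study: twelve receipt
#' years (2004-2015) of roughly 1600 non-small cell lung cancer reports
#' each (about 19.2k total, close to the 19901 real reports), a 0.2
#' probability that a report carries the study drug (3907/19901 in the
#' real extract), a baseline probability 0.05 that an unexposed report
#' lists the event term, a common true log odds ratio log(2.27) matching
#' the reported pooled anemia ROR, and between-year heterogeneity tau =
#' 0.2 on the log-odds-ratio scale.
#'
#' @param years receipt years, default 2004:2015.
#' @param reports_per_year scalar or per-year vector of report counts.
#' @param p_exposure probability a report carries `drug_term`.
#' @param p_event_unexposed baseline probability an unexposed report lists
#'   `event_term`.
#' @param true_log_or mean of the yearly log odds ratio.
#' @param tau between-year standard deviation of the yearly log odds ratio.
#' @param seed integer seed; all generator randomness flows through it.
#' @param indication_term,drug_term,event_term index terms carried by the
#'   generated reports.
#' @param duplicate_rate fraction of reports re-emitted later in the
#'   stream under the same report id (for exercising deduplication);
#'   default 0.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(years = 2004:2015, reports_per_year = 1600L,
                              p_exposure = 0.2, p_event_unexposed = 0.05,
                              true_log_or = log(2.27), tau = 0.2,
                              seed = 1L,
                              indication_term = "NON-SMALL CELL LUNG CANCER",
                              drug_term = "CARBOPLATIN",
                              event_term = "ANAEMIA",
                              duplicate_rate = 0) {
  years <- as.integer(years)
  reports_per_year <- rep_len(as.integer(reports_per_year), length(years))
  stopifnot(length(years) >= 1L, all(reports_per_year >= 1L),
            p_exposure > 0, p_exposure < 1,
            p_event_unexposed > 0, p_event_unexposed < 1,
            tau >= 0, duplicate_rate >= 0, duplicate_rate < 1)
  structure(list(years = years, reports_per_year = reports_per_year,
                 p_exposure = p_exposure,
                 p_event_unexposed = p_event_unexposed,
                 true_log_or = true_log_or, tau = tau, seed = as.integer(seed),
                 indication_term = normalize_term(indication_term),
                 drug_term = normalize_term(drug_term),
                 event_term = normalize_term(event_term),
                 duplicate_rate = duplicate_rate),
            class = "simulation_config")
}

#' Simulate a stream of adverse-event reports
#'
#' For each year a true log odds ratio `theta_i ~ Normal(true_log_or,
#' tau^2)` is drawn. Every report is independently drug-exposed with
#' probability `p_exposure`; unexposed reports list the event term with
#' probability `p_event_unexposed`, and exposed reports with the
#' probability whose odds equal `exp(theta_i)` times the baseline odds —
#' so `true_log_or` is exactly the log reporting odds ratio of the
#' generating process. Every report carries the study indication; exposed
#' reports carry the study drug plus decoy co-medications, unexposed
#' reports decoys only. Deterministic given `config$seed`; the caller's
#' RNG state is untouched.
#'
#' @param config a [simulation_config()].
#' @return a [safety_reports()] collection with attribute
#'   `yearly_log_or` (the realized `theta_i`).
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_preserved_seed(config$seed, {
    theta <- rnorm(length(config$years), config$true_log_or, config$tau)
    p0 <- config$p_event_unexposed
    p1 <- plogis(qlogis(p0) + theta)
    if (any(p1 <= 0 | p1 >= 1) || any(!is.finite(p1)))
      stop("implied exposed event probability outside (0,1)")
    per_year <- lapply(seq_along(config$years), function(i) {
      n <- config$reports_per_year[[i]]
      exposed <- runif(n) < config$p_exposure
      event <- runif(n) < ifelse(exposed, p1[[i]], p0)
      n_decoy_d <- sample(1:2, n, replace = TRUE)
      n_decoy_r <- sample(1:2, n, replace = TRUE)
      drugs <- lapply(seq_len(n), function(j) {
        base <- sample(decoy_drugs, n_decoy_d[[j]])
        if (exposed[[j]]) c(config$drug_term, base) else base
      })
      reactions <- lapply(seq_len(n), function(j) {
        base <- sample(decoy_reactions, n_decoy_r[[j]])
        if (event[[j]]) c(config$event_term, base) else base
      })
      list(ids = sprintf("%d-%06d", config$years[[i]], seq_len(n)),
           year = rep(config$years[[i]], n), drugs = drugs,
           reactions = reactions)
    })
    ids <- unlist(lapply(per_year, `[[`, "ids"))
    year <- unlist(lapply(per_year, `[[`, "year"))
    drugs <- do.call(c, lapply(per_year, `[[`, "drugs"))
    reactions <- do.call(c, lapply(per_year, `[[`, "reactions"))
    out <- safety_reports(ids, year, drugs,
                          indications = config$indication_term,
                          reactions = reactions)
    attr(out, "yearly_log_or") <- stats::setNames(theta, config$years)
    attr(out, "duplicate_ids") <-
      if (config$duplicate_rate > 0)
        sample(ids, max(1L, floor(config$duplicate_rate * length(ids))))
      else character()
    out
  })
}

#' Write a simulated stream, optionally with injected duplicates
#'
#' Serialises a simulated collection with [write_reports()]; if the
#' generating config requested `duplicate_rate > 0`, the flagged reports
#' are re-emitted at the end of the stream under their original ids, so a
#' subsequent [read_reports()] must deduplicate them.
#'
#' @param reports output of [simulate_reports()].
#' @param path destination file.
#' @param dialect `"openfda"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_simulated_stream <- function(reports, path,
                                   dialect = c("openfda", "csv")) {
  dialect <- match.arg(dialect)
  dup <- attr(reports, "duplicate_ids")
  write_reports(reports, path, dialect)
  if (length(dup)) {
    tmp <- tempfile(fileext = ".txt")
    on.exit(unlink(tmp), add = TRUE)
    extra <- reports[match(dup, reports$report_id), , drop = FALSE]
    class(extra) <- c("safety_reports", "data.frame")
    write_reports(extra, tmp, dialect)
    lines <- readLines(tmp, warn = FALSE)
    if (dialect == "csv") lines <- lines[-1L]
    cat(lines, file = path, sep = "\n", append = TRUE)
  }
  invisible(path)
}

#' Simulate a gene universe with one planted enriched category
#'
#' Builds a reference of `N` opaque gene ids, samples each category
#' uniformly from it, then draws a query of expected size `n_query` such
#' that the planted category's expected enrichment ratio equals `fold`:
#' each planted-category gene enters the query with probability
#' `fold * n_query / N`, and the remaining query members are drawn
#' uniformly from outside the planted category. `fold = 1` reduces to a
#' uniform null query. Deterministic given `seed`.
#'
#' @param N reference universe size.
#' @param n_query target query size.
#' @param categories named integer vector of category sizes `K`.
#' @param planted `list(name = <category>, fold = <expected ratio>)`, or
#'   `NULL` for a fully uniform query.
#' @param seed integer seed.
#' @return list with elements `genes`, `query`, `categories` (named list
#'   of id vectors, GMT-ready).
#' @export
simulate_gene_universe <- function(N, n_query, categories, planted = NULL,
                                   seed = 1L) {
  stopifnot(N >= 1, n_query >= 1, n_query <= N, length(categories) >= 1L,
            !is.null(names(categories)), all(categories >= 1),
            all(categories <= N))
  with_preserved_seed(seed, {
    genes <- sprintf("G%06d", seq_len(N))
    sets <- lapply(categories, function(K) sample(genes, K))
    if (is.null(planted)) {
      query <- sample(genes, n_query)
    } else {
      stopifnot(planted$name %in% names(categories), planted$fold >= 1)
      p_hit <- planted$fold * n_query / N
      members <- sets[[planted$name]]
      if (p_hit > 1 || planted$fold * n_query * length(members) / N >
            min(length(members), n_query))
        stop("planted fold infeasible for the given sizes")
      hits <- members[runif(length(members)) < p_hit]
      pool <- setdiff(genes, members)
      n_rest <- max(0L, n_query - length(hits))
      query <- c(hits, sample(pool, min(n_rest, length(pool))))
    }
    list(genes = genes, query = query, categories = sets)
  })
}
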