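#' Configuration for an end-to-end signal analysis
#'
#' @param input path to a report file, or a [safety_reports()] collection.
#' @param dialect input dialect for file input (see [read_reports()]).
#' @param indication_term,drug_term,event_term,years cohort definition
#'   (see [cohort_spec()]).
#' @param level confidence level, default 0.95.
#' @param het_alpha heterogeneity significance threshold driving model
#'   selection, default 0.05.
#' @param out_dir output directory (created if absent); `NULL` suppresses
#'   file output.
#' @return a `signal_config` list.
#' @export
signal_config <- function(input, dialect = "openfda", indication_term,
                          drug_term, event_term, years = 2004:2015,
                          level = 0.95, het_alpha = 0.05, out_dir = NULL) {
  structure(list(input = input, dialect = dialect,
                 spec = cohort_spec(indication_term, drug_term, event_term,
                                    years),
                 level = level, het_alpha = het_alpha, out_dir = out_dir),
            class = "signal_config")
}

write_tsv <- function(df, path) {
  # "." marks undefined cells
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.numeric(col))
      col <- trimws(formatC(col, digits = 10, format = "g"))
    col[is.na(df[[j]])] <- "."
    out[[j]] <- col
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full disproportionality signal analysis
#'
#' Executes the whole chain: cohort selection by indication and year
#' window, yearly 2x2 tables, continuity correction, per-year reporting
#' odds ratios, Cochran's Q / I-squared heterogeneity, model selection
#' (random-effects DerSimonian-Laird under significant heterogeneity,
#' fixed-effects Mantel-Haenszel otherwise), leave-one-out sensitivity,
#' and Egger's test with funnel coordinates.
#'
#' When `config$out_dir` is set the bundle is written there:
#' `strata_effects.tsv` (per-year cells and estimates),
#' `pooled_summary.json`, `sensitivity.tsv`, `funnel.tsv` and
#' `run_log.json` (cohort counts, excluded strata, correction events).
#' Outputs are byte-deterministic for a given config and input.
#'
#' @param config a [signal_config()].
#' @return invisibly, a list with elements `cohort_size`, `tables`,
#'   `estimates`, `het`, `model`, `pooled`, `loo`, `egger`, `funnel`,
#'   `excluded_strata`, `corrected_strata`.
#' @export
run_signal_analysis <- function(config) {
  stopifnot(inherits(config, "signal_config"))
  spec <- config$spec
  reports <- if (inherits(config$input, "safety_reports")) config$input
  else read_reports(config$input, config$dialect)
  cohort <- select_cohort(reports, spec$indication_term, spec$years)
  tables <- build_yearly_tables(cohort, spec)
  usable <- usable_strata(tables)
  excluded <- tables$stratum[!usable]
  if (length(excluded))
    warning(sprintf("excluding stratum/strata with an empty arm: %s",
                    paste(excluded, collapse = ", ")))
  raw <- tables[usable, , drop = FALSE]
  if (nrow(raw) < 2L) stop("fewer than 2 usable strata; cannot pool")
  corrected <- continuity_correct(raw)
  estimates <- effect_estimate(corrected, config$level)
  het <- cochran_q(estimates)
  model <- select_model(het, config$het_alpha)
  pooled <- if (model == "random_DL") pool_random_dl(estimates, config$level)
  else pool_fixed_mh(raw, config$level)
  loo <- if (nrow(estimates) >= 3L)
    leave_one_out(estimates, model, config$level, tables = raw)
  else NULL
  egger <- if (nrow(estimates) >= 3L) egger_test(estimates) else NULL
  funnel <- funnel_coordinates(estimates)
  res <- list(cohort_size = nrow(cohort), tables = tables,
              estimates = estimates, het = het, model = model,
              pooled = pooled, loo = loo, egger = egger, funnel = funnel,
              excluded_strata = excluded,
              corrected_strata = corrected$stratum[corrected$corrected])
  if (!is.null(config$out_dir)) write_signal_bundle(res, config)
  invisible(res)
}

write_signal_bundle <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  strata <- merge(res$tables, as.data.frame(res$estimates),
                  by = "stratum", all.x = TRUE, sort = TRUE)
  write_tsv(strata, p("strata_effects.tsv"))
  pooled <- res$pooled
  summary <- list(
    model = pooled$model,
    k = pooled$k,
    or_pooled = pooled$or_pooled,
    ci_low = pooled$ci_low,
    ci_high = pooled$ci_high,
    z = pooled$z,
    p = pooled$p,
    level = pooled$level,
    heterogeneity = res$het[c("Q", "df", "p", "I2", "tau2")],
    egger = if (is.null(res$egger)) NULL
    else res$egger[c("intercept", "se_intercept", "t", "df", "p",
                     "asymmetry")])
  jsonlite::write_json(summary, p("pooled_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$loo)) write_tsv(res$loo, p("sensitivity.tsv"))
  write_tsv(res$funnel, p("funnel.tsv"))
  log <- list(indication_term = config$spec$indication_term,
              drug_term = config$spec$drug_term,
              event_term = config$spec$event_term,
              years = config$spec$years,
              cohort_size = res$cohort_size,
              excluded_strata = res$excluded_strata,
              corrected_strata = res$corrected_strata,
              crude_table = as.list(colSums(
                res$tables[c("a", "b", "c", "d")])))
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Run an over-representation analysis from files or objects
#'
#' Thin orchestration over [run_ora()]: reads the query list and the
#' categories (GMT gene sets or a `name,K,k` count CSV), fixes the
#' reference size either directly or by [recover_reference_size()] from
#' printed ratios, and optionally writes the result TSV.
#'
#' @param query path to a one-id-per-line gene list, or a character
#'   vector of ids.
#' @param categories path to a GMT file or `name,K,k[,ratio]` CSV, or an
#'   object [run_ora()] accepts.
#' @param N reference size; if `NULL`, recovered from a `ratio` column of
#'   the count input.
#' @param n query size (needed for count input without a query file).
#' @param alpha selection threshold, default 0.01.
#' @param out optional output TSV path.
#' @return the `enrichment_result` data frame (invisibly if `out` given).
#' @export
run_enrichment <- function(query, categories, N = NULL, n = NULL,
                           alpha = 0.01, out = NULL) {
  if (is.character(query) && length(query) == 1L && file.exists(query))
    query <- read_gene_list(query)
  if (is.character(categories) && length(categories) == 1L) {
    if (!file.exists(categories))
      stop(sprintf("categories file not found: %s", categories))
    categories <- if (grepl("\\.gmt$", categories, ignore.case = TRUE))
      read_gmt(categories)
    else read.csv(categories, stringsAsFactors = FALSE)
  }
  if (is.null(N)) {
    if (!is.data.frame(categories) || !"ratio" %in% names(categories))
      stop("supply N, or count input with a 'ratio' column to recover it")
    nn <- if (is.null(n)) length(unique(query)) else n
    cand <- recover_reference_size(categories, nn)
    if (length(cand) > 1L)
      warning(sprintf("reference size not unique (%d candidates); using %d",
                      length(cand), cand[[1L]]))
    N <- cand[[1L]]
  }
  res <- run_ora(query, categories, N, n = n, alpha = alpha)
  if (!is.null(out)) {
    write_tsv(as.data.frame(res), out)
    return(invisible(res))
  }
  res
}
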