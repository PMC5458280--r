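#' Enrichment ratio
#'
#' Observed hit fraction over expected: `(k/n) / (K/N)`, where `k` of the
#' `n` query genes fall in a category containing `K` of the `N` reference
#' genes. Returned exact (the reporting layer rounds to two decimals, half
#' away from zero, via [round_half_away()]).
#'
#' @param k query hits in the category.
#' @param n query size.
#' @param K category size in the reference.
#' @param N reference (universe) size.
#' @return the ratio `k*N / (n*K)`.
#' @export
enrichment_ratio <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0))
    stop("n, K and N must be positive")
  if (any(k < 0) || any(K > N) || any(n > N))
    stop("require 0 <= k, K <= N, n <= N")
  k * N / (n * K)
}

#' Hypergeometric upper tail
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' uniform draw of `n` genes from a reference of `N`, of which `K` belong
#' to the category, contains at least `k` category members. Delegates to
#' the log-space-stable [stats::phyper()], so tail values near 1e-50
#' remain accurate.
#'
#' @inheritParams enrichment_ratio
#' @return probability in \[0, 1\]; `k > min(n, K)` returns 0, `k <= 0`
#'   returns 1.
#' @export
hypergeom_sf <- function(k, n, K, N) {
  if (any(n <= 0) || any(K < 0) || any(N <= 0))
    stop("n and N must be positive, K non-negative")
  if (any(K > N) || any(n > N)) stop("require K <= N and n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: in ascending order the i-th
#' p-value becomes `min over j >= i of min(1, m * p_(j) / j)`, mapped back
#' to input order. Adjusted values never fall below their raw values.
#'
#' @param pvals numeric vector of probabilities in \[0, 1\].
#' @return adjusted probabilities, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each category for over-representation of the query gene set
#' against a reference universe of size `N`. Categories may be given
#' either as gene sets (a named list of id vectors, e.g. from
#' [read_gmt()]), in which case `K` is the set size and `k` the
#' intersection with the query, or as pre-tabulated counts (a data frame
#' with columns `name`, `K`, `k`), in which case `n` must be supplied.
#'
#' The Benjamini-Hochberg family size `m` equals the number of categories
#' supplied. Rows are sorted by adjusted p ascending, ties broken by name;
#' a category is `selected` when its adjusted p falls strictly below
#' `alpha`.
#'
#' @param query character vector of query gene ids (ignored when counts
#'   are supplied, beyond defaulting `n`).
#' @param categories named list of gene-id vectors, or a data frame with
#'   columns `name`, `K`, `k`.
#' @param N reference universe size.
#' @param n query size; defaults to `length(unique(query))`.
#' @param alpha selection threshold on the adjusted p, default 0.01.
#' @return an `enrichment_result` data frame with columns `name`, `K`,
#'   `k`, `ratio`, `p_raw`, `p_adj`, `selected`.
#' @export
run_ora <- function(query, categories, N, n = NULL, alpha = 0.01) {
  if (is.data.frame(categories)) {
    need <- c("name", "K", "k")
    if (!all(need %in% names(categories)))
      stop("count input needs columns name, K, k")
    if (is.null(n)) n <- length(unique(query))
    if (!length(n) || n <= 0) stop("query size 'n' required for count input")
    name <- as.character(categories$name)
    K <- as.numeric(categories$K)
    k <- as.numeric(categories$k)
  } else {
    if (length(categories) == 0L) stop("no categories supplied")
    if (length(query) == 0L) stop("empty query")
    query <- unique(normalize_term(query))
    if (is.null(n)) n <- length(query)
    name <- names(categories)
    if (is.null(name) || any(!nzchar(name)))
      stop("categories must be a named list")
    K <- vapply(categories, function(g) length(unique(g)), numeric(1L))
    k <- vapply(categories, function(g)
      length(intersect(unique(normalize_term(g)), query)), numeric(1L))
  }
  if (length(name) == 0L) stop("no categories supplied")
  if (any(k > K) || any(k > n)) stop("hits exceed category or query size")
  ratio <- enrichment_ratio(k, n, K, N)
  p_raw <- hypergeom_sf(k, n, K, N)
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(name = name, K = K, k = k, ratio = ratio,
                    p_raw = p_raw, p_adj = p_adj,
                    selected = p_adj < alpha)
  out <- out[order(out$p_adj, out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "N") <- N
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# Exact two-decimal rounding test in integer arithmetic: does k*N/(n*K)
# round (half away from zero) to ratio2dp/100? Avoids float boundary
# effects in the grid search.
ratio_rounds_to <- function(k, n, K, N, ratio2dp_x100) {
  (200 * k * N + n * K) %/% (2 * n * K) == ratio2dp_x100
}

#' Recover the reference universe size from printed ratios
#'
#' Published over-representation tables print the enrichment ratio to two
#' decimals but rarely the reference size `N` it was computed against.
#' Since `ratio = k*N/(n*K)`, each printed row confines `N` to an integer
#' interval; intersecting the constraints over several rows pins it down.
#' The search is exact (integer arithmetic, half-away-from-zero rounding).
#'
#' @param rows data frame with columns `K`, `k`, `ratio` (the printed
#'   two-decimal ratios).
#' @param n query size.
#' @param lo,hi inclusive integer search range, default 10000..100000.
#' @return integer vector of all consistent `N` (length 1 when unique).
#' @export
recover_reference_size <- function(rows, n, lo = 10000L, hi = 100000L) {
  if (!nrow(rows)) stop("no rows supplied")
  N <- as.numeric(lo:hi)
  target <- as.integer(round(100 * rows$ratio))
  ok <- rep(TRUE, length(N))
  per_row <- matrix(FALSE, length(N), nrow(rows))
  for (i in seq_len(nrow(rows))) {
    per_row[, i] <- ratio_rounds_to(rows$k[[i]], n, rows$K[[i]], N,
                                    target[[i]])
    ok <- ok & per_row[, i]
  }
  hits <- N[ok]
  if (!length(hits)) {
    best <- which.max(rowSums(per_row))
    bad <- which(!per_row[best, ])
    lab <- if ("name" %in% names(rows)) rows$name[bad] else bad
    stop(sprintf(
      "no reference size in [%d, %d] reproduces all printed ratios; closest candidate N = %d violates row(s): %s",
      lo, hi, as.integer(N[[best]]), paste(lab, collapse = ", ")))
  }
  as.integer(hits)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene ids, tab-
#' separated. Returns a named list of id vectors (descriptions kept as a
#' `description` attribute).
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d in %s", bad[[1L]], path))
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- vapply(parts, `[[`, "", 1L)
  attr(out, "description") <- vapply(parts, `[[`, "", 2L)
  out
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path destination file.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[[i]], description[[i]], sets[[i]]), collapse = "\t"),
    ""), path)
  invisible(path)
}

#' Read a one-id-per-line gene list
#'
#' @param path text file, one gene id per line.
#' @return character vector of unique normalized ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(normalize_term(x[nzchar(x)]))
}

#' Published pathway counts for the carboplatin gene set
#'
#' The bundled fixture `carboplatin_kegg_counts.csv` holds the published
#' KEGG over-representation counts for the 205 carboplatin-interacting
#' human genes: per pathway the reference category size `K`, the query hit
#' count `k`, the printed two-decimal enrichment ratio, and the printed
#' BH-adjusted p-value. The reference universe size behind these numbers
#' is not printed; [recover_reference_size()] recovers it.
#'
#' @return data frame with columns `name`, `K`, `k`, `ratio`, `p_adj`,
#'   plus attributes `n` (query size 205).
#' @export
kegg_example_counts <- function() {
  path <- system.file("extdata", "carboplatin_kegg_counts.csv",
                      package = "pvsignal", mustWork = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  attr(out, "n") <- 205L
  out
}
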