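# Shared fixtures and independent oracles for the suite.

# Directly assemble an effect_estimates frame from (y, v) pairs, bypassing
# table construction, for meta-analysis and bias tests.
mk_est <- function(y, v, stratum = seq_along(y), level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(stratum = stratum, y = y, v = v, ror = exp(y),
                    ci_low = exp(y - z * sqrt(v)),
                    ci_high = exp(y + z * sqrt(v)))
  attr(out, "level") <- level
  class(out) <- c("effect_estimates", "data.frame")
  out
}

mk_tables <- function(a, b, c, d, stratum = seq_along(a),
                      corrected = FALSE) {
  out <- data.frame(stratum = stratum, a = a, b = b, c = c, d = d,
                    corrected = corrected)
  class(out) <- c("stratum_tables", "data.frame")
  out
}

# Independent brute-force hypergeometric upper tail: enumerate the support
# with binomial coefficients (exact in doubles for small N).
hyper_brute <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- max(k, max(0, n - (N - K))):hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Six toy reports forming a known 2x2 in one year: 2 exposed-with-event,
# 1 exposed-without, 1 unexposed-with, 2 unexposed-without.
toy_cohort <- function(year = 2010) {
  safety_reports(
    report_id = paste0("r", 1:6),
    year = rep(year, 6),
    drugs = list(c("CARBOPLATIN", "PACLITAXEL"), "CARBOPLATIN",
                 "CARBOPLATIN", "CISPLATIN", "CISPLATIN", "GEMCITABINE"),
    indications = "NON-SMALL CELL LUNG CANCER",
    reactions = list("ANAEMIA", "ANAEMIA", "NAUSEA", "ANAEMIA",
                     "NAUSEA", "RASH"))
}

toy_spec <- function(years = 2010) {
  cohort_spec("NON-SMALL CELL LUNG CANCER", "CARBOPLATIN", "ANAEMIA",
              years = years)
}
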