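#' Per-stratum reporting odds ratio
#'
#' Computes, for each stratum table, the reporting odds ratio
#' `ROR = (a*d)/(b*c)`, its natural-log value `y`, the Woolf variance
#' `v = 1/a + 1/b + 1/c + 1/d`, and the Wald confidence interval
#' `exp(y +/- z * sqrt(v))` at the requested level (z is the standard
#' normal `1 - alpha/2` quantile, 1.959964 for 95%).
#'
#' All four cells must be strictly positive: apply [continuity_correct()]
#' first. Strata whose raw table had an empty exposure or control arm are
#' rejected — their corrected estimate carries no information.
#'
#' @param tables a `stratum_tables` data frame.
#' @param level confidence level, default 0.95.
#' @return an `effect_estimates` data frame with columns `stratum`, `y`,
#'   `v`, `ror`, `ci_low`, `ci_high` and a `level` attribute.
#' @examples
#' t <- data.frame(stratum = 2010, a = 10, b = 90, c = 10, d = 890,
#'                 corrected = FALSE)
#' effect_estimate(t)
#' @export
effect_estimate <- function(tables, level = 0.95) {
  stopifnot(is.numeric(level), level > 0, level < 1)
  with(tables, {
    if (any(a <= 0 | b <= 0 | c <= 0 | d <= 0))
      stop("all cells must be > 0; apply continuity_correct() first")
    arm_empty <- corrected & ((a == 0.5 & b == 0.5) | (c == 0.5 & d == 0.5))
    if (any(arm_empty))
      stop(sprintf("stratum %s has an empty exposure or control arm",
                   paste(stratum[arm_empty], collapse = ", ")))
    y <- log(a) + log(d) - log(b) - log(c)
    v <- 1 / a + 1 / b + 1 / c + 1 / d
    z <- qnorm(1 - (1 - level) / 2)
    out <- data.frame(stratum = stratum, y = y, v = v, ror = exp(y),
                      ci_low = exp(y - z * sqrt(v)),
                      ci_high = exp(y + z * sqrt(v)))
    attr(out, "level") <- level
    class(out) <- c("effect_estimates", "data.frame")
    out
  })
}

#' Disproportionality signal flag
#'
#' A reporting odds ratio significantly greater than 1.00 — that is, a
#' lower confidence bound strictly above 1 — flags an excess reporting
#' signal for the exposed arm.
#'
#' @param est an `effect_estimates` data frame (or any data frame with a
#'   `ci_low` column).
#' @return logical vector, one element per stratum.
#' @export
is_signal <- function(est) est$ci_low > 1.00
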