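#' Egger's linear regression test for funnel-plot asymmetry
#'
#' Classic formulation: the standardized effect `z_i = y_i / se_i` is
#' regressed on the precision `prec_i = 1 / se_i` by unweighted ordinary
#' least squares, and the intercept is tested against zero with a
#' Student-t statistic on `k - 2` degrees of freedom. Under no reporting
#' bias small and large strata scatter symmetrically and the intercept is
#' near zero; selective suppression of unfavourable small strata drags it
#' away from zero.
#'
#' @param estimates an `effect_estimates` data frame, `k >= 3` rows with
#'   non-constant precisions.
#' @param alpha asymmetry significance threshold, default 0.05.
#' @return an `egger_result` list: `intercept`, `se_intercept`, `slope`,
#'   `t`, `df`, `p`, `asymmetry` (logical flag `p < alpha`).
#' @export
egger_test <- function(estimates, alpha = 0.05) {
  k <- nrow(estimates)
  if (is.null(k) || k < 3L) stop("Egger's test requires at least 3 strata")
  se <- sqrt(estimates$v)
  z <- estimates$y / se
  prec <- 1 / se
  if (max(prec) - min(prec) < .Machine$double.eps * max(prec))
    stop("precisions are all equal; Egger regression is degenerate")
  fit <- lm(z ~ prec)
  s <- summary(fit)
  if (s$sigma == 0)
    stop("zero residual variance; degenerate (perfectly collinear) input")
  co <- s$coefficients
  t <- co["(Intercept)", "t value"]
  df <- k - 2L
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(intercept = co["(Intercept)", "Estimate"],
                 se_intercept = co["(Intercept)", "Std. Error"],
                 slope = co["prec", "Estimate"],
                 t = t, df = df, p = p, asymmetry = p < alpha),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf(
    "Egger's test: intercept = %.4f (se %.4f), t = %.3f on %d df, p = %.4g\n",
    x$intercept, x$se_intercept, x$t, x$df, x$p))
  cat(if (x$asymmetry) "Significant funnel-plot asymmetry (reporting bias)\n"
      else "No significant funnel-plot asymmetry\n")
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' One point per stratum: horizontal coordinate the log reporting odds
#' ratio, vertical coordinate its standard error. By convention the
#' vertical axis is drawn increasing downward, so precise strata sit at
#' the funnel's top. Rendering is left to the caller; this module only
#' emits coordinates.
#'
#' @param estimates a non-empty `effect_estimates` data frame.
#' @return a data frame with columns `stratum`, `effect`, `se`.
#' @export
funnel_coordinates <- function(estimates) {
  k <- nrow(estimates)
  if (is.null(k) || k < 1L) stop("no estimates supplied")
  data.frame(stratum = estimates$stratum, effect = estimates$y,
             se = sqrt(estimates$v))
}
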