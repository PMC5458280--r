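#' Cochran's Q test and heterogeneity statistics
#'
#' Fixed-effect inverse-variance weights `w_i = 1/v_i` give the weighted
#' mean `yhat = sum(w*y)/sum(w)` and `Q = sum(w * (y - yhat)^2)`, which is
#' chi-square with `k - 1` degrees of freedom under homogeneity. The
#' returned object also carries `I2 = 100 * (Q - df) / Q` (floored at 0,
#' and 0 when Q = 0) and the DerSimonian-Laird moment estimate of the
#' between-stratum variance `tau2` (see [dl_tau2()]).
#'
#' @param estimates an `effect_estimates` data frame with at least two rows.
#' @return a `heterogeneity_result` list: `Q`, `df`, `p`, `I2`, `tau2`, `k`.
#' @export
cochran_q <- function(estimates) {
  k <- nrow(estimates)
  if (is.null(k) || k < 2L) stop("heterogeneity requires at least 2 strata")
  y <- estimates$y; v <- estimates$v
  if (any(v <= 0)) stop("all variances must be > 0")
  w <- 1 / v
  yhat <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yhat)^2)
  df <- k - 1L
  structure(list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE),
                 I2 = i_squared(Q, df), tau2 = dl_tau2(estimates), k = k),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf(
    "Heterogeneity: Q = %.4f on %d df (p = %.4g), I2 = %.2f%%, tau2 = %.4f\n",
    x$Q, x$df, x$p, x$I2, x$tau2))
  invisible(x)
}

#' I-squared heterogeneity percentage
#'
#' `I2 = 100 * (Q - df) / Q`, the percentage of total variability across
#' strata attributable to between-stratum heterogeneity rather than
#' sampling error. Floored at 0 (and defined as 0 when Q = 0), so the
#' result lies in \[0, 100).
#'
#' @param Q Cochran's Q statistic (non-negative).
#' @param df degrees of freedom, `k - 1`.
#' @return percentage in \[0, 100).
#' @export
i_squared <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  if (Q == 0) return(0)
  max(0, 100 * (Q - df) / Q)
}

#' DerSimonian-Laird between-stratum variance
#'
#' Method-of-moments estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w_i = 1/v_i`.
#'
#' @param estimates an `effect_estimates` data frame with at least two rows.
#' @return non-negative between-stratum variance.
#' @export
dl_tau2 <- function(estimates) {
  k <- nrow(estimates)
  if (is.null(k) || k < 2L) stop("tau2 requires at least 2 strata")
  y <- estimates$y; v <- estimates$v
  w <- 1 / v
  yhat <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yhat)^2)
  max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

pooled_result <- function(model, y_pooled, se_pooled, k, het, level) {
  z <- y_pooled / se_pooled
  crit <- qnorm(1 - (1 - level) / 2)
  structure(list(model = model, y_pooled = y_pooled, se_pooled = se_pooled,
                 or_pooled = exp(y_pooled),
                 ci_low = exp(y_pooled - crit * se_pooled),
                 ci_high = exp(y_pooled + crit * se_pooled),
                 z = z, p = 2 * pnorm(-abs(z)), k = k, het = het,
                 level = level),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  label <- c(random_DL = "Random-effects (DerSimonian-Laird)",
             fixed_MH = "Fixed-effects (Mantel-Haenszel)")[[x$model]]
  cat(sprintf("%s meta-analysis, k = %d strata\n", label, x$k))
  cat(sprintf("Pooled ROR = %.4f, %d%% CI [%.4f, %.4f], z = %.3f, p = %.3g\n",
              x$or_pooled, round(100 * x$level), x$ci_low, x$ci_high,
              x$z, x$p))
  if (!is.null(x$het)) print(x$het)
  invisible(x)
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Pools per-stratum log odds ratios with weights
#' `w*_i = 1/(v_i + tau2)`, where `tau2` is the moment estimate of
#' [dl_tau2()]: `y_pooled = sum(w* y)/sum(w*)`, standard error
#' `1/sqrt(sum(w*))`. When `tau2 = 0` this collapses exactly to
#' inverse-variance fixed-effect pooling.
#'
#' @param estimates an `effect_estimates` data frame with at least two rows.
#' @param level confidence level, default 0.95.
#' @return a `pooled_result` with `model = "random_DL"`.
#' @export
pool_random_dl <- function(estimates, level = 0.95) {
  k <- nrow(estimates)
  if (is.null(k) || k < 2L) stop("pooling requires at least 2 strata")
  het <- cochran_q(estimates)
  w <- 1 / (estimates$v + het$tau2)
  y_pooled <- sum(w * estimates$y) / sum(w)
  pooled_result("random_DL", y_pooled, sqrt(1 / sum(w)), k, het, level)
}

#' Fixed-effects pooling (Mantel-Haenszel)
#'
#' Pools stratified 2x2 tables on the count scale:
#' `OR_MH = sum(a_i d_i / T_i) / sum(b_i c_i / T_i)` with `T_i` the stratum
#' total. The variance of `log OR_MH` uses the Robins-Breslow-Greenland
#' estimator, which is consistent both with sparse strata and with few
#' large strata. Raw (uncorrected) tables are the natural input; the MH
#' estimator itself tolerates zero cells as long as some `b_i c_i > 0`.
#'
#' Heterogeneity diagnostics require per-stratum estimates, so they are
#' computed from the continuity-corrected tables when `k >= 2` (otherwise
#' `het` is `NULL`).
#'
#' @param tables a `stratum_tables` data frame, `k >= 1` rows.
#' @param level confidence level, default 0.95.
#' @return a `pooled_result` with `model = "fixed_MH"`.
#' @export
pool_fixed_mh <- function(tables, level = 0.95) {
  k <- nrow(tables)
  if (is.null(k) || k < 1L) stop("pooling requires at least 1 stratum")
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  tot <- a + b + c + d
  R <- a * d / tot
  S <- b * c / tot
  if (sum(S) == 0) stop("all b*c products are zero; OR_MH undefined")
  if (sum(R) == 0) stop("all a*d products are zero; OR_MH undefined")
  y_pooled <- log(sum(R)) - log(sum(S))
  P <- (a + d) / tot
  Q <- (b + c) / tot
  v <- sum(P * R) / (2 * sum(R)^2) +
    (sum(P * S) + sum(Q * R)) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  het <- if (k >= 2L) {
    corr <- if (any(tables$corrected)) tables else continuity_correct(tables)
    usable <- usable_strata(tables)
    if (sum(usable) >= 2L)
      cochran_q(effect_estimate(corr[usable, , drop = FALSE], level))
    else NULL
  } else NULL
  pooled_result("fixed_MH", y_pooled, sqrt(v), k, het, level)
}

#' Choose the pooling model from the heterogeneity test
#'
#' Significant heterogeneity (Q-test p-value strictly below `alpha`)
#' selects the random-effects DerSimonian-Laird model; otherwise the
#' fixed-effects Mantel-Haenszel model is used.
#'
#' @param het a `heterogeneity_result` from [cochran_q()].
#' @param alpha significance threshold, default 0.05.
#' @return `"random_DL"` or `"fixed_MH"`.
#' @export
select_model <- function(het, alpha = 0.05) {
  if (het$p < alpha) "random_DL" else "fixed_MH"
}

#' Leave-one-out sensitivity analysis
#'
#' Deletes one stratum at a time and re-pools the remainder under the SAME
#' model family as the full analysis (the model is a fixed perturbation
#' target, not re-selected per subset). A pooled estimate whose lower
#' confidence bound stays above 1.00 for every deletion indicates a signal
#' robust to any single year.
#'
#' @param estimates an `effect_estimates` data frame, `k >= 3` rows.
#' @param model `"random_DL"` or `"fixed_MH"`.
#' @param level confidence level, default 0.95.
#' @param tables the matching `stratum_tables` (required for
#'   `model = "fixed_MH"`, which pools on the count scale).
#' @return a `loo_result` data frame: `left_out`, `model`, `or_pooled`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
leave_one_out <- function(estimates, model = c("random_DL", "fixed_MH"),
                          level = 0.95, tables = NULL) {
  model <- match.arg(model)
  k <- nrow(estimates)
  if (is.null(k) || k < 3L)
    stop("leave-one-out requires at least 3 strata")
  if (model == "fixed_MH") {
    if (is.null(tables)) stop("fixed_MH leave-one-out requires 'tables'")
    tables <- tables[match(estimates$stratum, tables$stratum), , drop = FALSE]
  }
  rows <- lapply(seq_len(k), function(i) {
    pr <- if (model == "random_DL")
      pool_random_dl(estimates[-i, , drop = FALSE], level)
    else
      pool_fixed_mh(tables[-i, , drop = FALSE], level)
    data.frame(left_out = estimates$stratum[[i]], model = model,
               or_pooled = pr$or_pooled, ci_low = pr$ci_low,
               ci_high = pr$ci_high, p = pr$p)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loo_result", "data.frame")
  out
}
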