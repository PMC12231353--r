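# Reported statistics: regression metrics, classification accuracy tables
# and Welch two-sample t-tests.

#' Regression metrics for surrogate evaluation
#'
#' `r2 = 1 - SS_res / SS_tot` with residuals `y_pred - y_true`; `slope` is
#' the ordinary least-squares slope of `y_pred` regressed on `y_true` (with
#' intercept); `rmse_ustrain` the root-mean-square residual; `rmse_pct` the
#' RMSE as a percentage of the observed range of `y_true`.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 3); `y_true` must
#'   not be constant.
#' @return List with `r2`, `slope`, `rmse_ustrain`, `rmse_pct`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  if (max(y_true) == min(y_true))
    stop("R^2 undefined: y_true is constant", call. = FALSE)
  res <- y_pred - y_true
  ss_res <- sum(res^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  slope <- sum((y_true - mean(y_true)) * (y_pred - mean(y_pred))) / ss_tot
  rmse <- sqrt(mean(res^2))
  list(r2 = 1 - ss_res / ss_tot, slope = slope, rmse_ustrain = rmse,
       rmse_pct = 100 * rmse / (max(y_true) - min(y_true)))
}

#' Classification accuracy table
#'
#' Percentage of true and false predictions of a binary label.
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return List with `pct_true`, `pct_error`.
#' @export
classification_table <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  pct <- 100 * mean(as.integer(y_true) == as.integer(y_pred))
  list(pct_true = pct, pct_error = 100 - pct)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Satterthwaite degrees of freedom
#' (delegated to [stats::t.test()]).
#'
#' @param a,b Numeric samples, each of length >= 2 with positive variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0)
    stop("degenerate variance: both samples constant", call. = FALSE)
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

# Welch test from summary statistics (means, variances, counts), for the
# streamed heatmap where raw samples are never materialized.
welch_from_stats <- function(m1, v1, n1, m2, v2, n2) {
  if (n1 < 2 || n2 < 2 || (v1 <= 0 && v2 <= 0))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}
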