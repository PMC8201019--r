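#' Regression accuracy report
#'
#' Computes the standard chemometric accuracy metrics for a prediction:
#' coefficient of determination `R2 = 1 - SS_res / SS_tot`, root mean
#' square error (1/n denominator), mean absolute percentage error
#' `MAPE = 100 * mean(|y - yhat| / |y|)`, and the residual prediction
#' deviation `RPD = sd(y_obs) / RMSE` with the sample (n - 1) standard
#' deviation, together with its predictability class (see [rpd_class()]).
#' Zero observed values are excluded from the MAPE with a warning; a
#' perfect prediction reports `RPD = Inf`.
#'
#' @param y_obs observed values (g/kg), length >= 2, non-constant.
#' @param y_pred predicted values, same length.
#' @return A list of class `eval_report`: `r2`, `rmse`, `mape`, `rpd`,
#'   `rpd_class`, `n`.
#' @examples
#' prediction_metrics(c(10, 20, 30), c(12, 18, 33))
#' @export
prediction_metrics <- function(y_obs, y_pred) {
  y_obs <- as.numeric(y_obs); y_pred <- as.numeric(y_pred)
  n <- length(y_obs)
  if (n < 2L || length(y_pred) != n)
    stop("'y_obs' and 'y_pred' must have equal length >= 2")
  if (stats::sd(y_obs) < .Machine$double.eps)
    stop("'y_obs' is constant; R2 and RPD are undefined")
  res <- y_obs - y_pred
  rmse <- sqrt(mean(res^2))
  r2 <- 1 - sum(res^2) / sum((y_obs - mean(y_obs))^2)
  nz <- y_obs != 0
  if (!all(nz))
    warning(sum(!nz), " zero observed value(s) excluded from MAPE")
  mape <- if (any(nz)) 100 * mean(abs(res[nz] / y_obs[nz])) else NA_real_
  rpd <- if (rmse == 0) Inf else stats::sd(y_obs) / rmse
  structure(list(r2 = r2, rmse = rmse, mape = mape, rpd = rpd,
                 rpd_class = rpd_class(rpd), n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report (n = %d): R2 = %.3f, RMSE = %.3f g/kg, MAPE = %.1f%%, RPD = %.2f (%s)\n",
    x$n, x$r2, x$rmse, x$mape, x$rpd, x$rpd_class))
  invisible(x)
}

#' Predictability class from the residual prediction deviation
#'
#' Maps an RPD value to the conventional three-class scale: above 2 the
#' model is considered capable of accurate prediction, between 1.4 and 2
#' moderately predictive, and at or below 1.4 poorly predictive. Boundary
#' values are assigned downward (RPD = 2 is "moderate", RPD = 1.4 is
#' "poor").
#'
#' @param rpd numeric vector of nonnegative RPD values.
#' @return Character vector with levels "accurate", "moderate", "poor".
#' @export
rpd_class <- function(rpd) {
  rpd <- as.numeric(rpd)
  if (any(rpd < 0, na.rm = TRUE)) stop("'rpd' must be nonnegative")
  ifelse(rpd > 2, "accurate", ifelse(rpd > 1.4, "moderate", "poor"))
}

#' Stratified train/test split on a target variable
#'
#' Ranks the samples by target value, cuts them into equal-frequency
#' strata, and draws the test set within each stratum so the split
#' preserves the target distribution. The overall test count is
#' `floor(test_fraction * n)` (68 samples at 20% give the conventional
#' 55/13 split); per-stratum quotas are allotted proportionally with
#' largest remainders.
#'
#' @param targets numeric target values, length n.
#' @param test_fraction fraction of samples held out, in (0, 1).
#' @param n_bins number of equal-frequency strata (default 5).
#' @param seed optional integer seed.
#' @return List with sorted integer vectors `train` and `test`, a
#'   disjoint, exhaustive partition of `1..n`.
#' @export
stratified_split <- function(targets, test_fraction = 0.2, n_bins = 5L,
                             seed = NULL) {
  targets <- as.numeric(targets)
  n <- length(targets)
  n_bins <- as.integer(n_bins)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must be in (0, 1)")
  if (n < n_bins || n_bins < 2L) stop("need n >= n_bins >= 2")
  n_test <- floor(test_fraction * n)
  if (n_test < 1L) stop("test fraction yields an empty test set")
  ord <- order(targets, seq_len(n))        # stable ranking
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  strata <- split(ord, rep(seq_len(n_bins), sizes))
  # proportional quotas, largest remainders
  ideal <- n_test * sizes / n
  quota <- floor(ideal)
  short <- n_test - sum(quota)
  if (short > 0) {
    bump <- order(ideal - quota, decreasing = TRUE)[seq_len(short)]
    quota[bump] <- quota[bump] + 1L
  }
  quota <- pmin(quota, sizes)
  deficit <- n_test - sum(quota)
  if (deficit > 0) {                       # redistribute if a stratum capped
    room <- sizes - quota
    for (b in order(room, decreasing = TRUE)) {
      take <- min(deficit, room[b]); quota[b] <- quota[b] + take
      deficit <- deficit - take
      if (deficit == 0) break
    }
  }
  test <- with_seed(seed, unlist(mapply(function(s, q) {
    if (q == 0L) integer(0) else s[sample.int(length(s), q)]
  }, strata, quota, SIMPLIFY = FALSE), use.names = FALSE))
  list(train = sort(setdiff(seq_len(n), test)), test = sort(test))
}
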