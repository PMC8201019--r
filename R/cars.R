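#' Exponentially decreasing retention schedule
#'
#' Fraction of wavelength variables retained at a given CARS sampling run.
#' The schedule `r_i = mu * exp(-k * i)` is pinned by two boundary
#' conditions: all `p` variables are in play at the first run
#' (`r_1 = 1`) and only two remain at the last (`r_N = 2/p`), which fixes
#' `k = log(p/2) / (N - 1)` and `mu = exp(k)`.
#'
#' @param run_index run number `i`, `1 <= i <= n_runs`.
#' @param n_runs total number of sampling runs `N`.
#' @param p total number of candidate variables, >= 2.
#' @return Retention fraction in (0, 1].
#' @export
edf_retention <- function(run_index, n_runs, p) {
  run_index <- as.integer(run_index); n_runs <- as.integer(n_runs)
  p <- as.integer(p)
  if (p < 2L) stop("'p' must be >= 2")
  if (n_runs < 2L) stop("'n_runs' must be >= 2")
  if (any(run_index < 1L) || any(run_index > n_runs))
    stop("'run_index' must lie in [1, n_runs]")
  k <- log(p / 2) / (n_runs - 1)
  mu <- exp(k)
  mu * exp(-k * run_index)
}

# retained variable count implied by the EDF at run i (never below 2)
edf_count <- function(run_index, n_runs, p) {
  pmax(2L, as.integer(round(edf_retention(run_index, n_runs, p) * p)))
}

#' Adaptive reweighted sampling
#'
#' Weighted random draw of variables with probability proportional to
#' their weights (in CARS, the absolute PLSR regression coefficients).
#' With `replace = FALSE` (default) exactly `count` distinct variables are
#' returned; with `replace = TRUE` the draw is a `count`-fold weighted
#' bootstrap collapsed to its distinct outcomes, the competitive
#' "survival of the fittest" variant. Zero-weight variables are never
#' selected.
#'
#' @param weights nonnegative weights, one per candidate variable.
#' @param count number of draws; with `replace = FALSE` it must not exceed
#'   the number of positive weights.
#' @param replace bootstrap-style sampling with replacement?
#' @param seed optional integer seed.
#' @return Sorted integer vector of selected variable indices.
#' @export
ars_sample <- function(weights, count, replace = FALSE, seed = NULL) {
  weights <- as.numeric(weights)
  if (any(weights < 0) || anyNA(weights)) stop("weights must be nonnegative")
  npos <- sum(weights > 0)
  if (npos == 0L) stop("all weights are zero")
  count <- as.integer(count)
  if (count < 1L) stop("'count' must be positive")
  if (!replace && count > npos)
    stop("'count' exceeds the number of positive weights")
  idx <- with_seed(seed, {
    if (replace) unique(sample.int(length(weights), count, replace = TRUE,
                                   prob = weights))
    else sample.int(length(weights), count, replace = FALSE, prob = weights)
  })
  sort(idx)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Wavelength screening by Monte-Carlo PLSR. Each sampling run (i) fits a
#' PLSR model on a random calibration subset restricted to the currently
#' retained bands, (ii) applies the enforced exponentially-decreasing
#' reduction, keeping the top bands ranked by absolute regression
#' coefficient, (iii) competitively resamples among the survivors by
#' adaptive reweighted sampling, and (iv) scores the resulting subset by
#' k-fold cross-validated RMSE (RMSECV, minimized over the PLSR component
#' count). The subset with the lowest RMSECV over all runs is returned.
#'
#' @param X a [spectra_matrix] or plain n x p matrix.
#' @param y numeric response of length n.
#' @param n_runs number of sampling runs (default 50).
#' @param mc_fraction fraction of samples drawn for each Monte-Carlo
#'   calibration subset (default 0.8).
#' @param max_components upper bound on PLSR components (default 10).
#' @param cv_folds folds for RMSECV (default 5).
#' @param ars_replace use the bootstrap ("multiset") ARS variant inside
#'   the competitive step (default TRUE, the classic algorithm).
#' @param seed optional integer seed; fixes subsets, folds and draws.
#' @return A list of class `selection_result` (see [cars_spa()]) whose
#'   `diagnostics$trace` is a `cars_trace`: per-run `variable_counts`,
#'   `rmsecv`, `n_components`, `subsets`, and `best_run`.
#' @export
cars <- function(X, y, n_runs = 50L, mc_fraction = 0.8,
                 max_components = 10L, cv_folds = 5L,
                 ars_replace = TRUE, seed = NULL) {
  wl <- if (inherits(X, "spectra_matrix")) X$wavelengths else NULL
  Xm <- if (inherits(X, "spectra_matrix")) X$values else as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(Xm); p <- ncol(Xm)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (p < 2L) stop("need at least 2 candidate bands")
  if (n < cv_folds || cv_folds < 2L) stop("need n >= cv_folds >= 2")
  if (mc_fraction <= 0 || mc_fraction > 1) stop("'mc_fraction' in (0, 1]")
  n_runs <- as.integer(n_runs)

  with_seed(seed, {
    retained <- seq_len(p)
    counts <- integer(n_runs); rmsecv <- numeric(n_runs)
    ncomps <- integer(n_runs); subsets <- vector("list", n_runs)
    n_cal <- max(2L, round(mc_fraction * n))
    for (i in seq_len(n_runs)) {
      cal <- sample.int(n, n_cal)
      maxc <- min(max_components, length(retained), n_cal - 1L)
      fit <- plsr_fit(Xm[cal, retained, drop = FALSE], y[cal], maxc)
      w <- abs(fit$coefficients)
      target <- min(edf_count(i, n_runs, p), length(retained))
      # enforced EDF reduction: keep the top 'target' by |coefficient|
      ord <- order(w, decreasing = TRUE)
      survivors <- retained[sort(ord[seq_len(target)])]
      w_surv <- w[sort(ord[seq_len(target)])]
      # competitive adaptive reweighted sampling among survivors
      if (all(w_surv == 0)) w_surv[] <- 1
      n_draw <- if (ars_replace) target else min(target, sum(w_surv > 0))
      pick <- ars_sample(pmax(w_surv, 0), n_draw, replace = ars_replace)
      if (length(pick) < 2L) {                 # keep the subset viable
        extra <- setdiff(order(w_surv, decreasing = TRUE), pick)
        pick <- sort(c(pick, extra[seq_len(2L - length(pick))]))
      }
      retained <- survivors[pick]
      curve <- plsr_rmsecv(Xm[, retained, drop = FALSE], y,
                           min(max_components, length(retained)), cv_folds)
      counts[i] <- length(retained)
      rmsecv[i] <- min(curve)
      ncomps[i] <- which.min(curve)
      subsets[[i]] <- retained
    }
    best <- which.min(rmsecv)
    trace <- structure(list(n_runs = n_runs, variable_counts = counts,
                            rmsecv = rmsecv, n_components = ncomps,
                            subsets = subsets, best_run = best),
                       class = "cars_trace")
    selection_result("cars", subsets[[best]], wl,
                     diagnostics = list(trace = trace))
  })
}

#' @export
print.cars_trace <- function(x, ...) {
  cat("cars_trace:", x$n_runs, "runs; best run", x$best_run, "with",
      x$variable_counts[x$best_run], "variables, RMSECV =",
      format(min(x$rmsecv), digits = 4), "\n")
  invisible(x)
}

#' Plot a CARS screening trace
#'
#' Two-panel base-graphics view of a CARS run: retained-variable count and
#' the RMSECV curve against the sampling run, with the best run marked.
#'
#' @param x a `cars_trace` (from `cars(...)$diagnostics$trace`).
#' @param ... passed to `plot`.
#' @export
plot.cars_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  runs <- seq_len(x$n_runs)
  plot(runs, x$variable_counts, type = "s", xlab = "sampling run",
       ylab = "retained bands", ...)
  plot(runs, x$rmsecv, type = "l", xlab = "sampling run",
       ylab = "RMSECV (g/kg)", ...)
  graphics::abline(v = x$best_run, lty = 2)
  invisible(x)
}

# shared container for band selections
selection_result <- function(method, indices, wavelengths = NULL,
                             diagnostics = list()) {
  indices <- sort(unique(as.integer(indices)))
  structure(list(method = method, band_indices = indices,
                 wavelengths_nm = if (!is.null(wavelengths))
                   wavelengths[indices] else NULL,
                 diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result (", x$method, "): ", length(x$band_indices),
      " bands", sep = "")
  if (!is.null(x$wavelengths_nm))
    cat(" [", format(min(x$wavelengths_nm), trim = TRUE), "-",
        format(max(x$wavelengths_nm), trim = TRUE), " nm]", sep = "")
  cat("\n")
  invisible(x)
}
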