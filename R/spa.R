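#' Successive projections algorithm
#'
#' Forward variable selection that minimizes collinearity: starting from
#' each candidate column in turn, the chain grows by repeatedly adding the
#' candidate with the largest projection norm onto the orthogonal
#' complement of the span of the columns already chosen. Every prefix
#' `(start, N)` with `n_min <= N <= n_max` is then scored by the
#' leave-one-out RMSE of a multiple linear regression (with intercept) of
#' the response on the chain, and the chain with minimal RMSE wins (ties:
#' fewer variables, then lower starting index). Exactly collinear columns
#' (projection norm below tolerance) are skipped.
#'
#' @param X a [spectra_matrix] or matrix restricted to the candidate bands.
#' @param y numeric response, length n; n must exceed `n_max + 1` so the
#'   evaluation regressions are solvable.
#' @param n_max largest chain length to consider.
#' @param n_min smallest chain length to consider (default 1).
#' @param center column-center the candidates before the projections
#'   (default TRUE), so the chain order reflects variance structure
#'   rather than the shared mean reflectance level. The evaluation
#'   regression carries an intercept either way.
#' @return A `selection_result` with `method = "spa"`; `diagnostics$chain`
#'   holds the winning chain in selection order and `diagnostics$rmse`
#'   the (start, N) score table.
#' @export
spa <- function(X, y, n_max, n_min = 1L, center = TRUE) {
  wl <- if (inherits(X, "spectra_matrix")) X$wavelengths else NULL
  Xm <- if (inherits(X, "spectra_matrix")) X$values else as.matrix(X)
  if (center) Xm <- scale(Xm, center = TRUE, scale = FALSE)
  y <- as.numeric(y)
  n <- nrow(Xm); p <- ncol(Xm)
  n_max <- as.integer(n_max); n_min <- as.integer(n_min)
  if (p < n_max || n_max < n_min || n_min < 1L)
    stop("need candidate count >= n_max >= n_min >= 1")
  if (n <= n_max + 1L)
    stop("need n > n_max + 1 for the evaluation regression")
  best <- list(rmse = Inf, chain = NULL, N = NA_integer_, start = NA_integer_)
  score <- vector("list", p)
  for (start in seq_len(p)) {
    chain <- spa_chain(Xm, start, n_max)
    if (length(chain) < n_min) next
    rmses <- rep(NA_real_, length(chain))
    for (N in n_min:length(chain)) {
      r <- loo_rmse(Xm[, chain[seq_len(N)], drop = FALSE], y)
      rmses[N] <- r
      if (is.finite(r) &&
          (r < best$rmse - 1e-12 ||
           (abs(r - best$rmse) <= 1e-12 &&
            (N < best$N || (N == best$N && start < best$start))))) {
        best <- list(rmse = r, chain = chain[seq_len(N)], N = N,
                     start = start)
      }
    }
    score[[start]] <- rmses
  }
  if (is.null(best$chain)) stop("SPA found no solvable chain")
  selection_result("spa", best$chain, wl,
                   diagnostics = list(chain = best$chain,
                                      start = best$start,
                                      rmse = best$rmse,
                                      rmse_table = score))
}

# greedy projection chain from a fixed starting column
spa_chain <- function(Xm, start, n_max, tol = 1e-10) {
  p <- ncol(Xm)
  norms0 <- sqrt(colSums(Xm^2))
  if (norms0[start] < tol) return(integer(0))
  chain <- start
  Q <- Xm[, start, drop = FALSE] / norms0[start]   # orthonormal basis
  R <- Xm                                          # residual columns
  R <- R - Q %*% crossprod(Q, Xm)
  while (length(chain) < n_max) {
    rn <- sqrt(colSums(R^2))
    rn[chain] <- -Inf
    rn[norms0 < tol] <- -Inf
    # skip exactly collinear candidates
    rn[rn < tol * pmax(norms0, 1)] <- -Inf
    j <- which.max(rn)
    if (!is.finite(rn[j])) break
    qn <- R[, j] / sqrt(sum(R[, j]^2))
    chain <- c(chain, j)
    Q <- cbind(Q, qn)
    R <- R - qn %*% crossprod(qn, R)
  }
  chain
}

# leave-one-out RMSE of lm(y ~ X) via the hat-matrix shortcut
loo_rmse <- function(Xsub, y) {
  A <- cbind(1, Xsub)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) return(Inf)
  h <- rowSums(qr.Q(qrA)^2)
  res <- y - A %*% qr.coef(qrA, y)
  if (any(1 - h < 1e-10)) return(Inf)
  sqrt(mean((res / (1 - h))^2))
}

#' Coupled CARS-SPA wavelength selection
#'
#' Two-stage screening: [cars()] first selects a primary subset of bands
#' sensitive to the response; [spa()] then performs a secondary screening
#' on that subset to eliminate collinear bands. Returned indices refer to
#' the original band grid.
#'
#' @param X a [spectra_matrix] or n x p matrix.
#' @param y numeric response.
#' @param cars_params named list of arguments for [cars()].
#' @param spa_params named list of arguments for [spa()]; `n_max`
#'   defaults to `min(CARS subset size, n - 3)`, leaving the chain length
#'   to the RMSE criterion.
#' @param seed optional integer seed (passed to CARS).
#' @return A `selection_result` with `method = "cars_spa"`; diagnostics
#'   carry both the CARS trace and the SPA score table.
#' @export
cars_spa <- function(X, y, cars_params = list(), spa_params = list(),
                     seed = NULL) {
  wl <- if (inherits(X, "spectra_matrix")) X$wavelengths else NULL
  Xm <- if (inherits(X, "spectra_matrix")) X$values else as.matrix(X)
  y <- as.numeric(y)
  cars_res <- do.call(cars, c(list(X = Xm, y = y, seed = seed), cars_params))
  idx <- cars_res$band_indices
  if (length(idx) < 2L)
    return(selection_result("cars_spa", idx, wl,
                            diagnostics = cars_res$diagnostics))
  n_max <- spa_params$n_max
  if (is.null(n_max)) n_max <- min(length(idx), nrow(Xm) - 3L)
  n_max <- min(n_max, length(idx))
  spa_params$n_max <- n_max
  spa_res <- do.call(spa, c(list(X = Xm[, idx, drop = FALSE], y = y),
                            spa_params))
  final <- idx[spa_res$band_indices]
  selection_result("cars_spa", final, wl,
                   diagnostics = list(trace = cars_res$diagnostics$trace,
                                      cars_indices = idx,
                                      spa = spa_res$diagnostics))
}
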