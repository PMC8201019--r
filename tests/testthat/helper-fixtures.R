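# Shared fixture builders and independent oracles.

# random spectra on a uniform grid
random_spectra <- function(n = 4, m = 10, seed = 1, lo = 400, step = 4) {
  set.seed(seed)
  spectra_matrix(matrix(runif(n * m, 0.1, 0.9), n, m),
                 seq(lo, by = step, length.out = m))
}

# small random cube
random_cube <- function(rows = 8, cols = 8, bands = 3, seed = 1,
                        mask = NULL) {
  set.seed(seed)
  hypercube(array(runif(rows * cols * bands, 0.1, 0.9),
                  c(rows, cols, bands)),
            seq(500, by = 10, length.out = bands), mask = mask)
}

# brute-force sigma filter: literal per-pixel double loop over the window
brute_sigma_filter <- function(mat, mask, window, sigma_mult) {
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- (window - 1) %/% 2
  out <- mat
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    ii <- max(1, i - pad):min(nr, i + pad)
    jj <- max(1, j - pad):min(nc, j + pad)
    vals <- c();
    for (a in ii) for (b in jj) if (mask[a, b]) vals <- c(vals, mat[a, b])
    if (length(vals) < 2) next
    s <- sd(vals)
    incl <- vals[abs(vals - mat[i, j]) <= sigma_mult * s]
    if (length(incl) > 0) out[i, j] <- mean(incl)
  }
  out
}

# textbook OLS slope/intercept of y on x
ols_slope_intercept <- function(x, y) {
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = a, intercept = mean(y) - a * mean(x))
}

# exhaustive SPA oracle: rebuild every projection chain with explicit
# Gram-Schmidt loops and score every (start, N) prefix by refit-LOO RMSE
spa_oracle <- function(X, y, n_max, n_min = 1, center = TRUE) {
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  p <- ncol(X); n <- nrow(X)
  best <- list(rmse = Inf, chain = NULL)
  for (start in seq_len(p)) {
    if (sqrt(sum(X[, start]^2)) < 1e-10) next
    chain <- start
    while (length(chain) < n_max) {
      B <- X[, chain, drop = FALSE]
      nrm <- rep(-Inf, p)
      for (j in setdiff(seq_len(p), chain)) {
        # residual of x_j after projecting out span(B)
        r <- X[, j] - B %*% qr.coef(qr(B), X[, j])
        v <- sqrt(sum(r^2))
        if (v >= 1e-10 * max(sqrt(sum(X[, j]^2)), 1)) nrm[j] <- v
      }
      if (all(!is.finite(nrm))) break
      chain <- c(chain, which.max(nrm))
    }
    for (N in n_min:length(chain)) {
      sub <- chain[seq_len(N)]
      # literal leave-one-out refits
      errs <- vapply(seq_len(n), function(i) {
        df_tr <- data.frame(y = y[-i], X[-i, sub, drop = FALSE])
        df_te <- data.frame(X[i, sub, drop = FALSE])
        names(df_tr)[-1] <- names(df_te) <- paste0("v", seq_along(sub))
        fit <- lm(y ~ ., data = df_tr)
        y[i] - predict(fit, df_te)
      }, numeric(1))
      r <- sqrt(mean(errs^2))
      if (is.finite(r) && r < best$rmse - 1e-12) {
        best <- list(rmse = r, chain = sub)
      }
    }
  }
  best
}
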