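#' Fit a partial least squares regression model
#'
#' PLS1 regression by the NIPALS algorithm with mean centering only (no
#' unit-variance scaling), the usual convention in chemometrics for
#' reflectance spectra. Latent components are extracted until the
#' requested count or until the residual covariance collapses.
#'
#' @param X numeric matrix n x p of predictors (e.g. reflectance bands).
#' @param y numeric response of length n (e.g. SOM in g/kg).
#' @param n_components number of latent components, between 1 and
#'   `min(n - 1, p)`.
#' @return An object of class `plsr_model` with elements `coefficients`
#'   (length p), `x_mean`, `y_mean`, `weights`, `loadings`, `y_loadings`,
#'   `n_components` (number actually extracted), `fitted.values`.
#' @seealso [predict.plsr_model()], [plsr_cv_ncomp()]
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- X %*% c(1, -2, 0.5) + rnorm(20, sd = .1)
#' fit <- plsr_fit(X, y, 2)
#' head(predict(fit, X))
#' @export
plsr_fit <- function(X, y, n_components) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2L) stop("need at least 2 samples")
  if (stats::sd(y) < .Machine$double.eps) stop("'y' has zero variance")
  A <- as.integer(n_components)
  if (A < 1L || A > min(n - 1L, p))
    stop("'n_components' must be between 1 and min(n - 1, p) = ",
         min(n - 1L, p))
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  a <- 0L
  for (comp in seq_len(A)) {
    w <- crossprod(E, f)                       # p x 1
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break                      # residual covariance exhausted
    w <- w / wn
    t_scores <- E %*% w
    tt <- sum(t_scores^2)
    if (tt < 1e-28) break
    p_load <- crossprod(E, t_scores) / tt
    q_load <- sum(f * t_scores) / tt
    E <- E - t_scores %*% t(p_load)
    f <- f - q_load * t_scores
    a <- comp
    W[, a] <- w; P[, a] <- p_load; q[a] <- q_load
  }
  if (a == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  B <- W %*% solve(crossprod(P, W), q)         # p x 1 coefficient vector
  fit <- structure(list(coefficients = as.vector(B), x_mean = x_mean,
                        y_mean = y_mean, weights = W, loadings = P,
                        y_loadings = q, n_components = a,
                        algorithm = "nipals-pls1-centered"),
                   class = "plsr_model")
  fit$fitted.values <- predict(fit, X)
  fit$residuals <- y - fit$fitted.values
  fit
}

#' Predict from a PLSR model
#'
#' @param object a [plsr_fit()] model.
#' @param newdata numeric matrix with the same column count as training.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_mean))
  as.vector(sweep(newdata, 2, object$x_mean) %*% object$coefficients +
              object$y_mean)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("plsr_model:", x$n_components, "components over",
      length(x$coefficients), "predictors (", x$algorithm, ")\n")
  invisible(x)
}

#' @export
coef.plsr_model <- function(object, ...) object$coefficients

#' @export
residuals.plsr_model <- function(object, ...) object$residuals

# k-fold RMSECV curve for PLSR: vector indexed by component count.
# Folds are assigned by a seeded shuffle when seed is given, else by the
# current RNG stream.
plsr_rmsecv <- function(X, y, max_components, cv_folds = 5L, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L || cv_folds > n) stop("'cv_folds' must be in [2, n]")
  maxc <- min(as.integer(max_components), ncol(X))
  fold <- with_seed(seed,
                    sample(rep(seq_len(cv_folds), length.out = n)))
  # cap by the smallest training fold
  maxc <- min(maxc, n - max(tabulate(fold, cv_folds)) - 1L)
  if (maxc < 1L) stop("not enough samples per fold for even 1 component")
  press <- matrix(NA_real_, cv_folds, maxc)
  for (k in seq_len(cv_folds)) {
    tr <- fold != k
    if (stats::sd(y[tr]) < .Machine$double.eps)
      stop("cross-validation fold with constant response")
    fit <- plsr_fit(X[tr, , drop = FALSE], y[tr], maxc)
    for (a in seq_len(maxc)) {
      sub <- truncate_plsr(fit, a)
      pred <- predict(sub, X[!tr, , drop = FALSE])
      press[k, a] <- sum((y[!tr] - pred)^2)
    }
  }
  sqrt(colSums(press) / n)
}

# reduce a fitted plsr_model to its first a components
truncate_plsr <- function(fit, a) {
  if (a >= fit$n_components) return(fit)
  W <- fit$weights[, seq_len(a), drop = FALSE]
  P <- fit$loadings[, seq_len(a), drop = FALSE]
  q <- fit$y_loadings[seq_len(a)]
  B <- W %*% solve(crossprod(P, W), q)
  out <- fit
  out$coefficients <- as.vector(B)
  out$weights <- W; out$loadings <- P; out$y_loadings <- q
  out$n_components <- a
  out
}

#' Choose the PLSR component count by cross-validation
#'
#' Runs k-fold cross-validation for component counts `1..max_components`
#' and returns the count with minimal RMSECV (ties go to the smaller
#' count).
#'
#' @param X,y training data.
#' @param max_components largest component count to consider.
#' @param cv_folds number of folds (default 5).
#' @param seed optional integer controlling the fold assignment.
#' @return Integer component count.
#' @export
plsr_cv_ncomp <- function(X, y, max_components, cv_folds = 5L, seed = NULL) {
  rmsecv <- plsr_rmsecv(X, y, max_components, cv_folds, seed)
  which.min(rmsecv)
}
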