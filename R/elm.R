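#' Fit an extreme learning machine
#'
#' Single-hidden-layer feed-forward network with randomly drawn input
#' weights and hidden biases. Inputs are rescaled feature-wise to
#' \[-1, 1\] using the training ranges (stored in the model). The hidden
#' activations are `H = g(Xs W' + b)` and the output weights are the
#' minimum-norm least-squares solution `beta = pinv(H) y` via the
#' Moore-Penrose generalized inverse (SVD).
#'
#' @param X numeric matrix n x p of predictors.
#' @param y numeric response of length n.
#' @param n_hidden number of hidden neurons L (default 20).
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @param weights optional L x p input-weight matrix; drawn uniformly from
#'   \[-1, 1\] when NULL.
#' @param biases optional length-L hidden bias vector; drawn uniformly
#'   from \[-1, 1\] when NULL.
#' @param scaling optional 2 x p matrix (rows lo, hi) fixing the input
#'   scaling; computed from `X` column ranges when NULL.
#' @param seed optional integer seed for the random draw.
#' @return An object of class `elm_model`: `input_weights`,
#'   `hidden_biases`, `output_weights`, `activation`, `input_scaling`,
#'   `fitted.values`, `residuals`.
#' @examples
#' X <- matrix(rnorm(100), 25, 4); y <- sin(X[, 1]) + rnorm(25, sd = .05)
#' fit <- elm_fit(X, y, n_hidden = 15, seed = 1)
#' print(fit)
#' @export
elm_fit <- function(X, y, n_hidden = 20L, activation = c("sigmoid", "tanh"),
                    weights = NULL, biases = NULL, scaling = NULL,
                    seed = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  activation <- match.arg(activation)
  L <- as.integer(n_hidden)
  if (L < 1L) stop("'n_hidden' must be >= 1")
  if (is.null(scaling)) {
    scaling <- rbind(lo = apply(X, 2, min), hi = apply(X, 2, max))
  }
  with_seed(seed, {
    if (is.null(weights)) weights <- matrix(stats::runif(L * p, -1, 1), L, p)
    if (is.null(biases)) biases <- stats::runif(L, -1, 1)
  })
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(L, p))) stop("'weights' must be L x p")
  if (length(biases) != L) stop("'biases' must have length L")
  H <- elm_hidden(X, weights, biases, scaling, activation)
  if (any(!is.finite(H)))
    stop("non-finite hidden activations (activation = ", activation,
         "); check the input scaling")
  beta <- pinv_solve(H, y)
  model <- structure(list(input_weights = weights, hidden_biases = biases,
                          output_weights = beta, activation = activation,
                          input_scaling = scaling, n_hidden = L),
                     class = "elm_model")
  model$fitted.values <- as.vector(H %*% beta)
  model$residuals <- y - model$fitted.values
  model
}

# map inputs to [-1, 1] with the stored ranges and evaluate g(Xs W' + b)
elm_hidden <- function(X, W, b, scaling, activation) {
  lo <- scaling[1, ]; hi <- scaling[2, ]
  span <- hi - lo
  span[span < .Machine$double.eps] <- 1        # constant feature -> 0
  Xs <- sweep(sweep(X, 2, (lo + hi) / 2), 2, span / 2, "/")
  Z <- Xs %*% t(W) + matrix(b, nrow(X), length(b), byrow = TRUE)
  switch(activation,
         sigmoid = 1 / (1 + exp(-Z)),
         tanh = tanh(Z))
}

# minimum-norm least-squares via SVD pseudoinverse
pinv_solve <- function(H, y) {
  sv <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(rep(0, ncol(H)))
  as.vector(sv$v[, pos, drop = FALSE] %*%
              ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

#' Predict from an ELM model
#'
#' @param object an [elm_fit()] model.
#' @param newdata numeric matrix with the training column count.
#' @param ... unused.
#' @return Numeric prediction vector.
#' @export
predict.elm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$input_weights))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         ncol(object$input_weights))
  H <- elm_hidden(newdata, object$input_weights, object$hidden_biases,
                  object$input_scaling, object$activation)
  as.vector(H %*% object$output_weights)
}

#' @export
print.elm_model <- function(x, ...) {
  cat("elm_model:", x$n_hidden, "hidden neurons (", x$activation, "),",
      ncol(x$input_weights), "inputs\n")
  invisible(x)
}

#' @export
residuals.elm_model <- function(object, ...) object$residuals

#' @export
coef.elm_model <- function(object, ...) object$output_weights
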