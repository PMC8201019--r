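#' Particle swarm optimization configuration
#'
#' Container for the PSO hyper-parameters. The defaults follow the
#' configuration used throughout this package for ELM weight optimization:
#' a swarm of 100 particles, 100 iterations, inertia weight decreasing
#' linearly from 0.8 to 0.4, individual acceleration c1 = 2.4 and global
#' acceleration c2 = 1.6, positions confined to \[-1, 1\].
#'
#' @param swarm_size number of particles.
#' @param max_iter maximum number of iterations.
#' @param w_max,w_min initial and final inertia weight (w_max >= w_min > 0).
#' @param c1,c2 positive acceleration coefficients (individual, global).
#' @param position_bounds length-2 numeric, lower and upper position bound
#'   applied to every dimension.
#' @param velocity_clamp velocity limit as a fraction of the position
#'   range per dimension (default 0.5).
#' @param tol,patience early stop: halt when the global best improves by
#'   less than `tol` for `patience` consecutive iterations.
#' @param seed optional integer seed.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 100L, max_iter = 100L,
                       w_max = 0.8, w_min = 0.4, c1 = 2.4, c2 = 1.6,
                       position_bounds = c(-1, 1), velocity_clamp = 0.5,
                       tol = 1e-10, patience = 15L, seed = NULL) {
  if (w_max < w_min || w_min <= 0) stop("need w_max >= w_min > 0")
  if (c1 < 0 || c2 < 0) stop("acceleration coefficients must be >= 0")
  if (length(position_bounds) != 2L || !all(is.finite(position_bounds)) ||
      position_bounds[1] >= position_bounds[2])
    stop("'position_bounds' must be finite c(lo, hi) with lo < hi")
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iter = as.integer(max_iter),
                 w_max = w_max, w_min = w_min, c1 = c1, c2 = c2,
                 position_bounds = as.numeric(position_bounds),
                 velocity_clamp = velocity_clamp,
                 tol = tol, patience = as.integer(patience), seed = seed),
            class = "pso_config")
}

#' Minimize a function by particle swarm optimization
#'
#' Standard global-best PSO with linearly decreasing inertia. Particles
#' start uniformly inside the position bounds with zero velocity. Each
#' iteration updates `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`
#' with fresh uniform `r1, r2` per particle and dimension, clamps the
#' velocity to `velocity_clamp` times the position range, moves, and clips
#' positions back into bounds.
#'
#' @param fn objective returning a finite scalar to minimize; receives a
#'   numeric vector of length `dim`.
#' @param dim problem dimension.
#' @param config a [pso_config()].
#' @return A list of class `pso_result`: `best_par`, `best_value`,
#'   `trace` (global-best fitness after each iteration, including the
#'   initial evaluation), `iterations`.
#' @export
pso_optimize <- function(fn, dim, config = pso_config()) {
  stopifnot(inherits(config, "pso_config"))
  dim <- as.integer(dim)
  lo <- config$position_bounds[1]; hi <- config$position_bounds[2]
  vmax <- config$velocity_clamp * (hi - lo)
  S <- config$swarm_size
  with_seed(config$seed, {
    X <- matrix(stats::runif(S * dim, lo, hi), S, dim)
    V <- matrix(0, S, dim)
    fit <- apply(X, 1, fn)
    if (any(!is.finite(fit))) stop("non-finite fitness at initialization")
    P <- X; pfit <- fit
    g <- which.min(pfit)
    gbest <- P[g, ]; gfit <- pfit[g]
    trace <- gfit
    stall <- 0L; iters <- 0L
    for (t in seq_len(config$max_iter)) {
      w <- if (config$max_iter > 1L)
        config$w_max - (config$w_max - config$w_min) *
          (t - 1) / (config$max_iter - 1)
      else config$w_max
      r1 <- matrix(stats::runif(S * dim), S, dim)
      r2 <- matrix(stats::runif(S * dim), S, dim)
      V <- w * V + config$c1 * r1 * (P - X) +
        config$c2 * r2 * sweep(X, 2, gbest, function(x, g) g - x)
      V <- pmin(pmax(V, -vmax), vmax)
      X <- pmin(pmax(X + V, lo), hi)
      fit <- apply(X, 1, fn)
      if (any(!is.finite(fit))) stop("non-finite fitness during search")
      better <- fit < pfit
      P[better, ] <- X[better, , drop = FALSE]
      pfit[better] <- fit[better]
      g <- which.min(pfit)
      improvement <- gfit - pfit[g]
      if (pfit[g] < gfit) { gbest <- P[g, ]; gfit <- pfit[g] }
      trace <- c(trace, gfit)
      iters <- t
      stall <- if (improvement < config$tol) stall + 1L else 0L
      if (stall >= config$patience) break
    }
    structure(list(best_par = gbest, best_value = gfit, trace = trace,
                   iterations = iters),
              class = "pso_result")
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat("pso_result: best value", format(x$best_value, digits = 6), "after",
      x$iterations, "iterations\n")
  invisible(x)
}

#' Fit an ELM with PSO-optimized input weights and biases
#'
#' Instead of accepting a single random draw of the input weights `W` and
#' hidden biases `b`, a particle swarm searches over them: each particle
#' encodes a full `(W, b)` pair (dimension `L * (p + 1)`), its fitness is
#' the mean squared error on a validation set of the ELM whose output
#' weights are solved on the training portion with that particle's
#' `(W, b)`. The final model is rebuilt from the global-best particle with
#' the output weights solved on the complete training set.
#'
#' When no validation set is supplied, a seeded internal split reserves
#' `val_fraction` of the training samples for the fitness so the search
#' never sees held-out test data. Supplying `X_val`/`y_val` explicitly
#' reproduces the protocol in which an external test set drives the
#' fitness; in that case the caller is responsible for the information
#' leakage this implies.
#'
#' @param X_train,y_train training predictors and response.
#' @param X_val,y_val optional explicit validation set for the PSO fitness.
#' @param n_hidden hidden-layer size L (default 20).
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @param config a [pso_config()]; its `seed` also controls the internal
#'   validation split.
#' @param val_fraction fraction of training samples carved off for the
#'   internal validation split when `X_val` is NULL (default 0.2).
#' @return A list of class `pso_elm`: `model` (an `elm_model`), `trace`
#'   (a `pso_result`), and `validation` (the indices or "external").
#' @export
pso_elm_fit <- function(X_train, y_train, X_val = NULL, y_val = NULL,
                        n_hidden = 20L, activation = c("sigmoid", "tanh"),
                        config = pso_config(), val_fraction = 0.2) {
  activation <- match.arg(activation)
  X_train <- as.matrix(X_train); y_train <- as.numeric(y_train)
  n <- nrow(X_train); p <- ncol(X_train); L <- as.integer(n_hidden)
  scaling <- rbind(lo = apply(X_train, 2, min), hi = apply(X_train, 2, max))
  if (is.null(X_val)) {
    n_val <- max(1L, round(val_fraction * n))
    if (n_val >= n) stop("validation split would consume all training data")
    val_idx <- with_seed(config$seed, sample.int(n, n_val))
    Xf <- X_train[-val_idx, , drop = FALSE]; yf <- y_train[-val_idx]
    Xv <- X_train[val_idx, , drop = FALSE]; yv <- y_train[val_idx]
    val_tag <- val_idx
  } else {
    if (is.null(y_val) || nrow(as.matrix(X_val)) != length(y_val))
      stop("'X_val' and 'y_val' must be supplied together, same length")
    if (nrow(as.matrix(X_val)) < 1L) stop("empty validation set")
    Xf <- X_train; yf <- y_train
    Xv <- as.matrix(X_val); yv <- as.numeric(y_val)
    val_tag <- "external"
  }
  decode <- function(par) {
    list(W = matrix(par[seq_len(L * p)], L, p),
         b = par[L * p + seq_len(L)])
  }
  Hf_of <- function(W, b) elm_hidden(Xf, W, b, scaling, activation)
  Hv_of <- function(W, b) elm_hidden(Xv, W, b, scaling, activation)
  fitness <- function(par) {
    wb <- decode(par)
    beta <- pinv_solve(Hf_of(wb$W, wb$b), yf)
    mean((yv - Hv_of(wb$W, wb$b) %*% beta)^2)
  }
  res <- pso_optimize(fitness, dim = L * (p + 1L), config = config)
  wb <- decode(res$best_par)
  model <- elm_fit(X_train, y_train, n_hidden = L, activation = activation,
                   weights = wb$W, biases = wb$b, scaling = scaling)
  structure(list(model = model, trace = res, validation = val_tag),
            class = "pso_elm")
}

#' @export
print.pso_elm <- function(x, ...) {
  cat("pso_elm: ")
  print(x$model)
  cat("  PSO best validation MSE:",
      format(x$trace$best_value, digits = 6), "\n")
  invisible(x)
}

#' @export
predict.pso_elm <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
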