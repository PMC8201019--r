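test_that("EDF retention honors its boundary conditions analytically", {
  p <- 112L; N <- 50L
  expect_equal(edf_retention(1, N, p), 1, tolerance = 1e-12)
  expect_equal(edf_retention(N, N, p), 2 / p, tolerance = 1e-12)
  # interior value from the analytically solved constants
  k <- log(p / 2) / (N - 1); mu <- exp(k)
  expect_equal(edf_retention(25, N, p), mu * exp(-k * 25),
               tolerance = 1e-12)
  # implied counts: all p at the start, 2 at the end, monotone between
  counts <- vapply(1:N, function(i) soilspec:::edf_count(i, N, p),
                   integer(1))
  expect_equal(counts[1], p)
  expect_equal(counts[N], 2L)
  expect_true(all(diff(counts) <= 0))
  expect_error(edf_retention(0, N, p), "run_index")
  expect_error(edf_retention(51, N, p), "run_index")
})

test_that("ARS respects weights, zero weights, and exact counts", {
  # single positive weight is always drawn
  for (s in 1:5)
    expect_equal(ars_sample(c(0, 0, 1, 0), 1, seed = s), 3L)
  # count == number of positive weights retains all of them
  expect_equal(ars_sample(c(0.2, 0, 0.5, 0.9), 3, seed = 1), c(1L, 3L, 4L))
  # zero-weight variables never appear, either variant
  set.seed(42)
  for (rep in 1:50) {
    expect_false(2L %in% ars_sample(c(1, 0, 1, 1), 2))
    expect_false(2L %in% ars_sample(c(1, 0, 1, 1), 3, replace = TRUE))
  }
  expect_error(ars_sample(c(0, 0), 1), "zero")
  expect_error(ars_sample(c(1, 1), 3), "exceeds")
})

test_that("ARS with uniform weights draws uniformly (Monte Carlo)", {
  set.seed(99)
  p <- 8L; draws <- 10000L
  tab <- integer(p)
  for (i in seq_len(draws)) {
    pick <- ars_sample(rep(1, p), 2)
    tab[pick] <- tab[pick] + 1L
  }
  prob <- 2 / p                       # marginal inclusion probability
  se <- sqrt(prob * (1 - prob) / draws)
  expect_true(all(abs(tab / draws - prob) <= 3 * se))
})

test_that("CARS recovers a noise-free informative band and shrinks monotonically", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 40; p <- 30
    X <- matrix(rnorm(n * p), n, p)
    y <- X[, 17]                      # y IS band 17
    res <- cars(X, y, n_runs = 30, seed = s)
    tr <- res$diagnostics$trace
    expect_true(all(diff(tr$variable_counts) <= 0))
    expect_equal(tr$best_run, which.min(tr$rmsecv))
    expect_true(all(unlist(tr$subsets) >= 1 & unlist(tr$subsets) <= p))
    if (17L %in% res$band_indices) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("CARS is bit-reproducible under a fixed seed", {
  set.seed(1)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- X[, 3] + 0.5 * X[, 11] + rnorm(40, sd = 0.2)
  a <- cars(X, y, n_runs = 15, seed = 123)
  b <- cars(X, y, n_runs = 15, seed = 123)
  expect_identical(a$band_indices, b$band_indices)
  expect_identical(a$diagnostics$trace$rmsecv, b$diagnostics$trace$rmsecv)
  d <- cars(X, y, n_runs = 15, seed = 124)
  expect_false(identical(a$diagnostics$trace$rmsecv,
                         d$diagnostics$trace$rmsecv))
})

test_that("SPA never selects duplicated columns", {
  set.seed(5)
  n <- 30
  base <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(base, base[, 2])         # column 5 duplicates column 2
  y <- base %*% c(1, -1, 0.5, 0.2) + rnorm(n, sd = 0.1)
  sel <- spa(X, y, n_max = 4)
  expect_false(all(c(2L, 5L) %in% sel$band_indices))
})

test_that("SPA projection step picks the largest-norm remaining column", {
  # orthonormal columns scaled to distinct norms; uncentered geometry
  q <- qr.Q(qr(matrix(rnorm(20 * 4), 20, 4)))
  X <- q %*% diag(c(1, 5, 3, 2))
  chain <- soilspec:::spa_chain(X, start = 1L, n_max = 4L)
  # after x1, residual norms are the original norms (orthogonality)
  expect_equal(chain, c(1L, 2L, 3L, 4L))
})

test_that("SPA agrees with the exhaustive-search oracle on small instances", {
  set.seed(31)
  for (case in 1:12) {
    n <- 25; p <- sample(4:8, 1); nmx <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    beta <- rep(0, p); beta[sample(p, 2)] <- c(1.5, -1)
    y <- as.vector(X %*% beta + rnorm(n, sd = 0.3))
    sel <- spa(X, y, n_max = nmx)
    oracle <- spa_oracle(X, y, n_max = nmx)
    expect_equal(sel$band_indices, sort(oracle$chain))
    expect_equal(sel$diagnostics$rmse, oracle$rmse, tolerance = 1e-8)
  }
})

test_that("CARS-SPA reduces near-duplicate informative clusters", {
  shrunk <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 50
    sig <- rnorm(n)
    cluster <- sapply(1:6, function(i) sig + rnorm(n, sd = 0.02))
    noise <- matrix(rnorm(n * 14), n, 14)
    X <- cbind(cluster, noise)
    y <- sig + rnorm(n, sd = 0.1)
    cr <- cars(X, y, n_runs = 20, seed = s)
    cs <- cars_spa(X, y, cars_params = list(n_runs = 20), seed = s)
    if (length(cs$band_indices) < length(cr$band_indices)) shrunk <- shrunk + 1L
    # result indices refer to the original grid
    expect_true(all(cs$band_indices %in% seq_len(20)))
  }
  expect_gte(shrunk, 11L)
})

test_that("cars_spa wavelengths are consistent with the source grid", {
  sim <- simulate_samples(synthetic_config("SOM", seed = 2))
  m <- msc(sim$spectra)
  sel <- cars_spa(m$spectra, sim$targets$value, seed = 2)
  expect_equal(sel$wavelengths_nm,
               sim$spectra$wavelengths[sel$band_indices])
  expect_false(any(duplicated(sel$band_indices)))
})
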