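test_that("binning maps 281 native channels over 400-1000 nm to 150 bands", {
  sm <- spectra_matrix(matrix(runif(281 * 2), 2, 281),
                       seq(400, 1000, length.out = 281))
  out <- bin_spectra(sm, 4)
  expect_equal(length(out$wavelengths), 150L)
  expect_equal(ncol(out$values), 150L)
})

test_that("binning at the native spacing is the identity", {
  sm <- random_spectra(n = 3, m = 20, step = 4)
  out <- bin_spectra(sm, 4)
  expect_equal(out$wavelengths, sm$wavelengths)
  expect_equal(out$values, sm$values, tolerance = 1e-12)
})

test_that("binning a linear spectrum evaluates the line at bin centers", {
  wl <- seq(400, 1000, length.out = 281)
  sm <- spectra_matrix(rbind(wl / 1000, 2 - wl / 1000), wl)
  for (w in c(4, 7.5, 12)) {
    out <- bin_spectra(sm, w)
    expect_lt(max(abs(out$values[1, ] - out$wavelengths / 1000)), 1e-8)
    expect_lt(max(abs(out$values[2, ] - (2 - out$wavelengths / 1000))), 1e-8)
  }
  expect_error(bin_spectra(sm, -1), "positive")
  expect_error(bin_spectra(sm, 0.5), "spacing")
})

test_that("trim_bands keeps exactly the bands inside closed ranges", {
  sm <- random_spectra(n = 2, m = 13, lo = 400, step = 4)  # 400..448
  out <- trim_bands(sm, list(c(410, 430)))
  expect_equal(out$wavelengths, c(412, 416, 420, 424, 428))
  # water-vapour gap removal on a 4-nm grid
  big <- random_spectra(n = 2, m = 125, lo = 403, step = 4) # 403..899
  trimmed <- trim_bands(big, list(c(403, 759), c(783, 900)))
  expect_false(any(trimmed$wavelengths > 759 & trimmed$wavelengths < 783))
  expect_equal(length(trimmed$wavelengths), 120L)
  # full-cover range is the identity
  same <- trim_bands(sm, list(c(390, 460)))
  expect_equal(same$values, sm$values)
  expect_error(trim_bands(sm, list(c(900, 950))), "no band")
  expect_error(trim_bands(sm, list(c(400, 420), c(410, 450))),
               "non-overlapping")
})

test_that("sigma filter leaves a constant band unchanged", {
  cube <- random_cube(6, 6, 2)
  cube$values[, , 1] <- 0.5
  out <- sigma_filter(cube, window = 3)
  expect_equal(out$values[, , 1], matrix(0.5, 6, 6))
})

test_that("sigma filter matches the brute-force reference loop", {
  set.seed(7)
  mask <- matrix(runif(64) > 0.15, 8, 8)
  cube <- random_cube(8, 8, 3, seed = 7, mask = mask)
  cube$values[3, 4, ] <- 5  # outlier pixel
  for (w in c(3L, 5L)) {
    out <- sigma_filter(cube, window = w, sigma_mult = 2)
    for (b in 1:3) {
      ref <- brute_sigma_filter(cube$values[, , b], mask, w, 2)
      expect_lt(max(abs(out$values[, , b] - ref)), 1e-12)
    }
  }
  expect_error(sigma_filter(cube, window = 4), "odd")
  expect_error(sigma_filter(cube, window = 11), "larger")
})

test_that("MSC recovers affine scatter exactly and maps onto the reference", {
  set.seed(3)
  ref <- runif(30, 0.2, 0.8)
  a_true <- c(0.7, 1.0, 1.4, 2.0)
  b_true <- c(-0.05, 0, 0.08, 0.1)
  X <- sweep(outer(a_true, ref), 1, b_true, "+")
  sm <- spectra_matrix(X, seq(400, by = 4, length.out = 30))
  out <- msc(sm, reference = ref)
  expect_equal(out$coefficients$slope_a, a_true, tolerance = 1e-10)
  expect_equal(out$coefficients$intercept_b, b_true, tolerance = 1e-10)
  expect_lt(max(abs(sweep(out$spectra$values, 2, ref))), 1e-10)
})

test_that("MSC with mean reference: identical samples give (1, 0)", {
  X <- matrix(rep(runif(12, 0.2, 0.8), each = 3), 3, 12)
  sm <- spectra_matrix(X, seq(400, by = 4, length.out = 12))
  out <- msc(sm)
  expect_equal(out$coefficients$slope_a, rep(1, 3), tolerance = 1e-12)
  expect_equal(out$coefficients$intercept_b, rep(0, 3), tolerance = 1e-12)
  expect_equal(out$spectra$values, sm$values, tolerance = 1e-12)
})

test_that("MSC-corrected spectra regress on the reference with slope 1", {
  sm <- random_spectra(n = 3, m = 5, seed = 9)
  out <- msc(sm)
  ref <- out$coefficients$reference_spectrum
  for (i in 1:3) {
    ab <- ols_slope_intercept(ref, out$spectra$values[i, ])
    expect_equal(unname(ab["slope"]), 1, tolerance = 1e-10)
    expect_equal(unname(ab["intercept"]), 0, tolerance = 1e-10)
  }
  # coefficients agree with the closed-form cov/var OLS oracle
  raw <- msc(sm)
  for (i in 1:3) {
    ab <- ols_slope_intercept(ref, sm$values[i, ])
    expect_equal(raw$coefficients$slope_a[i], unname(ab["slope"]),
                 tolerance = 1e-10)
    expect_equal(raw$coefficients$intercept_b[i], unname(ab["intercept"]),
                 tolerance = 1e-10)
  }
})

test_that("MSC fails loudly on a degenerate (zero-slope) sample", {
  ref <- seq(0.2, 0.8, length.out = 10)
  X <- rbind(2 * ref, rep(0.5, 10))
  sm <- spectra_matrix(X, seq(400, by = 4, length.out = 10), c("ok", "flat"))
  expect_error(msc(sm, reference = ref), "flat")
})

test_that("SNV standardizes rows and is affine-invariant", {
  sm <- spectra_matrix(matrix(c(1, 2, 3), 1, 3), c(500, 510, 520))
  expect_equal(as.vector(snv(sm)$values), c(-1, 0, 1))
  x <- random_spectra(n = 4, m = 10, seed = 5)
  out <- snv(x)
  expect_lt(max(abs(rowMeans(out$values))), 1e-12)
  expect_lt(max(abs(apply(out$values, 1, sd) - 1)), 1e-12)
  # snv(c*x + d) == snv(x) for c > 0
  shifted <- spectra_matrix(3.7 * x$values + 0.21, x$wavelengths)
  expect_equal(snv(shifted)$values, out$values, tolerance = 1e-10)
  # already standardized input is a fixed point
  expect_equal(snv(out)$values, out$values, tolerance = 1e-12)
  flat <- spectra_matrix(matrix(0.4, 2, 5), seq(400, 440, 10))
  expect_error(snv(flat), "zero-variance")
})

test_that("derivatives match closed forms and compose", {
  wl <- seq(400, by = 4, length.out = 40)
  lin <- spectra_matrix(rbind(0.001 * wl + 0.1, rep(0.5, 40)), wl)
  fd <- derivative(lin, 1)
  expect_equal(ncol(fd$values), 39L)
  expect_lt(max(abs(fd$values[1, ] - 0.001)), 1e-12)
  expect_lt(max(abs(fd$values[2, ])), 1e-12)
  expect_equal(fd$wavelengths, wl[1:39])
  quad <- spectra_matrix(matrix(wl^2, 1), wl)
  sd2 <- derivative(quad, 2)
  expect_equal(ncol(sd2$values), 38L)
  expect_lt(max(abs(sd2$values - 2)), 1e-8)
  # second derivative equals first derivative applied twice (uniform grid)
  x <- random_spectra(n = 2, m = 20, seed = 11)
  twice <- derivative(derivative(x, 1), 1)
  expect_equal(derivative(x, 2)$values, twice$values, tolerance = 1e-10)
  expect_error(derivative(spectra_matrix(matrix(1, 1, 2), c(1, 2)), 2),
               "too few")
})

test_that("band SNR follows the 20*log10(mean/sd) convention", {
  set.seed(2)
  X <- cbind(rnorm(50, 1.0, 0.1), rnorm(50, 0.5, 0.5), rep(0.3, 50))
  X <- X - min(X) + 0.01      # keep reflectance positive
  sm <- spectra_matrix(X, c(500, 510, 520))
  snr <- band_snr(sm)
  for (k in 1:2) {
    expect_equal(unname(snr[k]),
                 20 * log10(mean(X[, k]) / sd(X[, k])), tolerance = 1e-10)
  }
  expect_true(is.infinite(snr[3]))
  # a band with mean == sd sits at 0 dB
  z <- rnorm(100)
  v <- (z - mean(z)) / sd(z) + 1            # mean 1, sd 1
  expect_equal(unname(band_snr(spectra_matrix(cbind(v), 500))[1]), 0,
               tolerance = 1e-8)
  # power convention
  expect_equal(unname(band_snr(sm, scale = 10)[1]),
               10 * log10(mean(X[, 1]) / sd(X[, 1])), tolerance = 1e-10)
})

test_that("band correlations equal the textbook formula and flag the max", {
  set.seed(4)
  y <- rnorm(10)
  X <- cbind(y, -y, rnorm(10), rep(1, 10))
  X <- X + 2
  y2 <- y
  sm <- spectra_matrix(X, c(500, 510, 520, 530))
  expect_warning(bc <- band_correlations(sm, y2), "constant")
  expect_equal(bc$r[1], 1, tolerance = 1e-12)
  expect_equal(bc$r[2], -1, tolerance = 1e-12)
  manual <- sum((X[, 3] - mean(X[, 3])) * (y2 - mean(y2))) /
    ((10 - 1) * sd(X[, 3]) * sd(y2))
  expect_equal(bc$r[3], manual, tolerance = 1e-12)
  expect_equal(bc$r[4], 0)
  expect_equal(bc$max_abs_r, 1)
  expect_true(bc$max_wavelength %in% c(500, 510))
})
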