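#' Bin spectra onto a coarser wavelength grid
#'
#' Re-grids each spectrum onto contiguous bins of fixed width spanning the
#' input range, by cubic-spline interpolation through the native channel
#' centers evaluated at the bin centers. The covered range is taken as the
#' native channel centers extended by half the native spacing on either
#' side, so binning an already-binned grid at its own width is the identity.
#' The number of output bands is `floor(range / target_width_nm)`.
#'
#' @param data a [spectra_matrix] or [hypercube].
#' @param target_width_nm bin width in nm; must be at least the native
#'   channel spacing.
#' @return Same kind of object as `data`, on the binned grid.
#' @examples
#' sm <- spectra_matrix(matrix(runif(562), 2, 281),
#'                      seq(400, 1000, length.out = 281))
#' dim(bin_spectra(sm, 4))   # 2 x 150
#' @export
bin_spectra <- function(data, target_width_nm) {
  if (!is.numeric(target_width_nm) || length(target_width_nm) != 1L ||
      target_width_nm <= 0)
    stop("'target_width_nm' must be a positive scalar")
  map_spectral(data, function(values, wl) {
    if (length(wl) < 2L) stop("need at least 2 channels to bin")
    spacing <- stats::median(diff(wl))
    if (target_width_nm < spacing - 1e-9)
      stop("'target_width_nm' (", target_width_nm,
           ") is below the native channel spacing (", signif(spacing, 6), ")")
    lo <- min(wl) - spacing / 2
    hi <- max(wl) + spacing / 2
    n_bins <- floor((hi - lo) / target_width_nm + 1e-9)
    if (n_bins < 2L)
      stop("wavelength range covers fewer than 2 bins of width ",
           target_width_nm)
    centers <- lo + target_width_nm * (seq_len(n_bins) - 0.5)
    out <- matrix(NA_real_, nrow(values), n_bins)
    for (i in seq_len(nrow(values))) {
      out[i, ] <- stats::splinefun(wl, values[i, ], method = "fmm")(centers)
    }
    list(values = out, wavelengths = centers)
  })
}

#' Trim spectra to a set of wavelength ranges
#'
#' Retains exactly the bands whose center lies inside any of the given
#' closed ranges, e.g. to excise the atmospheric water-vapour window around
#' 760--782 nm.
#'
#' @param data a [spectra_matrix] or [hypercube].
#' @param keep_ranges_nm list (or 2-column matrix) of `c(lo, hi)` ranges in
#'   nm, ascending and non-overlapping.
#' @return Same kind of object, restricted to the surviving bands.
#' @export
trim_bands <- function(data, keep_ranges_nm) {
  if (is.matrix(keep_ranges_nm))
    keep_ranges_nm <- split(keep_ranges_nm, row(keep_ranges_nm))
  ranges <- lapply(keep_ranges_nm, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2L || r[1] > r[2]) stop("each range must be c(lo, hi)")
    r
  })
  if (length(ranges) >= 2L) {
    m <- do.call(rbind, ranges)
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("'keep_ranges_nm' must be non-overlapping and ascending")
  }
  map_spectral(data, function(values, wl) {
    keep <- vapply(wl, function(w)
      any(vapply(ranges, function(r) w >= r[1] && w <= r[2], logical(1))),
      logical(1))
    if (!any(keep)) stop("no band survives the requested trim ranges")
    list(values = values[, keep, drop = FALSE], wavelengths = wl[keep])
  })
}

#' Sigma filter for hyperspectral cubes
#'
#' Edge-preserving Lee sigma smoothing applied band by band: each pixel is
#' replaced by the mean of the valid window pixels whose value lies within
#' `sigma_mult` local standard deviations of the center value, where the
#' local standard deviation is taken over the valid pixels of the window.
#' Pixels with no in-range neighbors (or an undefined local deviation)
#' keep their value. Masked-out pixels are excluded from all averages and
#' pass through unchanged.
#'
#' @param cube a [hypercube].
#' @param window odd window side length, >= 3 (default 11).
#' @param sigma_mult inclusion half-width in local standard deviations
#'   (default 2).
#' @return Filtered [hypercube] on the same grid.
#' @export
sigma_filter <- function(cube, window = 11L, sigma_mult = 2) {
  stopifnot(inherits(cube, "hypercube"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  if (!is.numeric(sigma_mult) || sigma_mult <= 0)
    stop("'sigma_mult' must be positive")
  d <- dim(cube$values)
  if (window > d[1] || window > d[2])
    stop("'window' is larger than the image")
  out <- cube$values
  for (b in seq_len(d[3])) {
    out[, , b] <- sigma_filter_band(cube$values[, , b], cube$mask,
                                    window, sigma_mult)
  }
  hypercube(out, cube$wavelengths, cube$mask, cube$pixel_size_m)
}

# one band; offset-accumulation implementation (no per-pixel loop)
sigma_filter_band <- function(mat, mask, window, sigma_mult) {
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- (window - 1L) %/% 2L
  pr <- nr + 2L * pad; pc <- nc + 2L * pad
  vp <- matrix(0, pr, pc)            # padded values
  mp <- matrix(0, pr, pc)            # padded validity (0/1)
  core_i <- (pad + 1L):(pad + nr); core_j <- (pad + 1L):(pad + nc)
  vp[core_i, core_j] <- ifelse(mask, mat, 0)
  mp[core_i, core_j] <- as.numeric(mask)

  s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (di in -pad:pad) for (dj in -pad:pad) {
    ii <- core_i + di; jj <- core_j + dj
    v <- vp[ii, jj]; m <- mp[ii, jj]
    s <- s + v; s2 <- s2 + v * v; n <- n + m
  }
  # sample variance over valid window pixels ((count - 1) denominator)
  varw <- (s2 - s * s / pmax(n, 1)) / pmax(n - 1, 1)
  varw[n < 2] <- NA_real_
  sdw <- sqrt(pmax(varw, 0))
  tau <- sigma_mult * sdw

  ssel <- matrix(0, nr, nc); nsel <- matrix(0, nr, nc)
  for (di in -pad:pad) for (dj in -pad:pad) {
    ii <- core_i + di; jj <- core_j + dj
    v <- vp[ii, jj]; m <- mp[ii, jj]
    incl <- m > 0 & !is.na(tau) & abs(v - mat) <= tau
    ssel <- ssel + ifelse(incl, v, 0)
    nsel <- nsel + incl
  }
  res <- ifelse(nsel > 0, ssel / pmax(nsel, 1), mat)
  res[!mask] <- mat[!mask]
  res[is.na(tau) & mask] <- mat[is.na(tau) & mask]
  res
}

#' Multiplicative scatter correction
#'
#' Corrects per-sample multiplicative and additive scatter by ordinary
#' least-squares regression of each spectrum on a reference spectrum
#' (by default the mean spectrum of the set): fitting
#' `R_i = b_i + a_i * ref` and returning `(R_i - b_i) / a_i`.
#'
#' @param data a [spectra_matrix] with at least 2 samples when
#'   `reference = "mean"`.
#' @param reference `"mean"` (default) or a numeric reference spectrum of
#'   length equal to the band count. Must not be constant.
#' @return A list with elements `spectra` (corrected [spectra_matrix]) and
#'   `coefficients` (class `scatter_coefficients`: per-sample `slope_a`,
#'   `intercept_b`, and the `reference_spectrum` used).
#' @export
msc <- function(data, reference = "mean") {
  stopifnot(inherits(data, "spectra_matrix"))
  X <- data$values
  if (identical(reference, "mean")) {
    if (nrow(X) < 2L) stop("need at least 2 samples for a mean reference")
    ref <- colMeans(X)
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != ncol(X))
      stop("'reference' length does not match the band count")
  }
  vref <- stats::var(ref)
  if (vref < .Machine$double.eps)
    stop("reference spectrum is constant; MSC regression is undefined")
  mref <- mean(ref)
  refc <- ref - mref
  # slope_i = cov(ref, R_i) / var(ref); intercept_i = mean(R_i) - a_i*mean(ref)
  a <- as.vector((X %*% refc) / sum(refc^2) -
                 rowMeans(X) * sum(refc) / sum(refc^2))
  b <- unname(rowMeans(X)) - a * mref
  bad <- which(abs(a) < 1e-12)
  if (length(bad))
    stop("MSC slope is zero for sample(s): ",
         paste(data$ids[bad], collapse = ", "))
  corrected <- sweep(sweep(X, 1, b, "-"), 1, a, "/")
  coefs <- structure(list(slope_a = a, intercept_b = b,
                          reference_spectrum = ref,
                          sample_ids = data$ids),
                     class = "scatter_coefficients")
  list(spectra = spectra_matrix(corrected, data$wavelengths, data$ids),
       coefficients = coefs)
}

#' @export
print.scatter_coefficients <- function(x, ...) {
  cat("scatter_coefficients:", length(x$slope_a), "samples; slope range [",
      format(min(x$slope_a)), ",", format(max(x$slope_a)), "]\n")
  invisible(x)
}

#' Standard normal variate transform
#'
#' Centers each spectrum by its own mean and scales by its sample standard
#' deviation (denominator m - 1), so every output row has mean 0 and unit
#' sample standard deviation.
#'
#' @param data a [spectra_matrix] with m >= 2 bands and no constant row.
#' @return Transformed [spectra_matrix].
#' @export
snv <- function(data) {
  stopifnot(inherits(data, "spectra_matrix"))
  X <- data$values
  if (ncol(X) < 2L) stop("SNV needs at least 2 bands")
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  bad <- which(sdv < .Machine$double.eps)
  if (length(bad))
    stop("zero-variance (constant) spectrum for sample(s): ",
         paste(data$ids[bad], collapse = ", "))
  out <- sweep(sweep(X, 1, mu, "-"), 1, sdv, "/")
  spectra_matrix(out, data$wavelengths, data$ids)
}

#' Spectral derivatives
#'
#' First- or second-order finite-difference derivative along wavelength.
#' Order 1: `(R[k+1] - R[k]) / (lambda[k+1] - lambda[k])`, m - 1 output
#' bands. Order 2: `(R[k+2] - 2 R[k+1] + R[k]) / (lambda[k+1] - lambda[k])^2`,
#' m - 2 output bands. Output wavelengths are left-anchored at `lambda[k]`.
#'
#' @param data a [spectra_matrix].
#' @param order 1 (first derivative, default) or 2 (second derivative).
#' @return A [spectra_matrix] of derivative spectra.
#' @export
derivative <- function(data, order = 1L) {
  stopifnot(inherits(data, "spectra_matrix"))
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("'order' must be 1 or 2")
  X <- data$values; wl <- data$wavelengths; m <- length(wl)
  if (m < order + 1L) stop("too few bands for derivative of order ", order)
  dwl <- diff(wl)
  if (order == 1L) {
    out <- (X[, -1, drop = FALSE] - X[, -m, drop = FALSE]) /
      matrix(dwl, nrow(X), m - 1L, byrow = TRUE)
    spectra_matrix(out, wl[seq_len(m - 1L)], data$ids)
  } else {
    num <- X[, 3:m, drop = FALSE] - 2 * X[, 2:(m - 1), drop = FALSE] +
      X[, 1:(m - 2), drop = FALSE]
    den <- matrix(dwl[seq_len(m - 2L)]^2, nrow(X), m - 2L, byrow = TRUE)
    spectra_matrix(num / den, wl[seq_len(m - 2L)], data$ids)
  }
}

#' Per-band signal-to-noise ratio
#'
#' SNR in decibels per band, `scale * log10(mean / sd)` over the sample
#' axis (for a spectra matrix) or over the valid pixels (for a cube),
#' with the sample (count - 1) standard deviation. Bands with zero
#' deviation are reported as `Inf`.
#'
#' @param data a [spectra_matrix] or [hypercube].
#' @param scale 20 (amplitude convention, default) or 10 (power).
#' @return Named numeric vector of SNR values in dB, one per band.
#' @export
band_snr <- function(data, scale = 20) {
  if (!scale %in% c(10, 20)) stop("'scale' must be 10 or 20")
  X <- if (inherits(data, "hypercube")) cube_to_spectra(data)$values
       else if (inherits(data, "spectra_matrix")) data$values
       else stop("'data' must be a spectra_matrix or hypercube")
  if (nrow(X) < 2L) stop("need at least 2 observations per band")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  snr <- ifelse(sdv < .Machine$double.eps, Inf, scale * log10(mu / sdv))
  names(snr) <- format(data$wavelengths, trim = TRUE)
  snr
}

#' Band-wise Pearson correlation with a target variable
#'
#' Correlates every band's reflectance column with a measured soil
#' property and reports the profile plus the location of the maximum
#' absolute correlation. Constant bands get r = 0 with a warning.
#'
#' @param data a [spectra_matrix] with n >= 3 samples.
#' @param y numeric target, length n, non-constant.
#' @return An object of class `band_correlations`: list with `r`
#'   (per-band correlations), `wavelengths`, `max_abs_r` and
#'   `max_wavelength`.
#' @export
band_correlations <- function(data, y) {
  stopifnot(inherits(data, "spectra_matrix"))
  y <- as.numeric(y)
  X <- data$values
  if (nrow(X) < 3L) stop("need at least 3 samples")
  if (length(y) != nrow(X)) stop("'y' length does not match sample count")
  if (stats::sd(y) < .Machine$double.eps) stop("'y' is constant")
  sdc <- apply(X, 2, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sdc >= .Machine$double.eps
  if (any(!ok))
    warning(sum(!ok), " constant band column(s); correlation set to 0")
  r[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], y))
  k <- which.max(abs(r))
  structure(list(r = r, wavelengths = data$wavelengths,
                 max_abs_r = abs(r[k]), max_wavelength = data$wavelengths[k]),
            class = "band_correlations")
}

#' @export
print.band_correlations <- function(x, ...) {
  cat("band_correlations over", length(x$r), "bands; max |r| =",
      format(x$max_abs_r, digits = 3), "at", x$max_wavelength, "nm\n")
  invisible(x)
}
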