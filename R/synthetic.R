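#' Configuration for the synthetic soil-spectra generator
#'
#' Describes the statistical structure the generator emulates: a field
#' survey of about 68 topsoil samples imaged in the VIS-NIR (4-nm bands
#' from 403 to 900 nm with the atmospheric water-vapour window 760--782 nm
#' excised), nutrient contents following truncated normal distributions
#' (SOM: mean 19.72 g/kg, CV 24%, range 11.4--30.6; STN: mean 1.38 g/kg,
#' CV 22%, range 0.84--2.08), per-sample multiplicative/additive scatter,
#' and white measurement noise. Nutrient content drives a set of Gaussian
#' absorption features: SOM-sensitive centers lie in the visible
#' 550--770 nm region, STN-sensitive centers around 510 nm.
#'
#' @param property `"SOM"` (default) or `"STN"`; selects the nutrient
#'   distribution and the default informative bands.
#' @param n_samples number of samples (default 68).
#' @param wavelengths band-center grid in nm; default 4-nm grid
#'   403--899 nm minus the 760--782 nm gap (120 bands).
#' @param informative_bands data.frame with columns `center` (nm),
#'   `width` (nm, Gaussian sigma), `coefficient` (absorption depth per
#'   g/kg of nutrient); defaults depend on `property`.
#' @param nutrient_mean,nutrient_sd,nutrient_lo,nutrient_hi truncated
#'   normal parameters for the nutrient content (g/kg); defaults depend
#'   on `property`.
#' @param scatter_slope_delta half-width of the per-sample multiplicative
#'   scatter, slope ~ U\[1 - delta, 1 + delta\] (default 0.1).
#' @param scatter_offset_delta half-width of the additive scatter,
#'   offset ~ U\[-delta, delta\] (default 0.02).
#' @param noise_sd white-noise standard deviation in reflectance units
#'   (default 0.01).
#' @param seed optional integer seed; the generator is bit-reproducible
#'   given (config, seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(property = c("SOM", "STN"),
                             n_samples = 68L,
                             wavelengths = default_wavelengths(),
                             informative_bands = NULL,
                             nutrient_mean = NULL, nutrient_sd = NULL,
                             nutrient_lo = NULL, nutrient_hi = NULL,
                             scatter_slope_delta = 0.1,
                             scatter_offset_delta = 0.02,
                             noise_sd = 0.01, seed = NULL) {
  property <- match.arg(property)
  defaults <- if (property == "SOM") {
    list(mean = 19.72, sd = 0.24 * 19.72, lo = 11.4, hi = 30.6,
         bands = data.frame(
           center = c(560, 596, 640, 700, 752),
           width = c(10, 10, 12, 10, 8),
           coefficient = c(0.0030, 0.0024, 0.0034, 0.0020, 0.0026)))
  } else {
    list(mean = 1.38, sd = 0.22 * 1.38, lo = 0.84, hi = 2.08,
         bands = data.frame(
           center = c(484, 506, 519, 532, 560),
           width = c(8, 8, 8, 10, 10),
           coefficient = c(0.040, 0.052, 0.044, 0.030, 0.026)))
  }
  if (is.null(informative_bands)) informative_bands <- defaults$bands
  informative_bands <- as.data.frame(informative_bands)
  if (nrow(informative_bands) > 0 &&
      (any(informative_bands$width <= 0)))
    stop("informative band widths must be positive")
  if (is.null(nutrient_mean)) nutrient_mean <- defaults$mean
  if (is.null(nutrient_sd)) nutrient_sd <- defaults$sd
  if (is.null(nutrient_lo)) nutrient_lo <- defaults$lo
  if (is.null(nutrient_hi)) nutrient_hi <- defaults$hi
  if (nutrient_lo >= nutrient_hi) stop("need nutrient_lo < nutrient_hi")
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) stop("wavelength grid must ascend")
  structure(list(property = property, n_samples = as.integer(n_samples),
                 wavelengths = wavelengths,
                 informative_bands = informative_bands,
                 nutrient_mean = nutrient_mean, nutrient_sd = nutrient_sd,
                 nutrient_lo = nutrient_lo, nutrient_hi = nutrient_hi,
                 scatter_slope_delta = scatter_slope_delta,
                 scatter_offset_delta = scatter_offset_delta,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_config")
}

#' Default VIS-NIR band grid
#'
#' 4-nm band centers from 403 to 899 nm with the water-vapour window
#' (760--782 nm) removed: 120 bands.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function() {
  wl <- seq(403, 899, by = 4)
  wl[wl < 760 | wl > 782]
}

# truncated normal by rejection
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# smooth soil reflectance baseline rising through the VIS-NIR
soil_baseline <- function(wl) {
  u <- (wl - 400) / 500
  0.12 + 0.28 * u - 0.06 * u^2
}

# clean (scatter- and noise-free) spectra for nutrient contents y
clean_spectra <- function(y, wl, bands) {
  base <- soil_baseline(wl)
  out <- matrix(base, length(y), length(wl), byrow = TRUE)
  if (nrow(bands) > 0) {
    for (j in seq_len(nrow(bands))) {
      shape <- exp(-(wl - bands$center[j])^2 / (2 * bands$width[j]^2))
      out <- out - outer(y * bands$coefficient[j], shape)
    }
  }
  out
}

#' Simulate a set of soil sample spectra
#'
#' Draws nutrient contents from the configured truncated normal, builds
#' clean spectra as a smooth baseline minus Gaussian absorption features
#' whose depth is proportional to the nutrient content, then applies
#' per-sample affine scatter (`a_i * clean + b_i`) and white noise. The
#' ground truth (contents, planted band indices, scatter coefficients,
#' clean spectra) is returned alongside.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `spectra` (a [spectra_matrix]), `targets`
#'   (data.frame `id`, `value`, `property`), and `truth` (list: `y`,
#'   `planted_indices`, `scatter` data.frame with `slope_a`/`intercept_b`,
#'   `clean` matrix).
#' @export
simulate_samples <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wl <- config$wavelengths
  bands <- config$informative_bands
  if (nrow(bands) > 0 && all(bands$coefficient == 0))
    stop("all informative-band coefficients are zero")
  with_seed(config$seed, {
    n <- config$n_samples
    y <- rtruncnorm(n, config$nutrient_mean, config$nutrient_sd,
                    config$nutrient_lo, config$nutrient_hi)
    clean <- clean_spectra(y, wl, bands)
    a <- stats::runif(n, 1 - config$scatter_slope_delta,
                      1 + config$scatter_slope_delta)
    b <- stats::runif(n, -config$scatter_offset_delta,
                      config$scatter_offset_delta)
    noise <- matrix(stats::rnorm(n * length(wl), 0, config$noise_sd),
                    n, length(wl))
    observed <- clean * a + b + noise
    ids <- paste0("syn", seq_len(n))
    planted <- if (nrow(bands) > 0)
      vapply(bands$center, function(cc) which.min(abs(wl - cc)), integer(1))
    else integer(0)
    list(spectra = spectra_matrix(observed, wl, ids),
         targets = data.frame(id = ids, value = y,
                              property = config$property,
                              stringsAsFactors = FALSE),
         truth = list(y = y, planted_indices = planted,
                      scatter = data.frame(slope_a = a, intercept_b = b),
                      clean = clean))
  })
}

#' Simulate a hyperspectral reflectance cube
#'
#' A smooth two-dimensional nutrient field (a seeded mixture of Gaussian
#' bumps rescaled into the configured nutrient range) drives per-pixel
#' spectra exactly as in [simulate_samples()]. A multiplicative stripe
#' shading of the given spatial period and depth (emulating the ~1 m
#' furrow pattern of ploughed fields seen at 0.1 m resolution) is
#' superimposed along the column axis, plus white noise.
#'
#' @param config a [synthetic_config()].
#' @param rows,cols cube size in pixels.
#' @param stripe_period_m stripe period in metres (default 1.0).
#' @param pixel_size_m pixel size in metres (default 0.1).
#' @param stripe_depth stripe modulation amplitude as a fraction of the
#'   signal (default 0.1; 0 disables striping).
#' @param n_bumps number of Gaussian bumps in the nutrient field.
#' @return A list with `cube` (a [hypercube]) and `truth` (list: `field`
#'   rows x cols nutrient truth, `planted_indices`, `shading` per-column
#'   stripe factor).
#' @export
simulate_cube <- function(config, rows = 40L, cols = 40L,
                          stripe_period_m = 1.0, pixel_size_m = 0.1,
                          stripe_depth = 0.1, n_bumps = 4L) {
  stopifnot(inherits(config, "synthetic_config"))
  rows <- as.integer(rows); cols <- as.integer(cols)
  period_px <- stripe_period_m / pixel_size_m
  if (rows < period_px || cols < period_px)
    stop("cube smaller than one stripe period")
  wl <- config$wavelengths
  bands <- config$informative_bands
  with_seed(config$seed, {
    # smooth nutrient field from Gaussian bumps, rescaled into range
    cx <- stats::runif(n_bumps, 1, rows)
    cy <- stats::runif(n_bumps, 1, cols)
    amp <- stats::runif(n_bumps, 0.5, 1)
    sig <- stats::runif(n_bumps, 0.2, 0.5) * max(rows, cols)
    field <- matrix(0, rows, cols)
    for (g in seq_len(n_bumps)) {
      field <- field + amp[g] *
        outer(exp(-(seq_len(rows) - cx[g])^2 / (2 * sig[g]^2)),
              exp(-(seq_len(cols) - cy[g])^2 / (2 * sig[g]^2)))
    }
    rng <- range(field)
    span <- if (diff(rng) < .Machine$double.eps) 1 else diff(rng)
    field <- config$nutrient_lo +
      (config$nutrient_hi - config$nutrient_lo) * (field - rng[1]) / span
    shading <- 1 + stripe_depth *
      sin(2 * pi * (seq_len(cols) - 1) * pixel_size_m / stripe_period_m)
    clean <- clean_spectra(as.vector(field), wl, bands)  # (rows*cols) x m
    shade_px <- rep(shading, each = rows)
    noise <- matrix(stats::rnorm(length(clean), 0, config$noise_sd),
                    nrow(clean), ncol(clean))
    observed <- clean * shade_px + noise
    cube <- hypercube(array(observed, c(rows, cols, length(wl))), wl,
                      pixel_size_m = pixel_size_m)
    planted <- if (nrow(bands) > 0)
      vapply(bands$center, function(cc) which.min(abs(wl - cc)), integer(1))
    else integer(0)
    list(cube = cube,
         truth = list(field = field, planted_indices = planted,
                      shading = shading))
  })
}
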