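#' Construct a spectra matrix
#'
#' A `spectra_matrix` holds reflectance spectra for a set of samples on a
#' shared wavelength grid: an n x m matrix of reflectance values (rows =
#' samples, columns = bands), a strictly ascending wavelength vector in nm,
#' and sample identifiers.
#'
#' @param values numeric matrix, n samples x m bands; reflectance
#'   (dimensionless, typically within \[0, 1.2\]).
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly ascending, length m.
#' @param ids character vector of sample identifiers, length n. Defaults to
#'   `"s1", "s2", ...`.
#' @return An object of class `spectra_matrix`: a list with elements
#'   `values`, `wavelengths`, `ids`.
#' @examples
#' sm <- spectra_matrix(matrix(runif(20), 4, 5), seq(500, 540, by = 10))
#' print(sm)
#' @export
spectra_matrix <- function(values, wavelengths, ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths))
    stop("number of columns of 'values' (", ncol(values),
         ") does not match length of 'wavelengths' (", length(wavelengths), ")")
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly ascending")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite with no missing entries")
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values))
    stop("length of 'ids' does not match number of rows")
  rownames(values) <- ids
  colnames(values) <- format(wavelengths, trim = TRUE)
  structure(list(values = values, wavelengths = wavelengths, ids = ids),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat("spectra_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " bands (", format(min(x$wavelengths)), "-",
      format(max(x$wavelengths)), " nm)\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$values)

#' @export
`[.spectra_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  spectra_matrix(x$values[i, j, drop = FALSE], x$wavelengths[j], x$ids[i])
}

#' Construct a hyperspectral cube
#'
#' A `hypercube` is a rows x cols x bands reflectance raster with a shared
#' wavelength grid, a validity mask (TRUE = valid soil pixel) and a ground
#' pixel size in metres.
#'
#' @param values numeric array rows x cols x m.
#' @param wavelengths ascending numeric vector, length m (nm).
#' @param mask logical rows x cols matrix; defaults to all TRUE.
#' @param pixel_size_m positive scalar, ground sampling distance in metres.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, wavelengths, mask = NULL, pixel_size_m = 0.1) {
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-d array (rows x cols x bands)")
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (dim(values)[3] != length(wavelengths))
    stop("third dimension of 'values' does not match 'wavelengths'")
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly ascending")
  if (is.null(mask)) mask <- matrix(TRUE, dim(values)[1], dim(values)[2])
  mask <- as.matrix(mask)
  if (!is.logical(mask)) stop("'mask' must be logical")
  if (!all(dim(mask) == dim(values)[1:2]))
    stop("'mask' shape does not match the spatial shape of 'values'")
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1L ||
      pixel_size_m <= 0)
    stop("'pixel_size_m' must be a positive scalar")
  structure(list(values = values, wavelengths = wavelengths, mask = mask,
                 pixel_size_m = as.numeric(pixel_size_m)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat("hypercube: ", d[1], " x ", d[2], " pixels x ", d[3], " bands (",
      format(min(x$wavelengths)), "-", format(max(x$wavelengths)),
      " nm), pixel ", x$pixel_size_m, " m, ",
      sum(x$mask), "/", d[1] * d[2], " valid\n", sep = "")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Extract valid-pixel spectra from a cube
#'
#' Flattens the valid (masked-in) pixels of a hypercube into a
#' `spectra_matrix`, one row per valid pixel, in column-major pixel order.
#'
#' @param cube a [hypercube].
#' @return A [spectra_matrix] with ids `"px<row>_<col>"`.
#' @export
cube_to_spectra <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  keep <- as.vector(cube$mask)
  idx <- which(keep)
  rc <- arrayInd(idx, d[1:2])
  spectra_matrix(flat[idx, , drop = FALSE], cube$wavelengths,
                 paste0("px", rc[, 1], "_", rc[, 2]))
}

# coerce a plain matrix (with wavelengths) or pass a spectra_matrix through
as_spectra <- function(x, wavelengths = NULL) {
  if (inherits(x, "spectra_matrix")) return(x)
  if (is.null(wavelengths))
    stop("wavelengths required to interpret a plain matrix as spectra")
  spectra_matrix(as.matrix(x), wavelengths)
}

# run a per-spectrum matrix operation over either container kind;
# f takes (matrix, wavelengths) and returns list(values, wavelengths)
map_spectral <- function(data, f) {
  if (inherits(data, "spectra_matrix")) {
    out <- f(data$values, data$wavelengths)
    spectra_matrix(out$values, out$wavelengths, data$ids)
  } else if (inherits(data, "hypercube")) {
    d <- dim(data$values)
    flat <- matrix(data$values, d[1] * d[2], d[3])
    out <- f(flat, data$wavelengths)
    hypercube(array(out$values, c(d[1], d[2], length(out$wavelengths))),
              out$wavelengths, data$mask, data$pixel_size_m)
  } else stop("'data' must be a spectra_matrix or hypercube")
}

# restore-on-exit seeded evaluation; seed = NULL leaves the RNG stream alone
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
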