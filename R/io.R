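#' Read and write sample spectra as CSV
#'
#' The on-disk layout is one header row `id,<wl_1>,...,<wl_m>` (wavelength
#' column names in nm) followed by one row per sample.
#'
#' @param path CSV file path.
#' @param spectra a [spectra_matrix] (for writing).
#' @return `read_spectra_csv` returns a [spectra_matrix];
#'   `write_spectra_csv` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "id")
    stop("malformed spectra CSV: expected columns id,<wavelengths...>")
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wl))
    stop("malformed spectra CSV: non-numeric wavelength column names")
  spectra_matrix(as.matrix(df[, -1, drop = FALSE]), wl, df$id)
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  df <- data.frame(id = spectra$ids, spectra$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", format(spectra$wavelengths, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write measured nutrient targets as CSV
#'
#' Layout: `id,SOM_g_kg,STN_g_kg` (either nutrient column may be absent).
#'
#' @param path CSV file path.
#' @param targets data.frame with an `id` column and one or more numeric
#'   nutrient columns (for writing).
#' @return `read_targets_csv` returns a data.frame.
#' @export
read_targets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("malformed targets CSV: no 'id' column")
  df
}

#' @rdname read_targets_csv
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(targets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a hypercube as an ENVI raster
#'
#' Writes the flat binary data file at `path` plus the text header
#' `<path>.hdr` carrying the band count, interleave, wavelength list and
#' data-ignore value. Masked-out pixels are written as the ignore value
#' in every band. Data are stored as 8-byte IEEE doubles (ENVI data type
#' 5) by default so the round trip is lossless; 4-byte floats (type 4)
#' can be requested.
#'
#' @param cube a [hypercube].
#' @param path data file path (header is `<path>.hdr`).
#' @param interleave `"bsq"` (default) or `"bil"`.
#' @param data_type ENVI data type code, 5 = double (default), 4 = float.
#' @param ignore_value value written for masked-out pixels.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil"),
                       data_type = 5L, ignore_value = -9999) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) stop("'data_type' must be 4 or 5")
  d <- dim(cube$values)
  vals <- cube$values
  if (!all(cube$mask)) {
    bad <- which(!cube$mask)
    for (b in seq_len(d[3])) {
      band <- vals[, , b]; band[bad] <- ignore_value; vals[, , b] <- band
    }
  }
  # ENVI stores row-major (line by line); R arrays are column-major
  if (interleave == "bsq") {
    out <- as.vector(aperm(vals, c(2, 1, 3)))        # sample, line, band
  } else {
    out <- as.vector(aperm(vals, c(2, 3, 1)))        # sample, band, line
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con, size = if (data_type == 5L) 8L else 4L,
           endian = "little")
  hdr <- c("ENVI",
           "file type = ENVI Standard",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           paste0("data type = ", data_type),
           paste0("interleave = ", interleave),
           "byte order = 0",
           "wavelength units = nm",
           paste0("pixel size = {", cube$pixel_size_m, ", ",
                  cube$pixel_size_m, "}"),
           paste0("data ignore value = ", ignore_value),
           paste0("wavelength = {",
                  paste(format(cube$wavelengths, trim = TRUE, digits = 12),
                        collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read an ENVI raster as a hypercube
#'
#' Parses the `<path>.hdr` text header (BSQ or BIL interleave, data types
#' 4 and 5, little or big endian) and the flat binary data file. Pixels
#' equal to the header's data-ignore value in every band are masked out.
#'
#' @param path data file path (header at `<path>.hdr`).
#' @return A [hypercube].
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  hdr <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ENVI header: missing field(s) ",
         paste(miss, collapse = ", "))
  samples <- as.integer(hdr[["samples"]])
  lines <- as.integer(hdr[["lines"]])
  bands <- as.integer(hdr[["bands"]])
  dtype <- as.integer(hdr[["data type"]])
  if (!dtype %in% c(4L, 5L))
    stop("unsupported ENVI data type: ", dtype)
  size <- if (dtype == 5L) 8L else 4L
  endian <- if (!is.null(hdr[["byte order"]]) &&
                as.integer(hdr[["byte order"]]) == 1L) "big" else "little"
  n_expected <- samples * lines * bands
  n_bytes <- file.size(path)
  if (is.na(n_bytes) || n_bytes != n_expected * size)
    stop("ENVI data size (", n_bytes, " bytes) does not match header (",
         samples, " x ", lines, " x ", bands, " x ", size, " bytes)")
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "double", n = n_expected, size = size,
                      endian = endian)
  interleave <- tolower(hdr[["interleave"]])
  arr <- switch(interleave,
    bsq = aperm(array(raw_vals, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(raw_vals, c(samples, bands, lines)), c(3, 1, 2)),
    stop("unsupported interleave: ", interleave))
  wl <- if (!is.null(hdr[["wavelength"]]))
    as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  else seq_len(bands)
  if (length(wl) != bands)
    stop("malformed ENVI header: wavelength list has ", length(wl),
         " entries for ", bands, " bands")
  px <- 0.1
  if (!is.null(hdr[["pixel size"]])) {
    ps <- as.numeric(strsplit(hdr[["pixel size"]], ",")[[1]])
    if (length(ps) >= 1 && is.finite(ps[1]) && ps[1] > 0) px <- ps[1]
  }
  mask <- matrix(TRUE, lines, samples)
  if (!is.null(hdr[["data ignore value"]])) {
    ig <- as.numeric(hdr[["data ignore value"]])
    mask <- apply(arr != ig, c(1, 2), all)
  }
  hypercube(arr, wl, mask, px)
}

# key = value header parser; {...} blocks may span lines
parse_envi_header <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1]))
    stop("malformed ENVI header: missing ENVI magic line")
  body <- paste(txt[-1], collapse = "\n")
  out <- list()
  pat <- gregexpr("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  body)[[1]]
  if (pat[1] == -1) return(out)
  for (i in seq_along(pat)) {
    piece <- substr(body, pat[i], pat[i] + attr(pat, "match.length")[i] - 1)
    key <- trimws(sub("=.*$", "", piece))
    val <- trimws(sub("^[^=]*=", "", piece))
    val <- gsub("^\\{|\\}$", "", val)
    out[[tolower(key)]] <- trimws(gsub("\n", " ", val))
  }
  out
}

#' Serialize a fitted model to JSON
#'
#' Writes ELM, PLSR or full pipeline (`soil_model`) objects as versioned
#' JSON with embedded numeric arrays at full precision, so that a
#' reloaded model predicts identically.
#'
#' @param model an `elm_model`, `plsr_model`, `pso_elm` or `soil_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- list(format = "soilspec-model", version = 1L,
                  class = class(model)[1],
                  data = serialize_model(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

serialize_model <- function(model) {
  if (inherits(model, "elm_model")) {
    list(input_weights = model$input_weights,
         hidden_biases = model$hidden_biases,
         output_weights = model$output_weights,
         activation = model$activation,
         input_scaling = model$input_scaling,
         n_hidden = model$n_hidden)
  } else if (inherits(model, "plsr_model")) {
    list(coefficients = model$coefficients, x_mean = model$x_mean,
         y_mean = model$y_mean, n_components = model$n_components,
         algorithm = model$algorithm)
  } else if (inherits(model, "pso_elm")) {
    list(model = serialize_model(model$model),
         best_value = model$trace$best_value)
  } else if (inherits(model, "soil_model")) {
    reg <- model$regressor
    list(preprocess = list(method = model$preprocess$method,
                           reference = model$preprocess$reference),
         selection = list(method = model$selection$method,
                          band_indices = model$selection$band_indices,
                          wavelengths_nm = model$selection$wavelengths_nm),
         model_type = model$model_type,
         property = model$property,
         wavelengths = model$wavelengths,
         regressor_class = if (inherits(reg, "pso_elm")) "elm_model"
                           else class(reg)[1],
         regressor = serialize_model(
           if (inherits(reg, "pso_elm")) reg$model else reg))
  } else stop("cannot serialize objects of class ", class(model)[1])
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file path.
#' @return The deserialized model object.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "soilspec-model"))
    stop("not a soilspec model file: ", path)
  if (!identical(as.integer(payload$version), 1L))
    stop("unknown model file version: ", payload$version)
  deserialize_model(payload$class, payload$data)
}

deserialize_model <- function(cls, d) {
  if (cls == "elm_model") {
    structure(list(input_weights = as.matrix(d$input_weights),
                   hidden_biases = as.numeric(d$hidden_biases),
                   output_weights = as.numeric(d$output_weights),
                   activation = d$activation,
                   input_scaling = {
                     sc <- as.matrix(d$input_scaling)
                     rownames(sc) <- c("lo", "hi"); sc
                   },
                   n_hidden = as.integer(d$n_hidden)),
              class = "elm_model")
  } else if (cls == "plsr_model") {
    structure(list(coefficients = as.numeric(d$coefficients),
                   x_mean = as.numeric(d$x_mean),
                   y_mean = as.numeric(d$y_mean),
                   n_components = as.integer(d$n_components),
                   algorithm = d$algorithm),
              class = "plsr_model")
  } else if (cls == "pso_elm") {
    structure(list(model = deserialize_model("elm_model", d$model),
                   trace = list(best_value = d$best_value),
                   validation = NULL),
              class = "pso_elm")
  } else if (cls == "soil_model") {
    reg <- deserialize_model(d$regressor_class, d$regressor)
    structure(list(preprocess = list(
                     method = d$preprocess$method,
                     reference = if (is.null(d$preprocess$reference)) NULL
                                 else as.numeric(d$preprocess$reference)),
                   selection = list(
                     method = d$selection$method,
                     band_indices = as.integer(d$selection$band_indices),
                     wavelengths_nm = as.numeric(d$selection$wavelengths_nm)),
                   regressor = reg, model_type = d$model_type,
                   wavelengths = as.numeric(d$wavelengths),
                   property = d$property),
              class = "soil_model")
  } else stop("unknown model class in file: ", cls)
}
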