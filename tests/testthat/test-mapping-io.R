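make_small_model <- function(seed = 21) {
  cfg <- synthetic_config("SOM", noise_sd = 0.005, seed = seed)
  sim <- simulate_samples(cfg)
  fit <- soil_train(sim$spectra, sim$targets$value, preprocess = "msc",
                    selector = "none", model = "elm", n_hidden = 10,
                    seed = seed)
  list(cfg = cfg, sim = sim, fit = fit)
}

test_that("a cube of repeated training spectra maps to constant predictions", {
  ms <- make_small_model()
  sim <- ms$sim; fit <- ms$fit
  one <- sim$spectra$values[5, ]
  cube <- hypercube(array(rep(one, each = 6 * 4), c(6, 4, length(one))),
                    sim$spectra$wavelengths)
  nm <- predict_cube(fit, cube)
  direct <- predict(fit, sim$spectra[5, ])
  expect_true(all(abs(nm$values - direct) < 1e-12))
  expect_equal(nm$property, "SOM")
})

test_that("masked pixels come back as nodata and provenance is recorded", {
  ms <- make_small_model()
  sim <- ms$sim
  mask <- matrix(TRUE, 5, 5); mask[2, 3] <- FALSE; mask[5, 5] <- FALSE
  cube <- hypercube(array(rep(sim$spectra$values[1, ], each = 25),
                          c(5, 5, ncol(sim$spectra$values))),
                    sim$spectra$wavelengths, mask = mask)
  nm <- predict_cube(ms$fit, cube)
  expect_true(is.na(nm$values[2, 3]))
  expect_true(is.na(nm$values[5, 5]))
  expect_false(anyNA(nm$values[mask]))
  expect_equal(nm$provenance$preprocess, "msc")
  expect_equal(nm$provenance$model_type, "elm")
  # grid mismatch is an error
  bad <- hypercube(cube$values, cube$wavelengths + 1, mask)
  expect_error(predict_cube(ms$fit, bad), "wavelength grid")
})

test_that("noise-free closed loop reproduces the truth map within 1% of range", {
  cfg <- synthetic_config("SOM", noise_sd = 0, scatter_slope_delta = 0.05,
                          scatter_offset_delta = 0.01, seed = 31)
  sim <- simulate_samples(cfg)
  simc <- simulate_cube(cfg, rows = 20, cols = 20, stripe_depth = 0.05)
  fit <- soil_train(sim$spectra, sim$targets$value, preprocess = "msc",
                    selector = "cars_spa", model = "elm", n_hidden = 15,
                    seed = 31)
  nm <- predict_cube(fit, simc$cube)
  rmse <- sqrt(mean((nm$values - simc$truth$field)^2))
  expect_lt(rmse, 0.01 * diff(range(simc$truth$field)))
})

test_that("grade areas match direct pixel counting and sum to 100 per zone", {
  vals <- matrix(c(15, 25, 25, 35,
                   15, 15, 45, 45), 2, 4, byrow = TRUE)
  nm <- structure(list(values = vals, mask = matrix(TRUE, 2, 4),
                       property = "SOM", pixel_size_m = 0.1,
                       provenance = list()), class = "nutrient_map")
  zones <- matrix(c("a", "a", "b", "b",
                    "a", "a", "b", "b"), 2, 4, byrow = TRUE)
  ga <- grade_areas(nm, zones = zones)
  for (z in c("a", "b"))
    expect_equal(sum(ga$percent[ga$zone == z]), 100, tolerance = 1e-9)
  # direct counts: zone a = {15,25,15,15}, zone b = {25,35,45,45}
  expect_equal(ga$n_pixels[ga$zone == "a" & ga$grade == "G4"], 3)
  expect_equal(ga$n_pixels[ga$zone == "a" & ga$grade == "G3"], 1)
  expect_equal(ga$percent[ga$zone == "b" & ga$grade == "G1"], 50)
  # uniform map lands 100% in one grade
  nm2 <- nm; nm2$values[] <- 22
  ga2 <- grade_areas(nm2)
  expect_equal(ga2$percent[ga2$grade == "G3"], 100)
  expect_true(all(ga2$percent[ga2$grade != "G3"] == 0))
})

test_that("a zone with no valid pixels is reported empty, not an error", {
  vals <- matrix(20, 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  nm <- structure(list(values = ifelse(mask, vals, NA), mask = mask,
                       property = "SOM", pixel_size_m = 0.1,
                       provenance = list()), class = "nutrient_map")
  zones <- matrix(c("a", "a", "b", "b"), 2, 2)
  ga <- grade_areas(nm, zones = zones)
  expect_true(all(is.na(ga$percent[ga$zone == "b"])))
  expect_equal(sum(ga$n_pixels[ga$zone == "b"]), 0)
  expect_equal(sum(ga$percent[ga$zone == "a"]), 100, tolerance = 1e-9)
})

test_that("ENVI cubes round-trip losslessly in BSQ and BIL", {
  for (il in c("bsq", "bil")) {
    cube <- random_cube(5, 7, 4, seed = 17)
    cube$mask[3, 2] <- FALSE
    path <- file.path(tempdir(), paste0("rt_", il, ".dat"))
    write_envi(cube, path, interleave = il)
    back <- read_envi(path)
    expect_equal(back$wavelengths, cube$wavelengths)
    expect_identical(back$mask, cube$mask)
    expect_equal(back$values[cube$mask], cube$values[rep(cube$mask, 4)],
                 tolerance = 0)
    expect_equal(back$pixel_size_m, cube$pixel_size_m)
    unlink(c(path, paste0(path, ".hdr")))
  }
})

test_that("an ENVI header that disagrees with the data size is rejected", {
  cube <- random_cube(4, 4, 3)
  path <- file.path(tempdir(), "bad.dat")
  write_envi(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  hdr <- sub("^bands = 3", "bands = 5", hdr)
  writeLines(hdr, paste0(path, ".hdr"))
  expect_error(read_envi(path), "does not match header")
  writeLines(c("not a header"), paste0(path, ".hdr"))
  expect_error(read_envi(path), "ENVI")
  unlink(c(path, paste0(path, ".hdr")))
})

test_that("spectra and targets CSV round-trip", {
  sm <- random_spectra(n = 5, m = 8, seed = 23)
  path <- file.path(tempdir(), "spectra.csv")
  write_spectra_csv(sm, path)
  back <- read_spectra_csv(path)
  expect_equal(back$wavelengths, sm$wavelengths)
  expect_equal(back$values, sm$values, tolerance = 1e-12)
  expect_equal(back$ids, sm$ids)
  tg <- data.frame(id = sm$ids, SOM_g_kg = rnorm(5, 20, 3))
  tpath <- file.path(tempdir(), "targets.csv")
  write_targets_csv(tg, tpath)
  tback <- read_targets_csv(tpath)
  expect_equal(tback$SOM_g_kg, tg$SOM_g_kg, tolerance = 1e-12)
  unlink(c(path, tpath))
})

test_that("model JSON serialization preserves predictions", {
  set.seed(41)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- as.vector(X %*% c(1, 2, -1, 0.5)) + rnorm(30, sd = 0.1)
  path <- file.path(tempdir(), "model.json")
  elm <- elm_fit(X, y, n_hidden = 7, seed = 2)
  save_model(elm, path)
  expect_equal(predict(load_model(path), X), predict(elm, X),
               tolerance = 1e-12)
  pls <- plsr_fit(X, y, 3)
  save_model(pls, path)
  expect_equal(predict(load_model(path), X), predict(pls, X),
               tolerance = 1e-12)
  # full pipeline round-trip, including the MSC reference
  ms <- make_small_model(seed = 43)
  save_model(ms$fit, path)
  back <- load_model(ms$fit |> save_model(path))
  expect_equal(predict(back, ms$sim$spectra),
               predict(ms$fit, ms$sim$spectra), tolerance = 1e-12)
  # version / format guards
  jsonlite::write_json(list(format = "other"), path, auto_unbox = TRUE)
  expect_error(load_model(path), "not a soilspec model")
  unlink(path)
})

test_that("the CLI simulate subcommand is reproducible under --seed", {
  cli <- system.file("cli", "soilspec", package = "soilspec")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out1 <- file.path(tempdir(), "cli_a")
  out2 <- file.path(tempdir(), "cli_b")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  r1 <- system2(rscript, c(cli, "simulate", "--seed", "4", "--n", "12",
                           "--out", out1), env = env, stdout = TRUE,
                stderr = TRUE)
  r2 <- system2(rscript, c(cli, "simulate", "--seed", "4", "--n", "12",
                           "--out", out2), env = env, stdout = TRUE,
                stderr = TRUE)
  a <- readLines(paste0(out1, "_spectra.csv"))
  b <- readLines(paste0(out2, "_spectra.csv"))
  expect_identical(a, b)
  expect_true(file.exists(paste0(out1, ".manifest.json")))
  unlink(Sys.glob(file.path(tempdir(), "cli_*")))
})
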