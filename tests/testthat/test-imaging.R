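# Reflectance calibration, segmentation, mean spectra, band trimming

make_cube <- function(vals, wl = NULL, sensor = "VIS_SWNIR") {
  if (is.null(wl)) wl <- seq(500, 900, length.out = dim(vals)[3])
  hypercube(vals, wl, sensor)
}

test_that("hypercube validates its axes and sensor range", {
  v <- array(0.5, c(4, 4, 3))
  expect_error(hypercube(v, c(500, 600), "VIS_SWNIR"), "wavelength")
  expect_error(hypercube(v, c(600, 550, 700), "VIS_SWNIR"), "increasing")
  expect_error(hypercube(v, c(200, 500, 700), "VIS_SWNIR"), "within")
  expect_error(hypercube(v, c(1000, 1200, 1400), "LWNIR"), NA)
})

test_that("reflectance calibration satisfies its closed-form identities", {
  dims <- c(5, 6, 4)
  set.seed(3)
  white <- make_cube(array(runif(prod(dims), 0.8, 1), dims))
  black <- make_cube(array(runif(prod(dims), 0, 0.1), dims))
  expect_equal(correct_image(white, white, black)$values,
               array(1, dims))
  expect_equal(correct_image(black, white, black)$values,
               array(0, dims))
  # scalar check: (0.5 - 0.1) / (0.9 - 0.1) = 0.5
  r <- correct_image(make_cube(array(0.5, dims)),
                     make_cube(array(0.9, dims)),
                     make_cube(array(0.1, dims)))
  expect_equal(r$values, array(0.5, dims))
  expect_true(r$calibrated)
})

test_that("calibration is invariant to a common per-pixel gain", {
  dims <- c(4, 4, 3)
  set.seed(7)
  raw <- array(runif(prod(dims), 0.2, 0.6), dims)
  white <- array(runif(prod(dims), 0.8, 1), dims)
  black <- array(runif(prod(dims), 0, 0.1), dims)
  gain <- array(runif(prod(dims), 0.5, 2), dims)
  a <- correct_image(make_cube(raw), make_cube(white), make_cube(black))
  b <- correct_image(make_cube(raw * gain), make_cube(white * gain),
                     make_cube(black * gain))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("degenerate white-minus-black is rejected with a location", {
  dims <- c(3, 3, 2)
  white <- array(0.9, dims); white[2, 3, 1] <- 0.05
  black <- array(0.05, dims)
  expect_error(correct_image(make_cube(array(0.5, dims)), make_cube(white),
                             make_cube(black)),
               "pixel \\(2, 3\\), band 1")
})

test_that("mask segmentation finds the kernel and rejects empty images", {
  # two-level toy image with a fixed threshold recovers the ROI exactly
  v <- array(0.1, c(20, 20, 3))
  roi <- matrix(FALSE, 20, 20); roi[5:15, 6:14] <- TRUE
  for (b in 1:3) v[, , b][roi] <- 0.8
  cube <- make_cube(v, wl = c(700, 849, 950))
  m <- build_mask(cube, 849, method = "fixed", threshold = 0.4,
                  fill_holes = FALSE, min_area = 0)
  expect_identical(unclass(m)[, ], roi)
  # synthetic scene: Otsu mask covers the true mask with little spillover
  sc <- tiny_scene()
  mo <- build_mask(sc$corrected, 849)
  expect_gt(sum(mo & sc$mask) / sum(sc$mask), 0.95)
  expect_lt(sum(mo & !sc$mask) / sum(mo), 0.05)
  # all-background image
  flat <- make_cube(array(0.1 + 1e-9 * seq_len(prod(c(10, 10, 2))),
                          c(10, 10, 2)), wl = c(840, 860))
  expect_error(build_mask(flat, 849, method = "fixed", threshold = 0.5),
               "no ROI found")
})

test_that("mean spectrum is the pixel average over the mask", {
  v <- array(0.3, c(4, 4, 2))
  cube <- make_cube(v, wl = c(600, 700))
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE; mask[2, 2] <- TRUE
  expect_equal(unname(extract_mean_spectrum(cube, mask)), c(0.3, 0.3))
  v[1, 1, 1] <- 0.2; v[2, 2, 1] <- 0.4
  expect_equal(unname(extract_mean_spectrum(make_cube(v, wl = c(600, 700)),
                                            mask)), c(0.3, 0.3))
  expect_error(extract_mean_spectrum(cube, matrix(FALSE, 4, 4)), "empty")
  # bounded by min/max within the mask at every band
  sc <- tiny_scene()
  sp <- extract_mean_spectrum(sc$corrected, sc$mask)
  vals <- matrix(sc$corrected$values, prod(dim(sc$mask)))
  roi <- vals[as.vector(sc$mask), ]
  expect_true(all(sp >= apply(roi, 2, min) & sp <= apply(roi, 2, max)))
})

test_that("noise-free scene mean spectrum equals base curve times scale", {
  cfg <- scene_config(spatial_size = c(32, 32), vis_bands = 10,
                      texture_noise_sd = c(0, 0, 0, 0))
  sc <- generate_scene(cfg, "moderate", "VIS_SWNIR", seed = 6)
  sp <- extract_mean_spectrum(sc$truth, sc$mask)
  wl <- sensor_wavelengths(cfg, "VIS_SWNIR")
  expect_equal(unname(sp), base_spectrum(wl, "VIS_SWNIR") * 0.72,
               tolerance = 1e-12)
})

test_that("band trimming keeps the requested range and composes", {
  x <- matrix(seq_len(20), 2)
  tr <- trim_bands(x, 1:10, 3, 7)
  expect_equal(ncol(tr$x), 5)
  expect_equal(tr$wavelengths, 3:7)
  expect_identical(trim_bands(x, 1:10, 1, 10)$x, x)
  nested <- trim_bands(tr$x, tr$wavelengths, 4, 6)
  direct <- trim_bands(x, 1:10, 4, 6)
  expect_identical(nested, direct)
  expect_error(trim_bands(x, 1:10, 7, 3), "below")
  expect_error(trim_bands(x, 1:10, 30, 40), "no bands")
  # the configured Vis-SWNIR grid survives trimming to its own range intact
  cfg <- scene_config()
  wl <- sensor_wavelengths(cfg, "VIS_SWNIR")
  keep <- trim_bands(matrix(0, 1, length(wl)), wl, 399, 1001)
  expect_equal(ncol(keep$x), cfg$vis_bands)
})
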