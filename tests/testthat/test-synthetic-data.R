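# Synthetic scene and feature-table generator

test_that("scene_config enforces study-design invariants", {
  expect_s3_class(scene_config(), "scene_config")
  expect_error(scene_config(level_reflectance_scale = c(1, 1, 0.7, 0.6)),
               "decreasing")
  expect_error(scene_config(texture_noise_sd = c(0.05, 0.03, 0.05, 0.07)),
               "nondecreasing")
  expect_error(scene_config(n_per_level = 1))
})

test_that("rendered scenes are deterministic and physically bounded", {
  cfg <- scene_config(spatial_size = c(32, 32), vis_bands = 12)
  a <- generate_scene(cfg, "mild", "VIS_SWNIR", seed = 5)
  b <- generate_scene(cfg, "mild", "VIS_SWNIR", seed = 5)
  expect_identical(a$raw$values, b$raw$values)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$truth$values >= 0 & a$truth$values <= 1.05))
  expect_true(all(a$white$values > a$black$values))
  expect_error(generate_scene(scene_config(spatial_size = c(8, 8),
                                           vis_bands = 12),
                              "mild", "VIS_SWNIR", seed = 1),
               "too small")
})

test_that("noise-free ROI mean reflectance decreases strictly with level", {
  cfg <- scene_config(spatial_size = c(32, 32), vis_bands = 15,
                      texture_noise_sd = c(0, 0, 0, 0),
                      scatter_sd = 0, band_noise_sd = 0)
  means <- sapply(mold_levels(), function(l) {
    sc <- generate_scene(cfg, l, "VIS_SWNIR", seed = 2)
    colMeans(matrix(sc$truth$values, 32 * 32)[as.vector(sc$mask), ])
  })
  # per band: healthy > mild > moderate > severe
  expect_true(all(apply(means, 1, function(r) all(diff(r) < 0))))
  # and equal to base curve x scale exactly (mean-preserving structure)
  wl <- sensor_wavelengths(cfg, "VIS_SWNIR")
  expect_equal(unname(means[, 1]),
               base_spectrum(wl, "VIS_SWNIR") * 1.0, tolerance = 1e-12)
})

test_that("base spectra carry the documented landmarks", {
  wl <- sensor_wavelengths(scene_config(), "VIS_SWNIR")
  b <- base_spectrum(wl, "VIS_SWNIR")
  expect_lt(abs(wl[which.max(b)] - 820), 40)   # peak near 820 nm
  wl2 <- sensor_wavelengths(scene_config(), "LWNIR")
  b2 <- base_spectrum(wl2, "LWNIR")
  ext <- wl2[which(diff(sign(diff(b2))) != 0) + 1]
  # peaks ~1100/1300, troughs ~1192/1445
  expect_true(all(vapply(c(1100, 1192, 1300, 1445),
                         function(t) min(abs(ext - t)) < 25, logical(1))))
})

test_that("CAT generation matches the grading distributions", {
  expect_identical(generate_cat(cat_params(), "healthy", 60, seed = 1),
                   rep(0, 60))
  # degenerate SD: all values exactly at the mean
  p0 <- cat_params(sds = c(0, 0.13, 0.09, 0))
  expect_identical(generate_cat(p0, "severe", 10, seed = 1), rep(2.24, 10))
  # truncation by redraw keeps values nonnegative and the mean on target
  v <- generate_cat(cat_params(), "mild", 1e5, seed = 42)
  expect_true(all(v >= 0))
  expect_lt(abs(mean(v) - 1.57), 0.01)
  expect_error(generate_cat(cat_params(), "rotten", 5), "arg")
  expect_error(cat_params(means = c(0.1, 1.57, 1.91, 2.24)), "exactly 0")
})

test_that("feature tables have the study shapes and balance", {
  data <- generate_feature_tables(scene_config(), seed = 9)
  expect_equal(dim(data$spectra$VIS_SWNIR), c(240, 389))
  expect_equal(dim(data$spectra$LWNIR), c(240, 112))
  for (p in names(data$texture$LWNIR))
    expect_equal(ncol(data$texture$LWNIR[[p]]), 112)
  expect_equal(as.vector(table(data$samples$level)), rep(60L, 4))
  # determinism
  data2 <- generate_feature_tables(scene_config(), seed = 9)
  expect_identical(data$spectra$VIS_SWNIR, data2$spectra$VIS_SWNIR)
  expect_identical(data$samples$cat, data2$samples$cat)
})

test_that("noise-free class-mean spectra equal base curves times scale", {
  cfg <- scene_config(n_per_level = 3, vis_bands = 20, lwnir_bands = 15,
                      scatter_sd = 0, band_noise_sd = 0)
  data <- generate_feature_tables(cfg, seed = 1)
  wl <- sensor_wavelengths(cfg, "VIS_SWNIR")
  base <- base_spectrum(wl, "VIS_SWNIR")
  for (li in 1:4) {
    rows <- which(as.integer(data$samples$level) == li)
    cm <- colMeans(data$spectra$VIS_SWNIR[rows, , drop = FALSE])
    expect_equal(unname(cm), base * cfg$level_reflectance_scale[li],
                 tolerance = 1e-12)
  }
})

test_that("fast-path texture means are ordered by mold level", {
  data <- generate_feature_tables(scene_config(n_per_level = 30), seed = 4)
  for (s in c("VIS_SWNIR", "LWNIR")) {
    lm <- function(p) sapply(1:4, function(li) mean(
      data$texture[[s]][[p]][as.integer(data$samples$level) == li, ]))
    expect_true(all(diff(lm("contrast")) > 0))
    expect_true(all(diff(lm("energy")) < 0))
  }
})

test_that("planted benchmark block marks genuinely informative columns", {
  pb <- make_planted_block(n = 80, p = 40, n_informative = 5, seed = 8)
  expect_length(pb$informative, 5)
  gap <- function(j) abs(mean(pb$X[pb$y == "severe", j]) -
                           mean(pb$X[pb$y == "healthy", j]))
  gaps_inf <- vapply(pb$informative, gap, numeric(1))
  gaps_noise <- vapply(setdiff(1:40, pb$informative), gap, numeric(1))
  expect_gt(min(gaps_inf), max(0.5, mean(gaps_noise)))
})
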