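# GLCM quantization, co-occurrence counting, texture parameters

test_that("quantization bins ROI values into equal-width levels", {
  mask <- matrix(TRUE, 1, 4)
  g <- matrix(c(0, 0.33, 0.66, 1.0), 1)
  expect_equal(as.vector(quantize(g, mask, 2)), c(1L, 1L, 2L, 2L))
  # uniform span, N = 8: bin edges at k/8
  g8 <- matrix(seq(0, 1, length.out = 17), 1)
  q <- quantize(g8, matrix(TRUE, 1, 17), 8)
  expect_equal(as.vector(q), pmin(floor(seq(0, 1, length.out = 17) * 8) + 1, 8))
  # constant band flagged, all level 1
  qc <- quantize(matrix(0.5, 2, 2), matrix(TRUE, 2, 2), 8)
  expect_true(attr(qc, "constant"))
  expect_true(all(qc == 1L))
  # background is invalid
  m2 <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  q2 <- quantize(matrix(1:4 / 4, 2), m2, 2)
  expect_true(is.na(q2[!m2]))
})

test_that("single-pair image gives a one-hot GLCM", {
  L <- matrix(c(1L, 2L), 1)
  P <- glcm(L, n_levels = 2, angle = 0)
  expect_equal(P, matrix(c(0, 0, 1, 0), 2))  # P[1,2] = 1
  expect_error(glcm(L, 2, angle = 90), "no valid")
})

test_that("3x3 worked example matches hand enumeration", {
  L <- matrix(c(1L, 1L, 2L,
                1L, 2L, 2L,
                2L, 2L, 1L), 3, 3, byrow = TRUE)
  P <- glcm(L, n_levels = 2, angle = 0)
  # 6 horizontal ordered pairs: (1,1) (1,2) (1,2) (2,2) (2,2) (2,1)
  expect_equal(P, matrix(c(1, 1, 2, 2) / 6, 2))
  expect_equal(texture_params(P), brute_texture_params(P), tolerance = 1e-14)
})

test_that("GLCM and parameters match the brute-force oracle exactly", {
  set.seed(99)
  for (rep in 1:50) {
    L <- matrix(sample(1:8, 64, replace = TRUE), 8, 8)
    if (rep %% 3 == 0) L[sample(64, 10)] <- NA   # background holes
    for (ang in c(0, 45, 90, 135)) {
      P <- glcm(L, 8, ang)
      expect_equal(P, brute_glcm(L, 8, ang), tolerance = 1e-14)
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(texture_params(P), brute_texture_params(P),
                   tolerance = 1e-12)
    }
  }
})

test_that("texture parameter identities hold on degenerate GLCMs", {
  # all mass on one diagonal cell
  P <- matrix(0, 4, 4); P[3, 3] <- 1
  tp <- texture_params(P)
  expect_equal(unname(tp[c("contrast", "energy", "homogeneity")]),
               c(0, 1, 1))
  expect_equal(unname(tp["correlation"]), 0)  # zero marginal SD -> 0
  expect_true(isTRUE(attr(tp, "correlation_undefined")))
  # uniform over N^2 = 4 cells: energy = 4 * 0.25^2
  expect_equal(unname(texture_params(matrix(0.25, 2, 2))["energy"]), 0.25)
})

test_that("band texture rows respond to spatial structure", {
  # constant ROI: contrast 0 at all bands
  v <- array(0.5, c(10, 10, 3))
  cube <- hypercube(v, c(600, 700, 800), "VIS_SWNIR", calibrated = TRUE)
  mask <- matrix(TRUE, 10, 10)
  tm <- band_texture_matrix(cube, mask)
  expect_equal(unname(tm["contrast", ]), c(0, 0, 0))
  # vertical stripes: horizontal steps >> vertical steps
  stripes <- matrix(rep(c(0.2, 0.8), each = 16, times = 8), 16, 16)
  L <- quantize(stripes, matrix(TRUE, 16, 16), 8)
  c0 <- texture_params(glcm(L, 8, 0))["contrast"]
  c90 <- texture_params(glcm(L, 8, 90))["contrast"]
  expect_gt(c0, c90)
})

test_that("scene texture blocks have one value per band and level order", {
  sc <- tiny_scene(bands = 12)
  tm <- band_texture_matrix(sc$corrected, sc$mask)
  expect_equal(dim(tm), c(4L, 12L))
  expect_true(all(is.finite(tm)))
  expect_true(all(tm["energy", ] > 0 & tm["energy", ] <= 1))
  expect_true(all(tm["homogeneity", ] > 0 & tm["homogeneity", ] <= 1))
  expect_true(all(tm["contrast", ] >= 0))
})

test_that("rendered class-mean contrast rises and energy falls with level", {
  cfg <- scene_config(spatial_size = c(48, 48), vis_bands = 8)
  cm <- sapply(seq_along(mold_levels()), function(li) {
    acc <- 0
    for (r in 1:4) {
      sc <- generate_scene(cfg, mold_levels()[li], "VIS_SWNIR",
                           seed = 500 + 10 * li + r)
      cc <- correct_image(sc$raw, sc$white, sc$black)
      acc <- acc + rowMeans(band_texture_matrix(cc, sc$mask)) / 4
    }
    acc
  })
  expect_true(all(diff(cm["contrast", ]) > 0))
  expect_true(all(diff(cm["energy", ]) < 0))
})

test_that("full-path and fast-path class means agree in structure", {
  cfg <- scene_config(spatial_size = c(48, 48), vis_bands = 8)
  rendered <- sapply(seq_along(mold_levels()), function(li) {
    acc <- 0
    for (r in 1:4) {
      sc <- generate_scene(cfg, mold_levels()[li], "VIS_SWNIR",
                           seed = 700 + 10 * li + r)
      cc <- correct_image(sc$raw, sc$white, sc$black)
      acc <- acc + rowMeans(band_texture_matrix(cc, sc$mask)) / 4
    }
    acc
  })
  data <- generate_feature_tables(scene_config(n_per_level = 25), seed = 7)
  fast <- sapply(1:4, function(li) sapply(
    names(data$texture$VIS_SWNIR), function(p)
      mean(data$texture$VIS_SWNIR[[p]][
        as.integer(data$samples$level) == li, ])))
  # same level trend, and values within Monte-Carlo distance
  for (p in c("contrast", "correlation", "energy", "homogeneity")) {
    expect_gt(cor(fast[p, ], rendered[p, ]), 0.85)
    expect_true(all(abs(fast[p, ] - rendered[p, ]) /
                      pmax(abs(rendered[p, ]), 0.05) < 0.35))
  }
  expect_true(all(diff(fast["contrast", ]) > 0))
  expect_true(all(diff(rendered["contrast", ]) > 0))
})
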