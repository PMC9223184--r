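# Spectral pretreatment chains

test_that("moving-average smoothing has the textbook behaviour", {
  B <- 30
  const <- matrix(0.7, 1, B)
  expect_equal(smooth_spectra(const, 9), const)
  ramp <- matrix(seq_len(B), 1)
  sm <- smooth_spectra(ramp, 9)
  expect_equal(sm[1, 5:(B - 4)], ramp[1, 5:(B - 4)])  # interior unchanged
  imp <- matrix(0, 1, B); imp[1, 15] <- 1
  si <- smooth_spectra(imp, 9)
  expect_equal(si[1, 11:19], rep(1 / 9, 9))
  expect_equal(sum(si[1, -(11:19)]), 0)
  expect_error(smooth_spectra(ramp, 8), "odd")
  expect_error(smooth_spectra(ramp, 33), "bands")
})

test_that("MSC removes affine scatter distortions", {
  ref <- sin(seq(0, 3, length.out = 40)) + 2
  x <- matrix(2 * ref + 3, 1)
  expect_equal(unname(msc(x, reference = ref)[1, ]), ref)
  expect_equal(unname(msc(matrix(ref, 1), reference = ref)[1, ]), ref)
  # random affine distortions of a common shape collapse to that shape
  set.seed(21)
  n <- 12
  X <- t(sapply(seq_len(n), function(i)
    runif(1, 0.5, 2) * ref + runif(1, -1, 1)))
  out <- msc(X)
  expect_lt(max(apply(out, 2, sd)), 1e-8)
})

test_that("degenerate MSC rows pass through with a warning", {
  ref <- seq(1, 2, length.out = 10)
  X <- rbind(2 * ref, rep(5, 10))   # second row has b ~ 0
  expect_warning(out <- msc(X, reference = ref), "unchanged")
  expect_equal(unname(out[2, ]), rep(5, 10))
})

test_that("detrend projects out the linear baseline and is idempotent", {
  wl <- seq(400, 1000, length.out = 50)
  lin <- matrix(3 + 0.01 * wl, 1)
  expect_equal(max(abs(detrend_spectra(lin, wl))), 0, tolerance = 1e-10)
  quad <- matrix(1e-5 * (wl - 700)^2, 1)
  resid <- detrend_spectra(quad, wl)
  wc <- wl - mean(wl)
  expect_lt(abs(mean(resid)), 1e-10)
  expect_lt(abs(sum(resid * wc) / sum(wc^2)), 1e-10)
  expect_equal(detrend_spectra(resid, wl), resid, tolerance = 1e-12)
})

test_that("centering freezes calibration means for prediction rows", {
  set.seed(5)
  cal <- matrix(rnorm(60), 10, 6)
  centered <- center_spectra(cal)
  expect_lt(max(abs(colMeans(centered))), 1e-12)
  mu <- attr(centered, "column_means")
  pred <- matrix(rnorm(12, mean = 3), 2, 6)   # shifted prediction rows
  with_cal <- center_spectra(pred, fitted_means = mu)
  with_own <- center_spectra(pred)
  expect_false(isTRUE(all.equal(with_cal, with_own,
                                check.attributes = FALSE)))
  expect_equal(unname(with_cal), unname(sweep(pred, 2, mu)),
               ignore_attr = TRUE)
  expect_error(center_spectra(pred, fitted_means = mu[1:3]), "length")
})

test_that("chains compose, record provenance, and reject bad recipes", {
  wl <- seq(400, 1000, length.out = 60)
  set.seed(31)
  x <- matrix(rnorm(5 * 60), 5)
  expect_equal(unname(preprocess_chain(x, wl, "")), x, ignore_attr = TRUE)
  out <- preprocess_chain(x, wl, "smooth-detrend")
  expect_identical(attr(out, "provenance"), "smooth-detrend")
  expect_error(preprocess_chain(x, wl, "smooth-snv"), "unknown")
  expect_error(preprocess_chain(x, wl, "detrend-smooth"), "first")
  # smooth-detrend flattens a noisy line down to the noise floor
  noisy_line <- matrix(rep(2 + 0.005 * wl, 4), 4, byrow = TRUE) +
    matrix(rnorm(4 * 60, 0, 0.01), 4)
  flat <- preprocess_chain(noisy_line, wl, "smooth-detrend")
  expect_lt(max(abs(flat)), 0.02)
})

test_that("fitted context makes chains identical on joined or split data", {
  wl <- seq(400, 1000, length.out = 40)
  set.seed(8)
  A <- matrix(rnorm(6 * 40, 1), 6)
  B <- matrix(rnorm(3 * 40, 2), 3)
  fitA <- preprocess_chain(A, wl, "smooth-msc-center")
  ctx <- attr(fitA, "context")
  sep <- preprocess_chain(B, wl, "smooth-msc-center", context = ctx)
  joined <- preprocess_chain(rbind(A, B), wl, "smooth-msc-center",
                             context = ctx)
  expect_equal(unname(joined[7:9, ]), unname(sep), tolerance = 1e-12,
               ignore_attr = TRUE)
})
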