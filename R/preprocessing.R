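# Chemometric spectral pretreatment: moving-window smoothing, multiplicative
# scatter correction (MSC), detrending and column mean-centering, composed as
# smooth-then-X chains. Fit-dependent treatments (MSC reference, centering
# means) are fitted on the calibration subset and frozen for prediction rows.

#' Moving-average smoothing
#'
#' Per-row centered moving average with an odd window (default the 9-point
#' smooth). Edges use symmetric shrinking windows, so the matrix keeps its
#' full band count.
#'
#' @param x samples x bands matrix.
#' @param window odd window size, `3 <= window <= bands`.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_spectra <- function(x, window = 9) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  B <- ncol(x)
  if (window %% 2 == 0) stop("smoothing window must be odd")
  if (window < 3 || window > B) stop("window must be in [3, bands]")
  half <- (window - 1) / 2
  out <- x
  for (k in seq_len(B)) {
    m <- min(k - 1, B - k, half)
    if (m > 0)
      out[, k] <- rowMeans(x[, (k - m):(k + m), drop = FALSE])
  }
  out
}

#' Multiplicative scatter correction
#'
#' Fits each spectrum to the reference by least squares, `x ~ a + b * ref`,
#' and returns `(x - a) / b`, removing additive offset and multiplicative
#' scatter. The reference defaults to the mean spectrum of `x` (for a
#' calibration set); pass the calibration reference when transforming
#' prediction rows.
#'
#' @param x samples x bands matrix (>= 2 bands).
#' @param reference optional reference spectrum of length `bands`.
#' @return Corrected matrix with the reference stored in attribute
#'   `msc_reference`. Rows with `|b| < 1e-8` pass through unchanged (counted
#'   in a warning).
#' @export
msc <- function(x, reference = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) < 2) stop("MSC needs at least 2 bands")
  if (is.null(reference)) reference <- colMeans(x)
  if (length(reference) != ncol(x))
    stop("reference length does not match band count")
  refc <- reference - mean(reference)
  denom <- sum(refc^2)
  if (denom < 1e-12) stop("reference spectrum is constant")
  b <- as.vector(x %*% refc) / denom
  a <- rowMeans(x) - b * mean(reference)
  degenerate <- abs(b) < 1e-8
  b_safe <- ifelse(degenerate, 1, b)
  a_safe <- ifelse(degenerate, 0, a)
  out <- (x - a_safe) / b_safe
  if (any(degenerate))
    warning(sum(degenerate), " rows with |b| < 1e-8 passed through unchanged")
  attr(out, "msc_reference") <- reference
  out
}

#' Detrend: remove the least-squares linear baseline
#'
#' Fits a first-degree line of reflectance on wavelength per row and
#' subtracts it, removing baseline drift. Idempotent; the residual is
#' orthogonal to both the constant and the wavelength axis.
#'
#' @param x samples x bands matrix.
#' @param wavelengths nm, one per column (>= 2 distinct values).
#' @return Detrended matrix.
#' @export
detrend_spectra <- function(x, wavelengths) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(wavelengths))
    stop("wavelength axis does not match column count")
  wc <- wavelengths - mean(wavelengths)
  ss <- sum(wc^2)
  if (ss < 1e-12) stop("need at least 2 distinct wavelengths")
  slope <- as.vector(x %*% wc) / ss
  x - rowMeans(x) - outer(slope, wc)
}

#' Column mean-centering
#'
#' Subtracts per-column (variable-wise) means. Means default to those of `x`
#' (a calibration set); supply the calibration means when centering
#' prediction rows so no information leaks from them.
#'
#' @param x samples x bands matrix.
#' @param fitted_means optional vector of column means of length `bands`.
#' @return Centered matrix with the means in attribute `column_means`.
#' @export
center_spectra <- function(x, fitted_means = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.null(fitted_means)) fitted_means <- colMeans(x)
  if (length(fitted_means) != ncol(x))
    stop("fitted_means length does not match band count")
  out <- sweep(x, 2, fitted_means)
  attr(out, "column_means") <- fitted_means
  out
}

#' Apply a named pretreatment chain
#'
#' Runs an ordered recipe of treatments drawn from smooth, msc, detrend and
#' center, named as a hyphen-joined string (e.g. `"smooth-detrend"`, the
#' chain selected for this pipeline; also `"smooth-msc"`, `"smooth-center"`).
#' When present, smooth must come first. Fit-dependent context (MSC
#' reference, centering means) is fitted here when `context` is `NULL` and
#' returned, so the same context can be replayed on prediction rows.
#'
#' @param x samples x bands matrix.
#' @param wavelengths nm, one per column.
#' @param recipe hyphen-joined treatment names, or `""` for identity.
#' @param window smoothing window (default 9).
#' @param context optional fitted context from a previous call.
#' @return The treated matrix with attributes `provenance` (the recipe
#'   string), `wavelengths` and `context`.
#' @export
preprocess_chain <- function(x, wavelengths, recipe = "smooth-detrend",
                             window = 9, context = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  steps <- if (identical(recipe, "") || is.null(recipe)) character(0)
           else strsplit(recipe, "-", fixed = TRUE)[[1]]
  known <- c("smooth", "msc", "detrend", "center")
  bad <- setdiff(steps, known)
  if (length(bad)) stop("unknown treatment name: ", paste(bad, collapse = ", "))
  if ("smooth" %in% steps && steps[1] != "smooth")
    stop("smooth must come first in a recipe")
  fit <- is.null(context)
  if (fit) context <- list()
  for (s in steps) {
    x <- switch(s,
      smooth = smooth_spectra(x, window),
      msc = {
        out <- msc(x, reference = if (fit) NULL else context$msc_reference)
        if (fit) context$msc_reference <- attr(out, "msc_reference")
        out
      },
      detrend = detrend_spectra(x, wavelengths),
      center = {
        out <- center_spectra(x, fitted_means = if (fit) NULL
                              else context$center_means)
        if (fit) context$center_means <- attr(out, "column_means")
        out
      })
  }
  attr(x, "provenance") <- paste(steps, collapse = "-")
  attr(x, "wavelengths") <- wavelengths
  attr(x, "context") <- context
  x
}
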