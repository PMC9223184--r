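#' Hyperspectral data cube
#'
#' Container for one sample's image stack: a height x width x bands array of
#' raw counts or reflectance, the wavelength axis in nm, and the sensor the
#' cube came from. The two supported sensors are the visible/shortwave
#' near-infrared system (`VIS_SWNIR`, acquisition range 327-1098 nm) and the
#' longwave near-infrared system (`LWNIR`, 930-2548 nm).
#'
#' @param values numeric array, height x width x bands.
#' @param wavelengths numeric vector of band-center wavelengths (nm), strictly
#'   increasing, length equal to the third array dimension.
#' @param sensor `"VIS_SWNIR"` or `"LWNIR"`.
#' @param calibrated logical; `TRUE` once the cube holds reflectance produced
#'   by [correct_image()].
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, wavelengths, sensor = c("VIS_SWNIR", "LWNIR"),
                      calibrated = FALSE) {
  sensor <- match.arg(sensor)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (height x width x bands)")
  if (length(wavelengths) != dim(values)[3L])
    stop("wavelength axis length (", length(wavelengths),
         ") does not match band count (", dim(values)[3L], ")")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  rng <- if (sensor == "VIS_SWNIR") c(327, 1098) else c(930, 2548)
  if (min(wavelengths) < rng[1] || max(wavelengths) > rng[2])
    stop(sensor, " wavelengths must lie within [", rng[1], ", ", rng[2], "] nm")
  structure(
    list(values = values, wavelengths = as.numeric(wavelengths),
         sensor = sensor, calibrated = isTRUE(calibrated)),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %s  %d x %d px, %d bands (%.0f-%.0f nm)%s\n",
              x$sensor, d[1], d[2], d[3], min(x$wavelengths),
              max(x$wavelengths),
              if (x$calibrated) ", calibrated" else ", raw"))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Reflectance calibration against white and dark references
#'
#' Converts raw counts to relative reflectance using the standard white
#' (Teflon, ~99% reflectivity) and dark-current reference frames:
#' `(raw - black) / (white - black)`, elementwise.
#'
#' @param raw,white,black [hypercube] objects sharing shape, wavelength axis
#'   and sensor.
#' @param eps guard on the `white - black` denominator; any element smaller in
#'   magnitude is an error (it would divide by a dead pixel/band).
#' @return A calibrated [hypercube]. Values outside `[-0.1, 1.5]` are left
#'   untouched but counted in a warning: they indicate a calibration problem
#'   rather than something to clamp silently.
#' @export
correct_image <- function(raw, white, black, eps = 1e-6) {
  for (cb in list(raw, white, black))
    if (!inherits(cb, "hypercube")) stop("inputs must be hypercubes")
  if (!identical(dim(raw$values), dim(white$values)) ||
      !identical(dim(raw$values), dim(black$values)))
    stop("raw, white and black cubes must share the same shape")
  if (!isTRUE(all.equal(raw$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, black$wavelengths)))
    stop("raw, white and black cubes must share the wavelength axis")
  denom <- white$values - black$values
  bad <- which(abs(denom) < eps)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(denom))
    stop(sprintf(
      "white - black below %g at pixel (%d, %d), band %d: cannot calibrate",
      eps, idx[1], idx[2], idx[3]))
  }
  out <- (raw$values - black$values) / denom
  n_out <- sum(out < -0.1 | out > 1.5)
  if (n_out > 0)
    warning(n_out, " calibrated values outside [-0.1, 1.5]; left as-is")
  hypercube(out, raw$wavelengths, raw$sensor, calibrated = TRUE)
}

#' Segment the kernel region of interest with a single-band mask
#'
#' Thresholds the gray image at the band nearest `mask_wavelength` (the bands
#' where kernel/background contrast is largest: 849 nm for Vis-SWNIR, 1098 nm
#' for LWNIR), then optionally fills holes and drops small connected
#' components. The default threshold is Otsu's method on that gray band;
#' a fixed threshold can be supplied instead.
#'
#' @param cube a [hypercube].
#' @param mask_wavelength nm; the nearest band is used.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold numeric threshold, required when `method = "fixed"`.
#' @param fill_holes fill enclosed background holes (default `TRUE`).
#' @param min_area drop foreground components smaller than this many pixels
#'   (default 20; set 0 to disable).
#' @return A logical height x width matrix (`TRUE` = foreground) with
#'   attributes `n_foreground`, `threshold` and `band_wavelength`.
#' @export
build_mask <- function(cube, mask_wavelength, method = c("otsu", "fixed"),
                       threshold = NULL, fill_holes = TRUE, min_area = 20) {
  stopifnot(inherits(cube, "hypercube"))
  method <- match.arg(method)
  wl <- cube$wavelengths
  if (mask_wavelength < min(wl) || mask_wavelength > max(wl))
    stop("mask_wavelength outside the cube's spectral range")
  b <- which.min(abs(wl - mask_wavelength))
  gray <- cube$values[, , b]
  if (method == "fixed") {
    if (is.null(threshold)) stop("method = \"fixed\" requires `threshold`")
    thr <- threshold
  } else {
    # Otsu on the gray band rescaled to [0, 1], threshold mapped back
    rng <- range(gray)
    if (diff(rng) <= 0) stop("no ROI found: constant gray band")
    g01 <- (gray - rng[1]) / diff(rng)
    thr <- rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(g01))
  }
  fg <- gray > thr
  if (fill_holes)
    fg <- EBImage::fillHull(EBImage::Image(fg + 0)) > 0.5
  if (min_area > 0 && any(fg)) {
    lab <- EBImage::bwlabel(EBImage::Image(fg + 0))
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[sizes >= min_area])
    fg <- matrix(as.integer(lab) %in% keep, nrow(fg), ncol(fg))
  }
  fg <- matrix(as.logical(fg), dim(cube$values)[1], dim(cube$values)[2])
  if (!any(fg)) stop("no ROI found")
  structure(fg, n_foreground = sum(fg), threshold = thr,
            band_wavelength = wl[b])
}

#' Mean reflectance spectrum over a masked region
#'
#' Arithmetic mean of reflectance over foreground pixels, band by band.
#'
#' @param cube a calibrated [hypercube].
#' @param mask logical matrix from [build_mask()] (or any mask of matching
#'   spatial shape with at least one `TRUE` pixel).
#' @return Numeric vector of length `bands`, named by wavelength.
#' @export
extract_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  if (!identical(dim(mask), d[1:2]))
    stop("mask spatial shape does not match the cube")
  if (!any(mask)) stop("empty mask")
  v <- matrix(cube$values, d[1] * d[2], d[3])
  sp <- colMeans(v[as.vector(mask), , drop = FALSE])
  names(sp) <- cube$wavelengths
  sp
}

#' Trim noisy leading/trailing bands from a feature matrix
#'
#' Keeps only the columns whose wavelength falls inside `[low, high]`; the
#' retained working ranges are 399-1001 nm (389 bands) for Vis-SWNIR and
#' 1005-1701 nm (112 bands) for LWNIR.
#'
#' @param x samples x bands matrix (or a single spectrum vector).
#' @param wavelengths nm, one per column of `x`.
#' @param low,high retained range limits (nm), `low < high`.
#' @return `list(x = trimmed matrix, wavelengths = retained wavelengths)`.
#' @export
trim_bands <- function(x, wavelengths, low, high) {
  if (low >= high) stop("`low` must be below `high`")
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(wavelengths))
    stop("wavelength axis does not match column count")
  keep <- wavelengths >= low & wavelengths <= high
  if (!any(keep)) stop("no bands retained in [", low, ", ", high, "] nm")
  list(x = x[, keep, drop = FALSE], wavelengths = wavelengths[keep])
}
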