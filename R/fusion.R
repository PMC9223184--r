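# Pixel-level fusion (direct column concatenation of full blocks) and
# feature-level fusion (concatenation after per-block variable selection),
# with full column provenance and calibration-fitted min-max scaling.

# internal: provenance data.frame for one block's columns
block_provenance <- function(sensor, block, cols, wavelengths) {
  data.frame(sensor = sensor, block = block, band_index = cols,
             wavelength = if (is.null(wavelengths)) NA_real_
                          else wavelengths[cols],
             stringsAsFactors = FALSE)
}

new_fused_matrix <- function(x, provenance, level) {
  stopifnot(nrow(provenance) == ncol(x))
  structure(x, provenance = provenance, fusion_level = level,
            class = c("fused_matrix", class(x)))
}

#' Column provenance of a fused matrix
#' @param x a `fused_matrix`.
#' @return data.frame with one row per column: sensor, block, original band
#'   index and wavelength.
#' @export
fusion_provenance <- function(x) attr(x, "provenance")

#' Pixel-level fusion of a spectra matrix and a texture block
#'
#' Direct column-wise concatenation `[spectra | texture]`: every variable of
#' both sources enters the fused matrix, one row per sample.
#'
#' @param spectra samples x bands matrix (with optional `wavelengths`
#'   attribute).
#' @param texture samples x bands texture-parameter matrix, same row order.
#' @param sensor sensor label recorded in the provenance.
#' @param texture_name texture parameter name recorded in the provenance.
#' @return A `fused_matrix` with `fusion_level = "pixel"`.
#' @export
pixel_fuse <- function(spectra, texture, sensor = "VIS_SWNIR",
                       texture_name = "texture") {
  if (is.null(dim(texture)) || ncol(texture) == 0 || nrow(texture) == 0)
    stop("empty texture block")
  if (is.null(dim(spectra)) || ncol(spectra) == 0)
    stop("empty spectra block")
  if (nrow(spectra) != nrow(texture))
    stop("row counts differ: samples are not aligned")
  prov <- rbind(
    block_provenance(sensor, "spectra", seq_len(ncol(spectra)),
                     attr(spectra, "wavelengths")),
    block_provenance(sensor, texture_name, seq_len(ncol(texture)),
                     attr(texture, "wavelengths")))
  new_fused_matrix(cbind(unclass(spectra), unclass(texture)), prov, "pixel")
}

#' Feature-level fusion of selected columns from several blocks
#'
#' Concatenates each block restricted to its selected columns; the fused
#' width is the sum of the per-block selection sizes.
#'
#' @param blocks list of blocks, each a list with elements `data` (matrix),
#'   `selection` (a `feature_selection` or an integer index vector),
#'   `sensor` and `block` (labels for the provenance).
#' @return A `fused_matrix` with `fusion_level = "feature"`.
#' @export
feature_fuse <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  n <- nrow(blocks[[1]]$data)
  parts <- list(); provs <- list()
  for (b in blocks) {
    idx <- if (inherits(b$selection, "feature_selection"))
      b$selection$indices else as.integer(b$selection)
    if (length(idx) == 0) stop("empty selection for block ",
                               b$sensor, "/", b$block)
    if (any(idx < 1 | idx > ncol(b$data)))
      stop("selection indices out of range for block ", b$sensor, "/", b$block)
    if (nrow(b$data) != n) stop("row counts differ across blocks")
    parts[[length(parts) + 1]] <- unclass(b$data)[, idx, drop = FALSE]
    provs[[length(provs) + 1]] <-
      block_provenance(b$sensor %||% NA_character_,
                       b$block %||% NA_character_, idx,
                       attr(b$data, "wavelengths"))
  }
  new_fused_matrix(do.call(cbind, parts), do.call(rbind, provs), "feature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit min-max scaling on calibration rows and transform all rows
#'
#' Per-column minimum and range are computed on the calibration rows only and
#' applied to the whole matrix, mapping calibration values into `[0, 1]`;
#' prediction rows may fall marginally outside and are not clamped. Constant
#' columns get scale 1 and offset at their minimum (counted in a warning).
#' Scaling keeps reflectance (~0-1) and texture contrast (~0-50) columns
#' comparable for margin-based classifiers.
#'
#' @param x a `fused_matrix` (or plain matrix).
#' @param calibration_rows row indices of the calibration set (>= 2).
#' @param context optional previously fitted scaling context to replay.
#' @return The scaled matrix with the fitted context in attribute
#'   `scaling` (list with `min` and `range`).
#' @export
fit_scaling <- function(x, calibration_rows, context = NULL) {
  stopifnot(length(calibration_rows) >= 2 || !is.null(context))
  if (is.null(context)) {
    cal <- unclass(x)[calibration_rows, , drop = FALSE]
    mins <- apply(cal, 2, min)
    rngs <- apply(cal, 2, max) - mins
    const <- rngs <= 0
    if (any(const)) {
      warning(sum(const), " constant columns: scale set to 1")
      rngs[const] <- 1
    }
    context <- list(min = mins, range = rngs)
  }
  out <- sweep(sweep(unclass(x), 2, context$min), 2, context$range, "/")
  attributes(out)$provenance <- attr(x, "provenance")
  attributes(out)$fusion_level <- attr(x, "fusion_level")
  attr(out, "scaling") <- context
  class(out) <- class(x)
  out
}
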