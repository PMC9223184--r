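# Per-band GLCM texture over the ROI: gray-level quantization, co-occurrence
# counting at distance 1 in four directions, and the four classic parameters
# (contrast, correlation, energy, homogeneity), averaged over directions.

#' GLCM extraction settings
#'
#' @param n_levels number of gray levels N (default 8).
#' @param distance pixel offset distance d (default 1).
#' @param angles directions in degrees; the four standard GLCM directions.
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(n_levels = 8, distance = 1,
                      angles = c(0, 45, 90, 135)) {
  stopifnot(n_levels >= 2, distance >= 1,
            all(angles %in% c(0, 45, 90, 135)))
  structure(list(n_levels = as.integer(n_levels),
                 distance = as.integer(distance),
                 angles = angles), class = "glcm_spec")
}

#' Quantize a gray band into N equal-width levels over the ROI
#'
#' ROI pixel values are binned linearly between the ROI minimum and maximum
#' of that band into `n_levels` equal-width bins (levels 1..N); background
#' pixels are marked invalid (`NA`). A constant band maps every ROI pixel to
#' level 1 and sets the `constant` attribute.
#'
#' @param gray numeric matrix (one band).
#' @param mask logical foreground matrix.
#' @param n_levels number of gray levels.
#' @return Integer matrix of levels with `NA` outside the ROI; attribute
#'   `constant` flags a degenerate band.
#' @export
quantize <- function(gray, mask, n_levels = 8) {
  stopifnot(identical(dim(gray), dim(mask)), any(mask))
  v <- gray[mask]
  rng <- range(v)
  out <- matrix(NA_integer_, nrow(gray), ncol(gray))
  if (diff(rng) <= 0) {
    out[mask] <- 1L
    attr(out, "constant") <- TRUE
    return(out)
  }
  lev <- floor((v - rng[1]) / diff(rng) * n_levels) + 1L
  out[mask] <- pmin(lev, as.integer(n_levels))
  attr(out, "constant") <- FALSE
  out
}

# internal: (row, col) offset of a GLCM direction at distance d
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported GLCM angle: ", angle))
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts ordered pixel pairs (pixel, neighbor at the direction's offset)
#' where both pixels are valid ROI levels, and normalizes to a joint
#' probability matrix P with `sum(P) = 1`. Pairs touching background or the
#' image border are excluded, not zero-filled.
#'
#' @param levels_img integer level matrix from [quantize()] (`NA` = invalid).
#' @param n_levels number of gray levels N.
#' @param angle direction in degrees (0, 45, 90 or 135).
#' @param distance offset distance in pixels.
#' @return N x N probability matrix `P[i, j]`.
#' @export
glcm <- function(levels_img, n_levels = 8, angle = 0, distance = 1) {
  off <- glcm_offset(angle, as.integer(distance))
  h <- nrow(levels_img); w <- ncol(levels_img)
  rlo <- max(1L, 1L - off[1]); rhi <- min(h, h - off[1])
  clo <- max(1L, 1L - off[2]); chi <- min(w, w - off[2])
  if (rlo > rhi || clo > chi)
    stop("no valid pixel pairs at this distance/angle")
  r0 <- rlo:rhi
  c0 <- clo:chi
  A <- levels_img[r0, c0, drop = FALSE]
  B <- levels_img[r0 + off[1], c0 + off[2], drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  if (!any(ok))
    stop("no valid pixel pairs at this distance/angle")
  counts <- tabulate((A[ok] - 1L) * n_levels + B[ok],
                     nbins = n_levels * n_levels)
  matrix(counts / sum(counts), n_levels, n_levels, byrow = TRUE)
}

#' Texture parameters of a GLCM
#'
#' Computes contrast `sum((i-j)^2 P)`, correlation
#' `(sum(ij P) - mu_i mu_j) / (sigma_i sigma_j)`, energy `sum(P^2)` and
#' homogeneity `sum(P / (1 + (i-j)^2))`, with `mu`/`sigma` the marginal means
#' and SDs of the GLCM. A degenerate GLCM with zero marginal SD has undefined
#' correlation; it is reported as 0 (with attribute
#' `correlation_undefined = TRUE`) to keep downstream matrices finite.
#'
#' @param P normalized nonnegative co-occurrence matrix.
#' @return Named numeric vector `(contrast, correlation, energy, homogeneity)`.
#' @export
texture_params <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P), all(P >= 0))
  N <- nrow(P)
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(seq_len(N) * pi_); mu_j <- sum(seq_len(N) * pj_)
  sd_i <- sqrt(sum((seq_len(N) - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((seq_len(N) - mu_j)^2 * pj_))
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  undef <- sd_i * sd_j < 1e-12
  correlation <- if (undef) 0 else (sum(i * j * P) - mu_i * mu_j) / (sd_i * sd_j)
  out <- c(contrast = contrast, correlation = correlation,
           energy = energy, homogeneity = homogeneity)
  if (undef) attr(out, "correlation_undefined") <- TRUE
  out
}

#' Per-band texture parameters for one cube
#'
#' For every band: quantize the ROI, build the GLCM at each of the four
#' directions, compute the four parameters per direction, and average the
#' parameter values over directions (matrices are not averaged). Bands where
#' a direction has no valid pairs propagate as `NA` with a warning.
#'
#' @param cube a calibrated [hypercube].
#' @param mask logical ROI matrix.
#' @param spec a [glcm_spec].
#' @return A 4 x bands matrix (rows contrast, correlation, energy,
#'   homogeneity) with the cube's wavelengths as a `wavelengths` attribute.
#' @export
band_texture_matrix <- function(cube, mask, spec = glcm_spec()) {
  stopifnot(inherits(cube, "hypercube"), inherits(spec, "glcm_spec"))
  d <- dim(cube$values)
  if (!identical(dim(mask), d[1:2])) stop("mask shape does not match cube")
  if (!any(mask)) stop("empty mask")
  params <- c("contrast", "correlation", "energy", "homogeneity")
  out <- matrix(NA_real_, 4, d[3], dimnames = list(params, NULL))
  n_failed <- 0L
  for (b in seq_len(d[3])) {
    L <- quantize(cube$values[, , b], mask, spec$n_levels)
    vals <- matrix(NA_real_, 4, length(spec$angles))
    ok <- TRUE
    for (ai in seq_along(spec$angles)) {
      P <- tryCatch(glcm(L, spec$n_levels, spec$angles[ai], spec$distance),
                    error = function(e) NULL)
      if (is.null(P)) { ok <- FALSE; break }
      vals[, ai] <- texture_params(P)
    }
    if (ok) out[, b] <- rowMeans(vals) else n_failed <- n_failed + 1L
  }
  if (n_failed > 0)
    warning(n_failed, " bands had no valid pixel pairs; values set to NA")
  attr(out, "wavelengths") <- cube$wavelengths
  out
}

#' Texture feature tables for a set of rendered scenes
#'
#' Runs calibration, segmentation and [band_texture_matrix()] over a list of
#' scene bundles (as returned by [generate_scene()]) and stacks one row per
#' sample into the four samples x bands texture blocks.
#'
#' @param scenes list of scene bundles.
#' @param spec a [glcm_spec].
#' @param use_true_mask use each scene's ground-truth mask (default) instead
#'   of re-segmenting.
#' @return Named list of four samples x bands matrices.
#' @export
texture_table <- function(scenes, spec = glcm_spec(), use_true_mask = TRUE) {
  rows <- lapply(scenes, function(sc) {
    cube <- correct_image(sc$raw, sc$white, sc$black)
    mask <- if (use_true_mask) sc$mask else
      build_mask(cube, mask_wavelength = if (cube$sensor == "VIS_SWNIR")
        849 else 1098)
    band_texture_matrix(cube, mask, spec)
  })
  params <- c("contrast", "correlation", "energy", "homogeneity")
  out <- lapply(params, function(p)
    do.call(rbind, lapply(rows, function(r) r[p, ])))
  names(out) <- params
  for (p in params) attr(out[[p]], "wavelengths") <- attr(rows[[1]], "wavelengths")
  out
}
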