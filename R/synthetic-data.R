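# Synthetic two-sensor scenes and feature tables emulating moldy-maize
# hyperspectral data: level-dependent reflectance depression, the documented
# spectral landmarks of each sensor, and texture heterogeneity concentrated in
# an embryo patch where mold develops first.

#' Scene generator configuration
#'
#' Study-design parameters for the synthetic data: four mold levels with 60
#' samples each, a Vis-SWNIR axis of 389 bands over 399-1001 nm and an LWNIR
#' axis of 112 bands over 1005-1701 nm (the retained working ranges after
#' noise-band trimming), reflectance scale factors that decrease with mold
#' severity, and embryo-patch speckle whose standard deviation grows with
#' severity.
#'
#' @param n_per_level samples per mold level (default 60).
#' @param spatial_size c(height, width) in pixels for rendered scenes
#'   (default 64 x 64; full-fidelity rendering is intended for small scene
#'   counts, the feature-table fast path for full 240-sample experiments).
#' @param vis_bands,lwnir_bands band counts (defaults 389 and 112).
#' @param vis_range,lwnir_range retained wavelength ranges in nm.
#' @param level_reflectance_scale four strictly decreasing factors applied to
#'   the base reflectance curve, healthy through severe.
#' @param texture_noise_sd four nondecreasing multiplicative speckle SDs for
#'   the embryo patch, healthy through severe.
#' @param embryo_patch_fraction fraction of ROI area taken by the embryo patch.
#' @param scatter_sd SD of the per-sample multiplicative scatter gain.
#' @param band_noise_sd SD of additive per-band spectral noise.
#' @param texture_sample_sd SD of the per-sample latent texture factor in the
#'   feature-table fast path.
#' @param seed default integer seed for generation helpers.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_per_level = 60, spatial_size = c(64, 64),
                         vis_bands = 389, lwnir_bands = 112,
                         vis_range = c(399, 1001), lwnir_range = c(1005, 1701),
                         level_reflectance_scale = c(1.00, 0.85, 0.72, 0.60),
                         texture_noise_sd = c(0.01, 0.03, 0.05, 0.07),
                         embryo_patch_fraction = 0.15,
                         scatter_sd = 0.06, band_noise_sd = 0.004,
                         texture_sample_sd = 0.12,
                         seed = 1L) {
  stopifnot(n_per_level >= 2, length(spatial_size) == 2,
            vis_bands >= 2, lwnir_bands >= 2,
            length(level_reflectance_scale) == 4,
            length(texture_noise_sd) == 4,
            embryo_patch_fraction > 0, embryo_patch_fraction < 0.5,
            scatter_sd >= 0, band_noise_sd >= 0, texture_sample_sd >= 0)
  if (any(diff(level_reflectance_scale) >= 0))
    stop("level_reflectance_scale must be strictly decreasing")
  if (any(diff(texture_noise_sd) < 0))
    stop("texture_noise_sd must be nondecreasing")
  if (vis_range[1] >= vis_range[2] || lwnir_range[1] >= lwnir_range[2])
    stop("wavelength ranges must be increasing")
  structure(list(
    n_per_level = as.integer(n_per_level),
    spatial_size = as.integer(spatial_size),
    vis_bands = as.integer(vis_bands), lwnir_bands = as.integer(lwnir_bands),
    vis_range = vis_range, lwnir_range = lwnir_range,
    level_reflectance_scale = level_reflectance_scale,
    texture_noise_sd = texture_noise_sd,
    embryo_patch_fraction = embryo_patch_fraction,
    scatter_sd = scatter_sd, band_noise_sd = band_noise_sd,
    texture_sample_sd = texture_sample_sd,
    seed = as.integer(seed)), class = "scene_config")
}

#' Wavelength axis of a configured sensor
#' @param config a [scene_config].
#' @param sensor `"VIS_SWNIR"` or `"LWNIR"`.
#' @return Numeric vector of band-center wavelengths (nm).
#' @export
sensor_wavelengths <- function(config, sensor = c("VIS_SWNIR", "LWNIR")) {
  sensor <- match.arg(sensor)
  if (sensor == "VIS_SWNIR")
    seq(config$vis_range[1], config$vis_range[2],
        length.out = config$vis_bands)
  else
    seq(config$lwnir_range[1], config$lwnir_range[2],
        length.out = config$lwnir_bands)
}

#' Base reflectance curve of healthy kernel tissue
#'
#' Smooth analytic mixture of logistic and Gaussian components reproducing
#' each sensor's landmarks: in the Vis-SWNIR range the curve rises from
#' 399 nm to a peak near 820 nm and then falls slowly; in the LWNIR range it
#' carries reflectance peaks near 1100 and 1300 nm and absorption troughs
#' near 1192 nm (carbohydrate C-H) and 1445 nm (water O-H / protein C-H).
#'
#' @param wavelengths nm.
#' @param sensor `"VIS_SWNIR"` or `"LWNIR"`.
#' @return Reflectance values in (0, 1).
#' @export
base_spectrum <- function(wavelengths, sensor = c("VIS_SWNIR", "LWNIR")) {
  sensor <- match.arg(sensor)
  wl <- wavelengths
  if (sensor == "VIS_SWNIR") {
    rise <- stats::plogis((wl - 590) / 85)
    crest <- exp(-((wl - 795) / 290)^2)
    0.14 + 0.68 * rise * crest
  } else {
    0.46 +
      0.17 * exp(-((wl - 1100) / 45)^2) +
      0.15 * exp(-((wl - 1300) / 70)^2) -
      0.10 * exp(-((wl - 1192) / 28)^2) -
      0.20 * exp(-((wl - 1445) / 60)^2)
  }
}

#' CAT activity distribution parameters per mold level
#'
#' Per-level mean and SD of catalase activity in mL/(h*g). Healthy kernels
#' are sterilized, so their CAT activity is exactly zero; the moldy levels
#' follow truncated Gaussians with strictly increasing means.
#'
#' @param means,sds length-4 numeric vectors, healthy through severe.
#' @return An object of class `cat_params`.
#' @export
cat_params <- function(means = c(0, 1.57, 1.91, 2.24),
                       sds = c(0, 0.13, 0.09, 0.12)) {
  stopifnot(length(means) == 4, length(sds) == 4, all(sds >= 0))
  if (means[1] != 0 || sds[1] != 0)
    stop("healthy mean and SD must be exactly 0")
  if (any(diff(means[-1]) <= 0))
    stop("non-healthy means must be strictly increasing")
  structure(list(means = means, sds = sds,
                 levels = mold_levels()), class = "cat_params")
}

#' Generate CAT activity values for one mold level
#'
#' Healthy samples are exactly zero. Moldy levels draw from a Gaussian with
#' the level's mean and SD, truncated at zero by redrawing negatives (so the
#' sample mean stays at the target rather than being inflated by clipping).
#'
#' @param params a [cat_params].
#' @param level mold level label.
#' @param n number of values.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` CAT activities, mL/(h*g).
#' @export
generate_cat <- function(params = cat_params(), level, n, seed = NULL) {
  stopifnot(inherits(params, "cat_params"), n >= 1)
  level <- match_level(level)
  if (!is.null(seed)) set.seed(seed)
  i <- match(level, params$levels)
  if (level == "healthy") return(rep(0, n))
  out <- rnorm(n, params$means[i], params$sds[i])
  while (any(out < 0))
    out[out < 0] <- rnorm(sum(out < 0), params$means[i], params$sds[i])
  out
}

# internal: elliptical ROI and embryo masks for a rendered scene
scene_geometry <- function(h, w, embryo_fraction) {
  if (min(h, w) < 16)
    stop("spatial size too small to contain ROI and embryo patch")
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a <- 0.38 * h; b <- 0.30 * w
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  roi <- ((r - cy) / a)^2 + ((c_ - cx) / b)^2 <= 1
  ae <- a * sqrt(embryo_fraction); be <- b * sqrt(embryo_fraction)
  ey <- cy - 0.15 * h
  embryo <- (((r - ey) / ae)^2 + ((c_ - cx) / be)^2 <= 1) & roi
  if (!any(embryo))
    stop("spatial size too small to contain ROI and embryo patch")
  list(roi = roi, embryo = embryo)
}

#' Render one synthetic scene: raw, white and black cubes plus ground truth
#'
#' Constructs a true reflectance scene — an elliptical kernel ROI on a dark
#' background, the sensor's base spectral curve scaled by the level's
#' reflectance factor, and an embryo patch with lower reflectance and
#' level-dependent multiplicative speckle — then simulates acquisition as
#' `raw = black + (white - black) * R` with noisy white (~0.99) and black
#' (~0.02) reference frames. The embryo/non-embryo structural factors are
#' mean-preserving, so with speckle off the ROI-mean spectrum is exactly
#' `base_spectrum * scale[level]`.
#'
#' @param config a [scene_config].
#' @param level mold level label.
#' @param sensor `"VIS_SWNIR"` or `"LWNIR"`.
#' @param seed optional integer seed.
#' @return List with [hypercube]s `raw`, `white`, `black`, the true
#'   reflectance cube `truth`, and the logical ground-truth ROI `mask`.
#' @export
generate_scene <- function(config, level, sensor = c("VIS_SWNIR", "LWNIR"),
                           seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  sensor <- match.arg(sensor)
  level <- match_level(level)
  if (!is.null(seed)) set.seed(seed)
  li <- match(level, mold_levels())
  h <- config$spatial_size[1]; w <- config$spatial_size[2]
  wl <- sensor_wavelengths(config, sensor)
  B <- length(wl)
  geo <- scene_geometry(h, w, config$embryo_patch_fraction)
  roi <- geo$roi; embryo <- geo$embryo
  n_roi <- sum(roi); n_emb <- sum(embryo)

  # mean-preserving structural factors: embryo darker, rest compensates
  f_emb <- 0.92
  frac <- n_emb / n_roi
  f_rest <- (1 - frac * f_emb) / (1 - frac)
  gain <- matrix(0, h, w)
  gain[roi] <- f_rest
  gain[embryo] <- f_emb

  # multiplicative speckle at the level's SD across the ROI; together with
  # the darker embryo patch this concentrates heterogeneity there while
  # keeping per-band min-max quantized texture monotone in mold level
  sdl <- config$texture_noise_sd[li]
  speck <- matrix(1, h, w)
  speck[roi & !embryo] <- 1 + rnorm(n_roi - n_emb, 0, sdl)
  speck[embryo] <- 1 + rnorm(n_emb, 0, sdl)
  speck <- pmax(speck, 0.05)

  base <- base_spectrum(wl, sensor) * config$level_reflectance_scale[li]
  px <- gain * speck              # h x w, zero outside ROI
  R <- array(0.05, dim = c(h, w, B))
  roi_v <- as.vector(roi)
  Rm <- matrix(R, h * w, B)
  Rm[roi_v, ] <- as.vector(px)[roi_v] %o% base
  Rm[Rm < 0] <- 0
  Rm[Rm > 1.05] <- 1.05
  R <- array(Rm, dim = c(h, w, B))

  white <- array(0.99 + rnorm(h * w * B, 0, 0.002), dim = c(h, w, B))
  black <- array(0.02 + rnorm(h * w * B, 0, 0.002), dim = c(h, w, B))
  raw <- black + (white - black) * R

  list(raw = hypercube(raw, wl, sensor),
       white = hypercube(white, wl, sensor),
       black = hypercube(black, wl, sensor),
       truth = hypercube(R, wl, sensor, calibrated = TRUE),
       mask = roi)
}

# Fast-path texture model: expected class-mean texture value as a function
# of the level's speckle SD. Contrast grows linearly with the SD; the other
# three parameters decay toward a noise-dominated floor. Coefficients frozen
# from one calibration run of the full imaging + texture pipeline on
# rendered default scenes (see the methods vignette). The rendered texture
# profile is flat across bands (per-band min-max quantization removes the
# band's amplitude), so no band modulation is applied. Loadings give the
# per-sample latent factor opposite signs for contrast vs the rest.
.texture_model <- list(
  contrast    = list(kind = "linear", a = 1.218, b = 22.2,  load = 1.0),
  correlation = list(kind = "exp", inf = 0.10, amp = 0.685, tau = 0.028,
                     load = -0.8),
  energy      = list(kind = "exp", inf = 0.047, amp = 0.092, tau = 0.012,
                     load = -0.6),
  homogeneity = list(kind = "exp", inf = 0.49, amp = 0.193, tau = 0.018,
                     load = -0.4)
)

# internal: expected texture value for one parameter at one speckle SD
texture_profile <- function(param, sd_level) {
  m <- .texture_model[[param]]
  if (m$kind == "linear")
    pmax(m$a + m$b * sd_level, 1e-3)
  else
    m$inf + m$amp * exp(-(sd_level - 0.01) / m$tau)
}

#' Generate ready-made feature tables (fast path)
#'
#' Synthesizes the samples x bands mean-spectra matrices and the four GLCM
#' texture blocks for both sensors directly, with the statistical structure
#' the full imaging + texture pipeline produces on rendered scenes:
#' class-separated mean spectra whose intensity decreases with mold level,
#' texture means ordered by level (contrast increasing, energy decreasing),
#' a per-sample multiplicative scatter gain, and a per-sample latent texture
#' factor shared across texture parameters. This is the route for
#' full 240-sample experiments, where rendering every cube would be
#' needlessly expensive.
#'
#' @param config a [scene_config].
#' @param params a [cat_params] for the per-sample CAT values.
#' @param seed optional integer seed.
#' @return List with `samples` (data.frame: id, level, culture_day, cat),
#'   `spectra` (per-sensor matrices with a `wavelengths` attribute) and
#'   `texture` (per-sensor list of four parameter matrices).
#' @export
generate_feature_tables <- function(config = scene_config(),
                                    params = cat_params(), seed = NULL) {
  stopifnot(inherits(config, "scene_config"), inherits(params, "cat_params"))
  if (!is.null(seed)) set.seed(seed)
  levels <- mold_levels()
  npl <- config$n_per_level
  n <- npl * 4L
  lev <- factor(rep(levels, each = npl), levels = levels)
  day <- rep(c(0L, 2L, 4L, 6L), each = npl)
  cat_vals <- unlist(lapply(levels, function(l)
    generate_cat(params, l, npl)))

  scatter <- rnorm(n, 0, config$scatter_sd)     # per-sample gain (spectra)
  texfac <- rnorm(n, 0, config$texture_sample_sd)  # per-sample latent texture

  sensors <- c("VIS_SWNIR", "LWNIR")
  spectra <- list(); texture <- list()
  for (s in sensors) {
    wl <- sensor_wavelengths(config, s)
    base <- base_spectrum(wl, s)
    scale_i <- config$level_reflectance_scale[as.integer(lev)]
    X <- (scale_i * (1 + scatter)) %o% base +
      matrix(rnorm(n * length(wl), 0, config$band_noise_sd), n)
    attr(X, "wavelengths") <- wl
    spectra[[s]] <- X

    sd_i <- config$texture_noise_sd[as.integer(lev)]
    blocks <- list()
    for (param in names(.texture_model)) {
      m <- .texture_model[[param]]
      mu <- texture_profile(param, sd_i)        # per-sample expected value
      Tm <- (mu * (1 + m$load * texfac)) %o% rep(1, length(wl))
      Tm <- Tm + matrix(rnorm(n * length(wl), 0,
                              0.04 * mean(abs(Tm))), n)
      if (param %in% c("energy", "homogeneity"))
        Tm <- pmin(pmax(Tm, 1e-4), 1)
      if (param == "contrast") Tm <- pmax(Tm, 0)
      if (param == "correlation") Tm <- pmin(pmax(Tm, -1), 1)
      attr(Tm, "wavelengths") <- wl
      blocks[[param]] <- Tm
    }
    texture[[s]] <- blocks
  }
  list(samples = data.frame(id = sprintf("S%03d", seq_len(n)),
                            level = lev, culture_day = day, cat = cat_vals,
                            stringsAsFactors = FALSE),
       spectra = spectra, texture = texture)
}

#' Planted-variable benchmark block for the wavelength selectors
#'
#' A samples x columns matrix in which a known subset of columns carries a
#' class-mean shift (adjacent class centers one `effect` apart, unit noise)
#' and the rest are pure noise, used to measure how reliably the selectors
#' recover informative variables.
#'
#' @param n samples (balanced over 4 classes).
#' @param p total columns.
#' @param n_informative planted informative columns.
#' @param effect adjacent-class center separation, in noise SD units.
#' @param seed optional integer seed.
#' @return List with `X`, factor `y` and integer `informative` positions.
#' @export
make_planted_block <- function(n = 240, p = 200, n_informative = 10,
                               effect = 1.0, seed = NULL) {
  stopifnot(n %% 4 == 0, p >= n_informative)
  if (!is.null(seed)) set.seed(seed)
  y <- factor(rep(mold_levels(), each = n / 4), levels = mold_levels())
  X <- matrix(rnorm(n * p), n, p)
  pos <- sort(sample.int(p, n_informative))
  centers <- (as.integer(y) - 2.5) * effect
  for (j in pos) X[, j] <- X[, j] + centers * sample(c(-1, 1), 1)
  list(X = X, y = y, informative = pos)
}
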