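# Independent brute-force oracles, kept deliberately naive (explicit double
# loops) so they share no code path with the package implementations.

# ordered-pair GLCM by explicit enumeration over every pixel
brute_glcm <- function(levels_img, n_levels, angle, distance = 1) {
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  counts <- matrix(0, n_levels, n_levels)
  h <- nrow(levels_img); w <- ncol(levels_img)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      a <- levels_img[r, c]; b <- levels_img[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts / sum(counts)
}

# texture parameters by direct scalar summation
brute_texture_params <- function(P) {
  N <- nrow(P)
  contrast <- 0; energy <- 0; homogeneity <- 0; sij <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    contrast <- contrast + (i - j)^2 * P[i, j]
    energy <- energy + P[i, j]^2
    homogeneity <- homogeneity + P[i, j] / (1 + (i - j)^2)
    sij <- sij + i * j * P[i, j]
  }
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(N)) mu_i <- mu_i + i * sum(P[i, ])
  for (j in seq_len(N)) mu_j <- mu_j + j * sum(P[, j])
  v_i <- 0; v_j <- 0
  for (i in seq_len(N)) v_i <- v_i + (i - mu_i)^2 * sum(P[i, ])
  for (j in seq_len(N)) v_j <- v_j + (j - mu_j)^2 * sum(P[, j])
  correlation <- if (sqrt(v_i * v_j) < 1e-12) 0 else
    (sij - mu_i * mu_j) / sqrt(v_i * v_j)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

# a small calibrated test scene bundle shared by several files
tiny_scene <- function(level = "moderate", seed = 11, bands = 25,
                       size = c(40, 40)) {
  cfg <- scene_config(spatial_size = size, vis_bands = bands,
                      lwnir_bands = bands)
  sc <- generate_scene(cfg, level, "VIS_SWNIR", seed = seed)
  sc$corrected <- correct_image(sc$raw, sc$white, sc$black)
  sc$config <- cfg
  sc
}
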