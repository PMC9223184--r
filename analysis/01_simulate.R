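#!/usr/bin/env Rscript
# Builds the synthetic study dataset: 4 mold levels x 60 samples, mean
# spectra and GLCM texture blocks for both sensors, and per-sample CAT
# activity. Writes the sample records and feature tables under results/.
# Also renders a handful of full-fidelity scenes to ENVI cubes so the
# imaging stages can be exercised on real files (02_extract_imaging.R).

library(maizemold)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- scene_config()
data <- build_dataset(config, cat_params(), seed = seed)

write.csv(data$samples, file.path(out, "samples.csv"), row.names = FALSE)
for (s in names(data$spectra)) {
  m <- data$spectra[[s]]
  colnames(m) <- sprintf("%.1f", attr(m, "wavelengths"))
  write.csv(cbind(id = data$samples$id, as.data.frame(m)),
            file.path(out, paste0("spectra_", s, ".csv")), row.names = FALSE)
  for (p in names(data$texture[[s]])) {
    tm <- data$texture[[s]][[p]]
    colnames(tm) <- sprintf("%.1f", attr(tm, "wavelengths"))
    write.csv(cbind(id = data$samples$id, as.data.frame(tm)),
              file.path(out, paste0("texture_", s, "_", p, ".csv")),
              row.names = FALSE)
  }
}
cat("Feature tables:", nrow(data$samples), "samples;",
    ncol(data$spectra$VIS_SWNIR), "Vis-SWNIR bands;",
    ncol(data$spectra$LWNIR), "LWNIR bands\n")
cat("CAT class means:",
    round(tapply(data$samples$cat, data$samples$level, mean), 3), "\n")

# a small gallery of full-fidelity scenes (memory stays desk-scale)
scene_cfg <- scene_config(spatial_size = c(64, 64), vis_bands = 60,
                          lwnir_bands = 40)
cube_dir <- file.path(out, "cubes")
dir.create(cube_dir, showWarnings = FALSE)
for (li in seq_along(mold_levels())) {
  for (rep in 1:3) {
    for (sensor in c("VIS_SWNIR", "LWNIR")) {
      sc <- generate_scene(scene_cfg, mold_levels()[li], sensor,
                           seed = seed * 10000 + li * 100 + rep)
      base <- file.path(cube_dir, sprintf("%s_%s_%d", mold_levels()[li],
                                          sensor, rep))
      write_cube(sc$raw, paste0(base, "_raw"))
      write_cube(sc$white, paste0(base, "_white"))
      write_cube(sc$black, paste0(base, "_black"))
      writeLines(apply(sc$mask + 0, 1, paste, collapse = " "),
                 paste0(base, "_mask.txt"))
    }
  }
}
cat("Rendered", 4 * 3 * 2, "scenes to", cube_dir, "\n")
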