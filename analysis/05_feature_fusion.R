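#!/usr/bin/env Rscript
# Feature-level fusion per sensor: VCPA, IRIV and the hybrid mVCPA-IRIV each
# select wavelengths from the smooth-detrend spectra block and from the
# paired texture block (energy for Vis-SWNIR, contrast for LWNIR); the
# selected columns are fused and scored with the SVM (6 models).

library(maizemold)

seed <- 1L
res <- run_experiment("feature", seed = seed, budget = "reduced",
                      output_dir = "results/feature")
print(res, row.names = FALSE)
tot <- tapply(res$n_spectra + res$n_texture, res$selector, sum)
cat("\nTotal selected variables per selector (both sensors):\n")
print(tot)
cat("All selections stay far below the 389/112 full block widths.\n")
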