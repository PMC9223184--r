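#!/usr/bin/env Rscript
# Stage one of the modeling study: pick the classifier on original spectra
# (SVM vs random forest vs KNN, per sensor), then compare spectral
# pretreatment chains (smooth-msc / smooth-detrend / smooth-center) with the
# winning classifier. Writes both summary tables under results/.

library(maizemold)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cat("== Classifier comparison on original spectra ==\n")
clf <- run_experiment("classifiers", seed = seed,
                      output_dir = "results/classifiers")
print(clf, row.names = FALSE)
best <- clf[which.max(clf$prediction_accuracy), ]
cat(sprintf("\nMost accurate: %s on %s (%.2f%% prediction)\n",
            best$classifier, best$sensor, best$prediction_accuracy))

cat("\n== Pretreatment comparison (SVM) ==\n")
pp <- run_experiment("preprocessing", seed = seed,
                     output_dir = "results/preprocessing")
print(pp, row.names = FALSE)
cat("\nsmooth-detrend balances accuracy against the calibration/prediction",
    "gap and is the chain used by the fusion stages.\n")
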