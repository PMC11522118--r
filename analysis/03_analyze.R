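#!/usr/bin/env Rscript

# Stage 3: patient-wise CV matrix, per-cohort mean CVs, the per-feature
# Welch screen at alpha = 0.05 (BH q-values reported alongside), the radar
# table of significant features and cohort descriptives.
#
# Usage: Rscript analysis/03_analyze.R [features_csv] [manifest_csv] [out_dir]

suppressPackageStartupMessages(library(lesioncv))
args <- commandArgs(trailingOnly = TRUE)
features <- if (length(args) >= 1) args[1] else "results/features/features.csv"
manifest <- if (length(args) >= 2) args[2] else "results/raw/manifest.csv"
out_dir <- if (length(args) >= 3) args[3] else "results/analysis"
sizes <- file.path(dirname(features), "lesion_sizes.csv")

res <- run_analyze(features, manifest, out_dir, alpha = 0.05,
                   lesion_sizes_path =
                     if (file.exists(sizes)) sizes else NULL)
print(res$report)
print(res$descriptives)
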