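#!/usr/bin/env Rscript

# Stage 2: split label masks into lesions, apply the 5 mm minimum
# equivalent-diameter filter and extract the 75 second-order texture
# features per lesion (bin width 25 HU, distance 1, 26-connectivity).
#
# Usage: Rscript analysis/02_extract.R [manifest_csv] [out_dir]

suppressPackageStartupMessages(library(lesioncv))
args <- commandArgs(trailingOnly = TRUE)
manifest <- if (length(args) >= 1) args[1] else "results/raw/manifest.csv"
out_dir <- if (length(args) >= 2) args[2] else "results/features"

run_extract(manifest, out_dir,
            config = texture_config(bin_width = 25, distance = 1,
                                    gldm_alpha = 0),
            min_diameter_mm = 5)
cat("feature table written under", out_dir, "\n")
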