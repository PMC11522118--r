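#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic two-cohort study.
#
# Cohort A: 20 patients, interlesional dispersion tau = 0.2.
# Cohort B: 15 patients, tau = 0.4 (double the dispersion).
# Both: 2-10 lesions per patient, nominal 6-voxel lesion radius inside
# 16^3-voxel cells at CT-like 0.7 x 0.7 x 1.5 mm spacing.
#
# Usage: Rscript analysis/01_simulate.R [out_dir] [seed]

suppressPackageStartupMessages(library(lesioncv))
args <- commandArgs(trailingOnly = TRUE)
out_dir <- if (length(args) >= 1) args[1] else "results/raw"
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

run_simulate(out_dir,
             n_patients_a = 20, n_patients_b = 15,
             lesions_per_patient = c(2, 10),
             tau_a = 0.2, tau_b = 0.4,
             lesion_radius_vox = 6, seed = seed,
             overwrite = TRUE)
cat("study written to", out_dir, "\n")
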