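#!/usr/bin/env Rscript
# Stage 1: build the synthetic breathing phantom that stands in for a 4D-CT
# exhale/inhale pair, with its analytically known deformation and lung mask.
suppressPackageStartupMessages(library(ventidose))
source("analysis/00_config.R")

out <- "results/phantom"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- phantom_config()
ph <- generate_phantom_pair(spec)

write_volume(ph$exhale, file.path(out, "exhale.nii.gz"))
write_volume(ph$inhale, file.path(out, "inhale.nii.gz"))
write_volume(ph$truth, file.path(out, "dvf_truth.nii.gz"))
write_volume(ph$lung, file.path(out, "lung.nii.gz"))

mag <- sqrt(apply(ph$truth$vectors^2, 1:3, sum))
stats <- data.frame(
  lung_voxels = sum(ph$lung$inside),
  lung_volume_cc = sum(ph$lung$inside) * prod(spec$spacing) / 1000,
  peak_displacement_mm = max(mag),
  mean_lung_displacement_mm = mean(mag[ph$lung$inside]))
write.csv(stats, file.path(out, "phantom_stats.csv"), row.names = FALSE)

cat("Phantom built:", paste(spec$grid_shape, collapse = "x"), "voxels at",
    paste(spec$spacing, collapse = "x"), "mm\n")
cat(sprintf("  lung volume %.0f cc, peak displacement %.1f mm (mean in lung %.1f mm)\n",
            stats$lung_volume_cc, stats$peak_displacement_mm,
            stats$mean_lung_displacement_mm))
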