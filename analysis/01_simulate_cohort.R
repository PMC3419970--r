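#!/usr/bin/env Rscript
# Simulate a small multi-site cohort with planted functional, voxel and
# morphometric class effects, and write its artifacts under results/cohort/.
# The full-size training-set composition is the generator default; this
# driver uses a reduced cohort so every later stage runs in minutes.

suppressPackageStartupMessages(library(adhdml))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(
  sites = data.frame(site = c("SiteA", "SiteB", "PittLike"),
                     n_td = c(20, 16, 12), n_adhd_c = c(10, 5, 0),
                     n_adhd_h = c(1, 0, 0), n_adhd_i = c(3, 7, 0)),
  n_timepoints = 96, n_roi = 8,
  planted_edges = data.frame(i = c(1, 3), j = c(2, 4), d = c(1.2, 1.2)),
  voxel_grid = c(5, 5, 5),
  reho_block = list(lo = c(2, 2, 2), hi = c(4, 4, 4)), reho_effect = 0.25,
  morph_effect = data.frame(
    column = c("lh_posteriorcingulate_ThickStd", "Left-Caudate_normMean"),
    d = c(1.2, 1)),
  iq_missing_sites = "SiteB",
  seed = seed)
cohort <- generate_cohort(cfg)

write_phenotypes(cohort$phenotypes, file.path(out, "phenotypes.csv"))
id1 <- cohort$phenotypes$subject_id[1]
write_timeseries_csv(cohort$timeseries[[id1]],
                     file.path(out, paste0(id1, "_timeseries.csv")))
write_nifti_array(cohort$voxels[[id1]],
                  file.path(out, paste0(id1, "_bold.nii.gz")),
                  pixdim = c(4, 4, 4, 2))
write_nifti_array(cohort$voxel_mask, file.path(out, "mask.nii.gz"))
utils::write.csv(cohort$morphometry, file.path(out, "morphometry.csv"),
                 row.names = FALSE)

tab <- table(cohort$phenotypes$site, cohort$phenotypes$dx)
cat("Simulated", nrow(cohort$phenotypes), "subjects across",
    nrow(cfg$sites), "sites (seed", seed, "):\n")
print(tab)
cat("ADHD - TD mean IQ difference:",
    round(mean(cohort$phenotypes$iq[cohort$phenotypes$dx != "TD"], na.rm = TRUE) -
          mean(cohort$phenotypes$iq[cohort$phenotypes$dx == "TD"], na.rm = TRUE), 1),
    "points (planted -9)\n")
cat("Artifacts in", out, "\n")
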