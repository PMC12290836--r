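#!/usr/bin/env Rscript
# Whole-brain searchlight information mapping.
#
# Maps emotion information with a radius-3 searchlight (93 voxels per
# sphere) for the within-imitation and cross-modal analyses of the two
# study-1-like cohorts; writes per-analysis group-mean accuracy maps as
# NIfTI. The 12^3 grid keeps the demonstration quick while leaving the
# sphere geometry untouched.

suppressPackageStartupMessages(library(crossmvpa))

out <- "results/searchlight"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
grid <- c(12, 12, 12)

for (nm in c("S1.1", "S1.2")) {
  seed <- if (nm == "S1.1") 111 else 112
  cfg <- synthetic_config(grid_dims = grid, seed = seed)
  coh <- generate_cohort(cfg)
  brain <- voxel_mask("brain", coh[[1]]$brain_mask)
  for (aname in c("within_imitation", "train_execution_test_imitation")) {
    spec <- default_analysis_matrix()[[aname]]
    maps <- lapply(coh, searchlight_map, analysis_mask = brain,
                   spec = spec, sphere = sphere_offsets(3))
    gm <- group_mean_map(maps)
    f <- file.path(out, paste0(nm, "_", aname, ".nii"))
    write_map(gm$grid, gm$mask, f)
    v <- gm$grid[gm$mask$grid]
    message(sprintf("%s %s: peak %.1f%%, %d voxels >= 60%%  -> %s",
                    nm, aname, max(v), sum(v >= 60), f))
  }
}
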