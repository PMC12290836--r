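# Shared fixtures, built lazily and cached for the session so expensive
# cohorts are generated once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small default-strength cohort on a compact grid
small_config <- function(seed = 11, n_subjects = 20, grid = c(10, 10, 10),
                         ...) {
  synthetic_config(grid_dims = grid, n_subjects = n_subjects, seed = seed,
                   ...)
}

small_cohort <- function() {
  fixture("small_cohort", function() generate_cohort(small_config()))
}

small_mask <- function() roi_masks_from_config(small_config())[[1]]

# a noiseless subject: planted shared execution/imitation pattern with
# near-zero noise (noise_sd must be > 0 by contract)
noiseless_subject <- function(seed = 5) {
  cfg <- synthetic_config(grid_dims = c(8, 8, 8), n_subjects = 1,
                          noise_sd = 1e-8, effect_amplitude = 1,
                          subject_pattern_jitter = 0, seed = seed)
  list(dataset = generate_subject(cfg, 1),
       mask = roi_masks_from_config(cfg)[[1]], config = cfg)
}

# hand-built dataset: betas are exactly sign(emotion) * w on ROI voxels
# for the given modalities (zero elsewhere, zero noise)
exact_pattern_dataset <- function(pattern_by_modality,
                                  grid = c(6, 6, 6),
                                  roi = default_roi(c(6, 6, 6), n = 8)) {
  tt <- make_design("study1")
  d <- grid
  lin <- roi$voxels[, 1] + (roi$voxels[, 2] - 1) * d[1] +
    (roi$voxels[, 3] - 1) * d[1] * d[2]
  flat <- matrix(0, prod(d), nrow(tt))
  for (i in seq_len(nrow(tt))) {
    m <- tt$modality[i]
    if (!m %in% names(pattern_by_modality)) next
    s <- if (tt$emotion[i] == "fear") 1 else -1
    flat[lin, i] <- s * pattern_by_modality[[m]]
  }
  ds <- subject_dataset(tt, array(flat, c(d, nrow(tt))), array(TRUE, d))
  g <- array(FALSE, d); g[roi$voxels] <- TRUE
  list(dataset = ds, mask = voxel_mask("roi", g), roi_linear = lin)
}
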