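#' Synthetic-cohort configuration
#'
#' Describes a simulated cohort with the same trial economy as the
#' imitation paradigm (three experimental modalities of 5 blocks x 4
#' trials plus interleaved control blocks, or the two-condition
#' follow-up design) and a planted, known ground truth: each modality
#' carries an emotion-discriminative spatial pattern that is `"shared"`
#' with the reference pattern, `"distinct"` (orthogonal to it), or
#' `"null"` (absent). Cross-modal decoding is recoverable above chance
#' exactly for pairs of `"shared"` modalities.
#'
#' @param grid_dims length-3 integer grid size (default 20^3 voxels).
#' @param roi_specs list of ROIs, each `list(name=, voxels=)` with an
#'   n x 3 matrix of 1-based voxel coordinates; the union of ROI voxels
#'   is the support of the planted patterns. Default: one 20-voxel ROI
#'   at the grid centre.
#' @param effect_amplitude pattern strength in beta units (>= 0);
#'   default 1.
#' @param noise_sd sd of i.i.d. Gaussian trial noise (> 0); default 0.5.
#' @param pattern_sharing named character vector over modalities with
#'   values `"shared"`, `"distinct"`, `"null"`. Default plants a shared
#'   pattern in execution and imitation and nothing in observation or
#'   control, the configuration that mirrors an action-specific shared
#'   representation.
#' @param subject_pattern_jitter sd of the subject-specific pattern
#'   perturbation (patterns are re-normalized after jitter); default 0.2.
#' @param n_subjects cohort size; default 20.
#' @param design `"study1"` or `"study2"`.
#' @param emotion_coding `"sign_flip"` (fear = +pattern, anger =
#'   -pattern; default) or `"two_pattern"` (independent fear and anger
#'   patterns).
#' @param noise_smoothing_fwhm optional Gaussian smoothing FWHM (voxels)
#'   applied to the noise field; default 0 (off, matching unsmoothed
#'   beta images).
#' @param seed master seed; all randomness derives from named substreams
#'   of it.
#' @return a `synthetic_config`.
#' @export
synthetic_config <- function(grid_dims = c(20L, 20L, 20L),
                             roi_specs = NULL,
                             effect_amplitude = 1,
                             noise_sd = 0.5,
                             pattern_sharing = c(execution = "shared",
                                                 imitation = "shared",
                                                 observation = "null",
                                                 control = "null"),
                             subject_pattern_jitter = 0.2,
                             n_subjects = 20L,
                             design = c("study1", "study2"),
                             emotion_coding = c("sign_flip", "two_pattern"),
                             noise_smoothing_fwhm = 0,
                             seed = 1L) {
  design <- match.arg(design)
  emotion_coding <- match.arg(emotion_coding)
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1),
            effect_amplitude >= 0, noise_sd > 0,
            subject_pattern_jitter >= 0, n_subjects >= 1)
  if (is.null(roi_specs)) {
    roi_specs <- list(default_roi(grid_dims))
  }
  for (r in roi_specs) {
    stopifnot(is.character(r$name), is.matrix(r$voxels), ncol(r$voxels) == 3)
    if (any(r$voxels < 1) ||
        any(sweep(r$voxels, 2, grid_dims, `>`)))
      stop("ROI '", r$name, "' has voxels outside the grid")
  }
  design_mods <- if (design == "study1") MODALITIES
                 else c("imitation", "control")
  if (!all(names(pattern_sharing) %in% design_mods))
    stop("pattern_sharing names modality absent from design: ",
         paste(setdiff(names(pattern_sharing), design_mods), collapse = ", "))
  stopifnot(all(pattern_sharing %in% c("shared", "distinct", "null")))
  structure(list(grid_dims = grid_dims, roi_specs = roi_specs,
                 effect_amplitude = effect_amplitude, noise_sd = noise_sd,
                 pattern_sharing = pattern_sharing,
                 subject_pattern_jitter = subject_pattern_jitter,
                 n_subjects = as.integer(n_subjects), design = design,
                 emotion_coding = emotion_coding,
                 noise_smoothing_fwhm = noise_smoothing_fwhm,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default 20-voxel ROI at the grid centre
#' @param grid_dims length-3 integer vector.
#' @param n number of voxels (default 20).
#' @param name ROI name.
#' @return `list(name, voxels)` usable in `roi_specs`.
#' @export
default_roi <- function(grid_dims, n = 20L, name = "planted") {
  ctr <- pmax(1L, as.integer(grid_dims) %/% 2L)
  side <- ceiling(n^(1 / 3))
  off <- seq_len(side) - 1L
  g <- as.matrix(expand.grid(x = ctr[1] + off, y = ctr[2] + off,
                             z = ctr[3] + off))
  g <- g[order(g[, 3], g[, 2], g[, 1]), , drop = FALSE]
  g <- g[seq_len(min(n, nrow(g))), , drop = FALSE]
  if (any(g < 1) || any(sweep(g, 2, grid_dims, `>`)))
    stop("grid too small for default ROI")
  dimnames(g) <- NULL
  list(name = name, voxels = g)
}

#' Build the trial design of one of the two study paradigms
#'
#' `"study1"`: imitation, observation and execution each with 5 blocks of
#' 4 trials (2 fear + 2 anger per block, 10 + 10 in total), and 30
#' control trials delivered as 3 two-trial control blocks between each
#' experimental-block cycle (15 control blocks in total). `"study2"`:
#' imitation and control only, 5 blocks x 4 trials each (10 fear, 10
#' anger per condition). Emotion order is pseudorandomized within block
#' under the stated balance; block order is fixed.
#'
#' @param design `"study1"` or `"study2"`.
#' @param seed seed for the within-block emotion order (fixed default so
#'   the template design is reproducible).
#' @param subject_id label for the returned table.
#' @return a `trial_table`.
#' @export
make_design <- function(design = c("study1", "study2"), seed = 20260101L,
                        subject_id = "template") {
  design <- match.arg(design)
  shuffle <- function(x) x[sample.int(length(x))]
  with_substream(seed, .STREAM_DESIGN, {
    rows <- list()
    add <- function(modality, block, emotions) {
      rows[[length(rows) + 1]] <<- data.frame(
        modality = modality, emotion = emotions,
        block = block, stringsAsFactors = FALSE)
    }
    if (design == "study1") {
      ctrl_block <- 0L
      for (cycle in 1:5) {
        for (m in c("imitation", "observation", "execution"))
          add(m, cycle, shuffle(c("fear", "fear", "anger", "anger")))
        for (k in 1:3) {
          ctrl_block <- ctrl_block + 1L
          add("control", ctrl_block, shuffle(c("fear", "anger")))
        }
      }
    } else {
      for (cycle in 1:5) {
        add("imitation", cycle, shuffle(c("fear", "fear", "anger", "anger")))
        add("control", cycle, shuffle(c("fear", "fear", "anger", "anger")))
      }
    }
    df <- do.call(rbind, rows)
    trial_table(subject_id, df$modality, df$emotion, df$block)
  })
}

# Unit-norm reference and per-modality planted patterns over the ROI
# voxel union. "distinct" patterns are orthogonalized against the
# reference so cross-decoding against a "shared" modality is chance in
# expectation.
.cohort_patterns <- function(config) {
  vox <- .roi_voxel_indices(config)
  nv <- nrow(vox$coords)
  with_substream(config$seed, .STREAM_PATTERN, {
    unit <- function(v) v / sqrt(sum(v^2))
    ref <- unit(rnorm(nv))
    ref2 <- NULL
    if (config$emotion_coding == "two_pattern") {
      raw <- rnorm(nv)
      ref2 <- unit(raw - sum(raw * ref) * ref)
    }
    distinct <- list()
    for (m in sort(names(config$pattern_sharing))) {
      if (config$pattern_sharing[[m]] == "distinct") {
        raw <- rnorm(nv)
        d <- raw - sum(raw * ref) * ref
        if (!is.null(ref2)) d <- d - sum(d * ref2) * ref2
        distinct[[m]] <- unit(d)
      }
    }
    list(ref = ref, ref2 = ref2, distinct = distinct, voxels = vox)
  })
}

.roi_voxel_indices <- function(config) {
  coords <- unique(do.call(rbind, lapply(config$roi_specs, `[[`, "voxels")))
  coords <- coords[order(coords[, 3], coords[, 2], coords[, 1]), ,
                   drop = FALSE]
  d <- config$grid_dims
  lin <- coords[, 1] + (coords[, 2] - 1L) * d[1] +
    (coords[, 3] - 1L) * d[1] * d[2]
  list(coords = coords, linear = as.integer(lin))
}

#' Generate one synthetic subject
#'
#' Trial-wise betas are `sign(emotion) * A * w_m(v) + noise`, with
#' `sign(fear) = +1`, `sign(anger) = -1`, amplitude `A`, i.i.d. Gaussian
#' noise over voxels and trials, and `w_m` the modality's planted
#' pattern: the cohort reference pattern for `"shared"` modalities, an
#' orthogonal pattern for `"distinct"`, zero for `"null"`. Each subject
#' perturbs the cohort patterns by Gaussian jitter and re-normalizes, so
#' all `"shared"` modalities within a subject still carry one common
#' pattern. Deterministic given `(config$seed, subject_index)`.
#'
#' @param config a `synthetic_config`.
#' @param subject_index 1-based subject number.
#' @return a `subject_dataset`.
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "synthetic_config"), subject_index >= 1)
  pat <- .cohort_patterns(config)
  trials <- make_design(config$design, seed = config$seed,
                        subject_id = sprintf("sub-%02d", subject_index))
  d <- config$grid_dims
  nt <- nrow(trials)
  nv_roi <- length(pat$voxels$linear)
  unit <- function(v) v / sqrt(sum(v^2))

  with_substream(config$seed, .stream_subject(subject_index), {
    # subject-specific patterns: jitter draws come first (fixed order),
    # then the noise field, so both are reproducible per subject
    j <- config$subject_pattern_jitter
    w_shared <- unit(pat$ref + j * rnorm(nv_roi))
    w_shared2 <- if (!is.null(pat$ref2)) unit(pat$ref2 + j * rnorm(nv_roi))
    w_distinct <- list()
    for (m in sort(names(pat$distinct)))
      w_distinct[[m]] <- unit(pat$distinct[[m]] + j * rnorm(nv_roi))

    noise <- array(rnorm(prod(d) * nt, sd = config$noise_sd), c(d, nt))
    if (config$noise_smoothing_fwhm > 0)
      noise <- .smooth4d(noise, config$noise_smoothing_fwhm)

    flat <- matrix(noise, prod(d), nt)
    A <- config$effect_amplitude
    if (A > 0) {
      for (i in seq_len(nt)) {
        m <- trials$modality[i]
        sh <- if (m %in% names(config$pattern_sharing))
          config$pattern_sharing[[m]] else "null"
        if (sh == "null") next
        if (config$emotion_coding == "sign_flip") {
          w <- if (sh == "shared") w_shared else w_distinct[[m]]
          s <- if (trials$emotion[i] == "fear") 1 else -1
          flat[pat$voxels$linear, i] <-
            flat[pat$voxels$linear, i] + s * A * w
        } else {
          # two-pattern coding: each emotion has its own pattern
          if (sh == "shared") {
            w <- if (trials$emotion[i] == "fear") w_shared else w_shared2
          } else {
            w <- w_distinct[[m]]
            if (trials$emotion[i] == "anger") w <- -w
          }
          flat[pat$voxels$linear, i] <- flat[pat$voxels$linear, i] + A * w
        }
      }
    }
    betas <- array(flat, c(d, nt))
    subject_dataset(trials, betas, array(TRUE, d))
  })
}

# separable Gaussian smoothing of each 3D volume (FWHM in voxels)
.smooth4d <- function(arr, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - r); hi <- min(n, i + r)
      kk <- k[(lo - i + r + 1):(hi - i + r + 1)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  d <- dim(arr)
  for (t in seq_len(d[4])) {
    v <- arr[, , , t]
    v <- apply(v, c(2, 3), conv1)
    v <- aperm(apply(v, c(1, 3), conv1), c(2, 1, 3))
    v <- aperm(apply(v, c(1, 2), conv1), c(2, 3, 1))
    arr[, , , t] <- v
  }
  arr
}

#' Generate a synthetic cohort
#'
#' @param config a `synthetic_config`.
#' @return list of `n_subjects` independent `subject_dataset`s (disjoint
#'   RNG substreams per subject).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lapply(seq_len(config$n_subjects), function(i) generate_subject(config, i))
}

#' Generate label-independent motion covariates
#'
#' Six rigid-body motion parameters (3 translations, 3 rotations) per
#' trial, simulated as slow random-walk drift that is independent of the
#' emotion labels by construction — the negative control used to verify
#' that emotional content cannot be decoded from head motion alone.
#'
#' @param trials a `trial_table`.
#' @param seed integer seed.
#' @param step_sd innovation sd per trial (mm / degrees); default 0.05.
#' @return data.frame with columns `trans_x..z`, `rot_x..z`, one row per
#'   trial.
#' @export
generate_motion_covariates <- function(trials, seed, step_sd = 0.05) {
  validate_trial_table(trials)
  n <- nrow(trials)
  with_substream(seed, .STREAM_MOTION, {
    m <- vapply(1:6, function(j) cumsum(rnorm(n, sd = step_sd)),
                numeric(n))
    m <- as.data.frame(m)
    names(m) <- c("trans_x", "trans_y", "trans_z",
                  "rot_x", "rot_y", "rot_z")
    m
  })
}

#' ROI masks implied by a synthetic configuration
#'
#' @param config a `synthetic_config`.
#' @return named list of `voxel_mask` objects, one per planted ROI.
#' @export
roi_masks_from_config <- function(config) {
  d <- config$grid_dims
  out <- list()
  for (r in config$roi_specs) {
    g <- array(FALSE, d)
    g[r$voxels] <- TRUE
    out[[r$name]] <- voxel_mask(r$name, g)
  }
  out
}
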