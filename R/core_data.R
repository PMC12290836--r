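MODALITIES <- c("execution", "observation", "imitation", "control")
EMOTIONS <- c("fear", "anger")
EXPERIMENTAL_MODALITIES <- c("execution", "observation", "imitation")

#' Construct a trial table
#'
#' A trial table describes one subject's acquisition: one row per trial
#' with the action modality (execution, observation, imitation or
#' control), the emotional content of the facial expression (fear or
#' anger), the acquisition block, and the 0-based position in acquisition
#' order. Row order equals acquisition order and is the positional link
#' to the trial-wise beta volumes.
#'
#' @param subject_id character scalar.
#' @param modality character vector over
#'   `c("execution","observation","imitation","control")`.
#' @param emotion character vector over `c("fear","anger")`.
#' @param block integer vector of within-modality block numbers (>= 1).
#' @param trial_index optional 0-based acquisition positions; defaults to
#'   row order.
#' @return a `trial_table` (a validated `data.frame`).
#' @export
trial_table <- function(subject_id, modality, emotion, block,
                        trial_index = seq_along(modality) - 1L) {
  tt <- data.frame(
    modality = as.character(modality),
    emotion = as.character(emotion),
    block = as.integer(block),
    trial_index = as.integer(trial_index),
    stringsAsFactors = FALSE
  )
  attr(tt, "subject_id") <- as.character(subject_id)[1]
  class(tt) <- c("trial_table", "data.frame")
  validate_trial_table(tt)
}

#' Validate a trial table
#'
#' Enforces the design invariants assumed downstream: known modality and
#' emotion levels, blocks >= 1, unique contiguous 0-based trial indices,
#' and within every experimental modality an equal number of fear and
#' anger trials per block (the class balance that makes raw accuracy
#' equal balanced accuracy).
#'
#' @param tt a `trial_table`.
#' @return `tt`, invisibly unchanged, or an error.
#' @export
validate_trial_table <- function(tt) {
  stopifnot(is.data.frame(tt))
  req <- c("modality", "emotion", "block", "trial_index")
  if (!all(req %in% names(tt)))
    stop("trial table must have columns ", paste(req, collapse = ", "))
  if (nrow(tt) == 0) stop("trial table is empty")
  if (!all(tt$modality %in% MODALITIES))
    stop("unknown modality: ",
         paste(setdiff(unique(tt$modality), MODALITIES), collapse = ", "))
  if (!all(tt$emotion %in% EMOTIONS))
    stop("unknown emotion: ",
         paste(setdiff(unique(tt$emotion), EMOTIONS), collapse = ", "))
  if (any(tt$block < 1L)) stop("block numbers must be >= 1")
  idx <- sort(tt$trial_index)
  if (!identical(idx, seq_len(nrow(tt)) - 1L))
    stop("trial_index must be unique and contiguous from 0")
  for (m in intersect(unique(tt$modality), EXPERIMENTAL_MODALITIES)) {
    sub <- tt[tt$modality == m, ]
    bal <- tapply(sub$emotion == "fear", sub$block, mean)
    if (any(abs(bal - 0.5) > 1e-12))
      stop("unbalanced emotions within block for modality '", m, "'")
  }
  tt
}

#' Construct a subject dataset
#'
#' Bundles one subject's trial-wise parameter-estimate (beta) volumes,
#' the trial table, and a brain mask. Betas are stored as a 4D array in
#' NIfTI axis order `x, y, z, trial`; volume `i` corresponds positionally
#' to trial-table row `i`. All internal geometry works in 0-based voxel
#' indices; the affine is carried only for I/O fidelity.
#'
#' @param trials a `trial_table`.
#' @param betas 4D numeric array, dims `c(nx, ny, nz, n_trials)`.
#' @param brain_mask 3D logical array with dims `c(nx, ny, nz)`; at least
#'   one `TRUE` voxel. Out-of-mask voxels are never used as features.
#' @param voxel_size length-3 numeric, mm (metadata only).
#' @param affine optional 4x4 matrix carried through to NIfTI output.
#' @return a `subject_dataset`.
#' @export
subject_dataset <- function(trials, betas, brain_mask,
                            voxel_size = c(3, 3, 3), affine = NULL) {
  validate_trial_table(trials)
  if (length(dim(betas)) != 4) stop("betas must be a 4D array")
  if (length(dim(brain_mask)) != 3 ||
      !identical(dim(betas)[1:3], dim(brain_mask)))
    stop("grid mismatch: betas and brain mask dims differ")
  if (dim(betas)[4] != nrow(trials))
    stop("design mismatch: ", dim(betas)[4], " volumes but ",
         nrow(trials), " trial rows")
  brain_mask <- array(as.logical(brain_mask), dim(brain_mask))
  if (!any(brain_mask)) stop("empty mask: brain mask has no TRUE voxel")
  flat <- matrix(betas, prod(dim(betas)[1:3]), dim(betas)[4])
  if (!all(is.finite(flat[as.vector(brain_mask), , drop = FALSE])))
    stop("invalid betas: non-finite in-mask values")
  structure(
    list(trials = trials, betas = betas, brain_mask = brain_mask,
         voxel_size = as.numeric(voxel_size), affine = affine),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  d <- dim(x$betas)
  cat(sprintf("<subject_dataset> %s: %d trials, grid %dx%dx%d, %d in-mask voxels\n",
              attr(x$trials, "subject_id"), d[4], d[1], d[2], d[3],
              sum(x$brain_mask)))
  invisible(x)
}

#' Construct a voxel mask
#'
#' @param name character label (e.g. ROI name).
#' @param grid 3D logical array; must be nonempty.
#' @param space character space tag; masks and datasets may only be
#'   combined when their grids (and tags) agree. Defaults to the grid
#'   dimension string.
#' @return a `voxel_mask`.
#' @export
voxel_mask <- function(name, grid, space = paste(dim(grid), collapse = "x")) {
  if (length(dim(grid)) != 3) stop("mask grid must be 3D")
  grid <- array(as.logical(grid), dim(grid))
  if (anyNA(grid)) stop("mask grid contains NA")
  if (!any(grid)) stop("empty mask: '", name, "' has no TRUE voxel")
  structure(list(name = as.character(name)[1], grid = grid,
                 space = as.character(space)[1]),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> '%s': %d voxels in %s\n", x$name,
              sum(x$grid), x$space))
  invisible(x)
}

#' Linear-classifier specification
#'
#' The decoder is a soft-margin linear support-vector classifier with a
#' fixed regularization constant, matching the common neuroimaging
#' default (no hyperparameter search).
#'
#' @param C positive regularization constant; default 1.
#' @param scaling `"none"` (default; betas enter as-is) or
#'   `"zscore_train"` (features z-scored with train-fold statistics).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(C = 1, scaling = c("none", "zscore_train")) {
  scaling <- match.arg(scaling)
  if (!is.numeric(C) || length(C) != 1 || C <= 0) stop("C must be > 0")
  structure(list(kind = "linear_max_margin", C = as.numeric(C),
                 scaling = scaling),
            class = "classifier_spec")
}

#' Union of ROI masks
#'
#' Combines single-region masks into a system mask (e.g. parietal,
#' inferior-frontal and superior-temporal regions into a mirror-neuron
#' system mask) by voxelwise union. Commutative, associative and
#' idempotent.
#'
#' @param masks list of `voxel_mask` objects with identical dims and
#'   space tags.
#' @param name name of the combined mask.
#' @return a `voxel_mask`.
#' @export
combine_masks <- function(masks, name) {
  if (length(masks) < 1) stop("need at least one mask")
  stopifnot(all(vapply(masks, inherits, logical(1), "voxel_mask")))
  d <- dim(masks[[1]]$grid)
  sp <- masks[[1]]$space
  for (m in masks[-1]) {
    if (!identical(dim(m$grid), d) || !identical(m$space, sp))
      stop("grid mismatch: masks differ in dims or space tag")
  }
  g <- Reduce(`|`, lapply(masks, `[[`, "grid"))
  voxel_mask(name, g, space = sp)
}

# ---- I/O ------------------------------------------------------------------

#' Read a trial-wise beta series from disk
#'
#' Accepts either one 4D NIfTI file or a list of 3D files (normalized to
#' one internal 4D array), a binary brain-mask NIfTI, and a BIDS-style
#' events TSV with columns `modality`, `emotion`, `block` (and optionally
#' `trial_index`). Trial order is positional: TSV row i describes volume
#' i; no filename heuristics.
#'
#' @param path_or_paths character vector of NIfTI paths.
#' @param mask_path path to a binary mask NIfTI of identical spatial dims.
#' @param trials_path path to the events TSV.
#' @param subject_id subject label for the trial table.
#' @return a validated `subject_dataset`.
#' @export
read_beta_series <- function(path_or_paths, mask_path, trials_path,
                             subject_id = "subject") {
  imgs <- lapply(path_or_paths, RNifti::readNifti)
  vols <- list()
  for (im in imgs) {
    a <- as.array(im)
    nd <- length(dim(a))
    if (nd == 3) {
      vols[[length(vols) + 1]] <- a
    } else if (nd == 4) {
      for (k in seq_len(dim(a)[4])) vols[[length(vols) + 1]] <- a[, , , k]
    } else stop("beta images must be 3D or 4D NIfTI")
  }
  d <- dim(vols[[1]])
  if (!all(vapply(vols, function(v) identical(dim(v), d), logical(1))))
    stop("grid mismatch: beta volumes differ in dims")
  mimg <- RNifti::readNifti(mask_path)
  mask <- as.array(mimg) != 0
  if (!identical(dim(mask), d))
    stop("grid mismatch: mask dims differ from beta dims")
  tsv <- read.delim(trials_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("modality", "emotion", "block") %in% names(tsv)))
    stop("events TSV must have columns modality, emotion, block")
  if (length(vols) != nrow(tsv))
    stop("design mismatch: ", length(vols), " volumes but ",
         nrow(tsv), " trial rows")
  ti <- if ("trial_index" %in% names(tsv)) tsv$trial_index
        else seq_len(nrow(tsv)) - 1L
  tt <- trial_table(subject_id, tsv$modality, tsv$emotion, tsv$block, ti)
  betas <- array(unlist(vols, use.names = FALSE), dim = c(d, length(vols)))
  vs <- tryCatch(RNifti::pixdim(imgs[[1]])[1:3], error = function(e) c(3, 3, 3))
  subject_dataset(tt, betas, mask, voxel_size = vs,
                  affine = tryCatch(RNifti::xform(imgs[[1]]),
                                    error = function(e) NULL))
}

#' Write a subject dataset to disk
#'
#' Writes the betas as one 4D NIfTI, the brain mask as a binary NIfTI and
#' the trial table as a BIDS-style events TSV, the layout accepted by
#' [read_beta_series()].
#'
#' @param dataset a `subject_dataset`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; defaults to the subject id.
#' @return named character vector of the three paths written.
#' @export
write_subject_dataset <- function(dataset, dir,
                                  prefix = attr(dataset$trials, "subject_id")) {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bpath <- file.path(dir, paste0(prefix, "_betas.nii"))
  mpath <- file.path(dir, paste0(prefix, "_mask.nii"))
  tpath <- file.path(dir, paste0(prefix, "_events.tsv"))
  RNifti::writeNifti(.as_nifti(dataset$betas, dataset), bpath,
                     datatype = "double")
  RNifti::writeNifti(.as_nifti(dataset$brain_mask * 1L, dataset), mpath)
  write.table(as.data.frame(dataset$trials), tpath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  c(betas = bpath, mask = mpath, events = tpath)
}

.as_nifti <- function(arr, reference) {
  img <- RNifti::asNifti(arr)
  if (!is.null(reference$affine)) {
    RNifti::qform(img) <- structure(reference$affine, code = 2L)
  }
  img
}

#' Write a statistical/accuracy map as NIfTI
#'
#' Out-of-mask voxels are written as NaN so downstream viewers ignore
#' them; in-mask values are preserved at float precision.
#'
#' @param map 3D numeric array or an `accuracy_map`.
#' @param reference a `subject_dataset` or `voxel_mask` providing dims,
#'   mask and (if available) affine.
#' @param path output file path (.nii).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, reference, path) {
  if (inherits(map, "accuracy_map")) {
    if (missing(reference)) reference <- map$mask
    map <- map$grid
  }
  if (inherits(reference, "subject_dataset")) {
    mask <- reference$brain_mask
    ref <- reference
  } else if (inherits(reference, "voxel_mask")) {
    mask <- reference$grid
    ref <- list(affine = NULL)
  } else stop("reference must be a subject_dataset or voxel_mask")
  if (!identical(dim(map), dim(mask)))
    stop("grid mismatch: map dims differ from reference")
  if (!any(mask)) stop("empty mask")
  out <- map
  out[!mask] <- NaN
  RNifti::writeNifti(.as_nifti(out, ref), path, datatype = "double")
  invisible(path)
}

#' Read a map written by [write_map()]
#' @param path NIfTI path.
#' @return 3D numeric array (out-of-mask voxels are NaN).
#' @export
read_map <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  array(as.numeric(a), dim(a))
}

#' Write a results table as TSV
#'
#' One row per (cohort x ROI x analysis); tab-separated with a header
#' row, mirroring the layout of a per-analysis accuracy/AUC table.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
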