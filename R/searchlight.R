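#' Searchlight sphere offsets
#'
#' Integer voxel offsets with squared Euclidean norm strictly less than
#' `radius^2`. The strict-inequality convention is pinned by the sphere
#' size it implies at the conventional radius of 3 voxels: 93 voxels per
#' searchlight (the non-strict convention would give 123). The offset
#' set always contains the centre and is symmetric under sign flips and
#' axis permutations.
#'
#' @param radius positive sphere radius in voxel units (default 3).
#' @return a `sphere_index`: `list(radius, offsets)` with `offsets` an
#'   n x 3 integer matrix in canonical (z, y, x ascending) order.
#' @export
sphere_offsets <- function(radius = 3) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a positive number")
  b <- max(0L, as.integer(ceiling(radius) - 1))
  g <- as.matrix(expand.grid(x = -b:b, y = -b:b, z = -b:b))
  keep <- rowSums(g^2) < radius^2
  off <- g[keep, , drop = FALSE]
  off <- off[order(off[, 3], off[, 2], off[, 1]), , drop = FALSE]
  dimnames(off) <- NULL
  structure(list(radius = radius, offsets = off), class = "sphere_index")
}

#' @export
print.sphere_index <- function(x, ...) {
  cat(sprintf("<sphere_index> radius %g: %d voxels\n", x$radius,
              nrow(x$offsets)))
  invisible(x)
}

#' Searchlight information map for one subject
#'
#' Runs the decoding analysis inside a sphere centred on every voxel of
#' `analysis_mask` (intersected with the dataset's brain mask) and
#' assigns the mean decoding accuracy to the centre voxel. Spheres are
#' truncated at grid and mask edges (the centre voxel is always
#' included), so full coverage is retained at the brain boundary.
#' Centres are independent; any execution order yields an identical map.
#'
#' @param dataset a `subject_dataset`.
#' @param analysis_mask a `voxel_mask`: which centres to map.
#' @param spec a `decoding_spec` (scaling `"none"` supported on this
#'   fast path).
#' @param sphere a `sphere_index`; default radius 3.
#' @return an `accuracy_map`: `list(grid, mask, provenance)` with
#'   percent accuracies at mapped centres and `NaN` elsewhere.
#' @export
searchlight_map <- function(dataset, analysis_mask, spec,
                            sphere = sphere_offsets(3)) {
  stopifnot(inherits(dataset, "subject_dataset"),
            inherits(analysis_mask, "voxel_mask"),
            inherits(sphere, "sphere_index"))
  if (!identical(dim(analysis_mask$grid), dim(dataset$brain_mask)))
    stop("grid mismatch: analysis mask dims differ from dataset")
  if (spec$classifier$scaling != "none")
    stop("searchlight fast path supports scaling = 'none'")
  setup <- .fold_setup(dataset, spec)
  d <- dim(dataset$betas)
  flat <- matrix(dataset$betas, prod(d[1:3]), d[4])[, setup$rows,
                                                    drop = FALSE]
  inmask <- analysis_mask$grid & dataset$brain_mask
  centers <- which(inmask)
  grid <- array(NaN, d[1:3])
  Ymat <- matrix(setup$y, ncol = 1)
  C <- spec$classifier$C
  off <- sphere$offsets
  brain <- as.vector(dataset$brain_mask)
  cc <- arrayInd(centers, d[1:3])
  nfeat <- integer(length(centers))
  for (k in seq_along(centers)) {
    nb <- sweep(off, 2, cc[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    lin <- sort(lin[brain[lin]])
    X <- t(flat[lin, , drop = FALSE])
    fr <- .fold_fracs(X, Ymat, setup$folds, C)[, 1]
    grid[centers[k]] <- 100 * mean(fr)
    nfeat[k] <- length(lin)
  }
  structure(list(
    grid = grid,
    mask = voxel_mask(paste0(analysis_mask$name, "+brain"), inmask,
                      space = analysis_mask$space),
    provenance = list(spec = spec, radius = sphere$radius,
                      n_offsets = nrow(off),
                      feature_count_range = range(nfeat),
                      subject_id = attr(dataset$trials, "subject_id"))
  ), class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  v <- x$grid[x$mask$grid]
  cat(sprintf("<accuracy_map> %d centres, accuracy %.1f-%.1f%% (mean %.1f%%)\n",
              sum(x$mask$grid), min(v), max(v), mean(v)))
  invisible(x)
}

#' Group-mean accuracy map
#'
#' Unweighted voxelwise mean across subjects' maps. A voxel missing
#' (NaN) in any subject is NaN in the group map.
#'
#' @param maps list of `accuracy_map`s on identical grids.
#' @return an `accuracy_map` with the common mask.
#' @export
group_mean_map <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, logical(1), "accuracy_map")))
  d <- dim(maps[[1]]$grid)
  for (m in maps) if (!identical(dim(m$grid), d))
    stop("grid mismatch between subject maps")
  acc <- Reduce(`+`, lapply(maps, `[[`, "grid")) / length(maps)
  common <- Reduce(`&`, lapply(maps, function(m) m$mask$grid))
  structure(list(
    grid = acc,
    mask = voxel_mask("group", common, space = maps[[1]]$mask$space),
    provenance = list(n_subjects = length(maps),
                      subject_provenance = maps[[1]]$provenance)
  ), class = "accuracy_map")
}

#' Per-subject searchlight permutation-null maps
#'
#' Re-runs the searchlight with label permutations (same scheme as
#' [subject_null()]) and returns one accuracy map per permutation, for
#' voxelwise two-step group inference.
#'
#' @param dataset a `subject_dataset`.
#' @param analysis_mask a `voxel_mask`.
#' @param spec a `decoding_spec`.
#' @param sphere a `sphere_index`.
#' @param config an [inference_config()].
#' @param stream RNG substream index for this subject's permutations.
#' @return matrix (n_centres x n_perm) of percent accuracies, with
#'   attribute `centers` (linear voxel indices).
#' @export
searchlight_null_maps <- function(dataset, analysis_mask, spec,
                                  sphere = sphere_offsets(3),
                                  config = inference_config(),
                                  stream = 0L) {
  setup <- .fold_setup(dataset, spec)
  Yperm <- .permutation_matrix(dataset, spec, setup, config, stream)
  d <- dim(dataset$betas)
  flat <- matrix(dataset$betas, prod(d[1:3]), d[4])[, setup$rows,
                                                    drop = FALSE]
  inmask <- analysis_mask$grid & dataset$brain_mask
  centers <- which(inmask)
  brain <- as.vector(dataset$brain_mask)
  cc <- arrayInd(centers, d[1:3])
  off <- sphere$offsets
  out <- matrix(NA_real_, length(centers), ncol(Yperm))
  for (k in seq_along(centers)) {
    nb <- sweep(off, 2, cc[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    lin <- sort(lin[brain[lin]])
    X <- t(flat[lin, , drop = FALSE])
    fr <- .fold_fracs(X, Yperm, setup$folds, spec$classifier$C)
    # apply(mean) keeps float behaviour identical to the observed map
    out[k, ] <- 100 * apply(fr, 2, mean)
  }
  attr(out, "centers") <- centers
  out
}
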