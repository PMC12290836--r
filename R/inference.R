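#' Two-step permutation inference configuration
#'
#' Subject-level label permutations followed by group-level bootstrap
#' draws of permutation accuracies, tested right-tailed against the
#' observed group mean.
#'
#' @param n_perm subject-level label permutations (default 100).
#' @param n_draws group-level bootstrap draws (default 1e5).
#' @param alpha significance level (default 0.05).
#' @param seed master seed for permutation and bootstrap substreams.
#' @param permutation_unit `"trial_within_block"` (default: labels
#'   shuffled within block within modality, preserving fold structure
#'   and class balance) or `"block_flip"` (whole-block label swaps).
#' @return an `inference_config`.
#' @export
inference_config <- function(n_perm = 100L, n_draws = 1e5, alpha = 0.05,
                             seed = 1L,
                             permutation_unit = c("trial_within_block",
                                                  "block_flip")) {
  permutation_unit <- match.arg(permutation_unit)
  stopifnot(n_perm >= 1, n_draws >= 1, alpha > 0, alpha < 1)
  structure(list(n_perm = as.integer(n_perm), n_draws = as.integer(n_draws),
                 alpha = alpha, tail = "right", seed = as.integer(seed),
                 permutation_unit = permutation_unit),
            class = "inference_config")
}

# One label permutation of `labels` restricted to `perm_rows`, shuffled
# within the (modality x block) cells of those rows (or sign-flipping
# whole blocks). Returns the full permuted label vector.
.permute_labels <- function(labels, groups, perm_rows, unit) {
  out <- labels
  if (unit == "trial_within_block") {
    for (g in unique(groups[perm_rows])) {
      idx <- perm_rows[groups[perm_rows] == g]
      out[idx] <- labels[idx][sample.int(length(idx))]
    }
  } else {
    cls <- sort(unique(labels))
    for (g in unique(groups[perm_rows])) {
      idx <- perm_rows[groups[perm_rows] == g]
      if (runif(1) < 0.5)
        out[idx] <- ifelse(labels[idx] == cls[1], cls[2], cls[1])
    }
  }
  out
}

# Build the +/-1 label matrix (rows aligned with setup$rows) whose
# columns are the permuted analyses. For cross-validated specs one
# permutation is applied to all selected trials before folding; for
# cross-modal specs only training labels are permuted and test labels
# stay untouched. Optional `permutations` (list of full permuted label
# vectors over setup rows) overrides random generation.
.permutation_matrix <- function(dataset, spec, setup, config, stream,
                                permutations = NULL) {
  trials <- dataset$trials
  labels <- setup$labels
  groups <- interaction(trials$modality[setup$rows],
                        trials$block[setup$rows], drop = TRUE)
  perm_rows <- if (spec$cv == "leave_one_block_out") {
    seq_along(setup$rows)
  } else {
    setup$folds[[1]]$train
  }
  cls <- setup$classes
  if (is.null(permutations)) {
    permutations <- with_substream(config$seed, stream, {
      lapply(seq_len(config$n_perm), function(i)
        .permute_labels(labels, groups, perm_rows,
                        config$permutation_unit))
    })
  }
  Y <- vapply(permutations, function(lab) {
    stopifnot(length(lab) == length(labels),
              identical(sort(lab[perm_rows]),
                        sort(labels[perm_rows])))
    ifelse(lab == cls[2], 1L, -1L)
  }, integer(length(labels)))
  matrix(Y, nrow = length(labels))
}

#' Subject-level permutation null accuracies
#'
#' Re-runs the full decoding analysis under label permutations that
#' respect the design: emotion labels are shuffled within block within
#' modality, so CV fold membership and class balance are preserved; for
#' cross-modal specs only the training labels are permuted. Deterministic
#' given `(config$seed, stream)`.
#'
#' @param dataset a `subject_dataset`.
#' @param mask a `voxel_mask` defining the features.
#' @param spec a `decoding_spec` (scaling `"none"` on this fast path).
#' @param config an [inference_config()].
#' @param stream RNG substream index (give each subject its own).
#' @param permutations optional list of permuted label vectors (aligned
#'   with the selected trials) overriding random generation — e.g. the
#'   identity permutation reproduces the observed accuracy exactly.
#' @return numeric vector of `n_perm` mean accuracies (percent).
#' @export
subject_null <- function(dataset, mask, spec, config = inference_config(),
                         stream = 0L, permutations = NULL) {
  stopifnot(inherits(config, "inference_config"))
  if (spec$classifier$scaling != "none")
    stop("permutation fast path supports scaling = 'none'")
  setup <- .fold_setup(dataset, spec)
  Y <- .permutation_matrix(dataset, spec, setup, config, stream,
                           permutations)
  X <- extract_features(dataset, mask)[setup$rows, , drop = FALSE]
  fr <- .fold_fracs(X, Y, setup$folds, spec$classifier$C)
  100 * apply(fr, 2, mean)
}

#' Group-level bootstrap p value from subject permutation accuracies
#'
#' Builds `n_draws` null group means by drawing, per subject and with
#' replacement, one of that subject's permutation accuracies, and tests
#' the observed group mean right-tailed against them. Add-one smoothing
#' keeps p strictly positive:
#' `p = (1 + #draws >= observed) / (n_draws + 1)`. Ties are compared
#' with a small numeric tolerance so equal accuracies count as ties
#' regardless of floating-point summation order.
#'
#' @param observed_mean observed group-mean accuracy (percent).
#' @param perm_matrix subjects x n_perm matrix of permutation accuracies.
#' @param config an [inference_config()].
#' @param stream RNG substream index for the bootstrap draws.
#' @return a `group_result`: `list(observed, p, q, significant, n_draws)`
#'   (`q` is `NA` here; it is filled by [fdr_correct()] for map
#'   families).
#' @export
group_bootstrap_p <- function(observed_mean, perm_matrix,
                              config = inference_config(),
                              stream = .STREAM_BOOT) {
  if (!is.matrix(perm_matrix) || nrow(perm_matrix) < 1 ||
      ncol(perm_matrix) < 1)
    stop("perm_matrix must be a non-empty subjects x n_perm matrix")
  if (!all(is.finite(perm_matrix))) stop("perm_matrix must be finite")
  ns <- nrow(perm_matrix)
  nd <- config$n_draws
  draw_means <- with_substream(config$seed, stream, {
    idx <- matrix(sample.int(ncol(perm_matrix), ns * nd, replace = TRUE),
                  ns, nd)
    .bootstrap_means(perm_matrix, idx)
  })
  p <- (1 + sum(draw_means >= observed_mean - 1e-9)) / (nd + 1)
  structure(list(observed = observed_mean, p = p, q = NA_real_,
                 significant = p <= config$alpha, n_draws = nd,
                 n_subjects = ns),
            class = "group_result")
}

.bootstrap_means <- function(perm_matrix, idx) {
  ns <- nrow(idx)
  vals <- matrix(perm_matrix[cbind(rep(seq_len(ns), ncol(idx)),
                                   as.vector(idx))], ns, ncol(idx))
  colMeans(vals)
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> observed %.1f%%, p = %.4g%s (%d subjects, %d draws)\n",
              x$observed, x$p,
              if (x$significant) " *" else "", x$n_subjects, x$n_draws))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction over a voxel family
#'
#' Step-up adjustment of per-voxel p values; `q` values are monotone in
#' p and invariant to voxel ordering.
#'
#' @param p numeric vector of p values in (0, 1] over in-mask voxels.
#' @param alpha FDR level (default 0.05).
#' @return `list(q =, significant =)` aligned with `p`.
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (length(p) == 0) stop("empty p-value family")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p values must be finite and in (0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' ROI-level two-step group test for one analysis
#'
#' Decodes every subject, generates each subject's permutation null, and
#' evaluates the group-mean accuracy with the bootstrap test. ROI-level
#' results use the uncorrected permutation p at `alpha`.
#'
#' @param cohort list of `subject_dataset`s.
#' @param mask a `voxel_mask` (the ROI).
#' @param spec a `decoding_spec`.
#' @param config an [inference_config()].
#' @return a `roi_result`: group result plus per-subject accuracies,
#'   AUCs and the permutation matrix.
#' @export
roi_group_test <- function(cohort, mask, spec,
                           config = inference_config()) {
  stopifnot(length(cohort) >= 1)
  res <- lapply(cohort, decode, mask = mask, spec = spec)
  acc <- vapply(res, `[[`, numeric(1), "mean_accuracy")
  auc <- vapply(res, `[[`, numeric(1), "auc")
  perm <- t(vapply(seq_along(cohort), function(i)
    subject_null(cohort[[i]], mask, spec, config,
                 stream = .stream_perm(i)),
    numeric(config$n_perm)))
  grp <- group_bootstrap_p(mean(acc), perm, config)
  structure(list(group = grp, subject_accuracies = acc,
                 subject_aucs = auc, mean_auc = mean(auc),
                 perm_matrix = perm, spec = spec,
                 mask_name = mask$name),
            class = "roi_result")
}

#' Replication-overlap configuration
#'
#' @param accuracy_threshold group-mean accuracy cut-off in percent
#'   (default 60; must lie in (50, 100\]).
#' @param require_significance require voxels to also be FDR-significant
#'   in each cohort (default TRUE); threshold-only mode sets this FALSE.
#' @return a `replication_config`.
#' @export
replication_config <- function(accuracy_threshold = 60,
                               require_significance = TRUE) {
  stopifnot(accuracy_threshold > 50, accuracy_threshold <= 100)
  structure(list(accuracy_threshold = accuracy_threshold,
                 require_significance = isTRUE(require_significance)),
            class = "replication_config")
}

#' Replication-overlap map of two cohorts
#'
#' Voxelwise conjunction of per-cohort criteria: group-mean accuracy at
#' or above the threshold and, when required, FDR significance. The
#' result is binary (1 = replicated) with NaN outside the common mask.
#' Symmetric in its two arguments.
#'
#' @param map_a,map_b group `accuracy_map`s on identical grids. If
#'   `require_significance`, each must carry a logical `significant`
#'   grid (as attached by [group_map_inference()]).
#' @param config a [replication_config()].
#' @return a `replication_map`: `list(grid, mask, n_replicated)`.
#' @export
replication_overlap <- function(map_a, map_b,
                                config = replication_config()) {
  stopifnot(inherits(map_a, "accuracy_map"),
            inherits(map_b, "accuracy_map"))
  if (!identical(dim(map_a$grid), dim(map_b$grid)))
    stop("grid mismatch between cohort maps")
  crit <- function(m) {
    ok <- m$mask$grid & !is.na(m$grid) &
      m$grid >= config$accuracy_threshold
    if (config$require_significance) {
      if (is.null(m$significant))
        stop("require_significance: map lacks a significance grid")
      ok <- ok & m$significant
    }
    ok
  }
  common <- map_a$mask$grid & map_b$mask$grid
  rep_grid <- array(NaN, dim(map_a$grid))
  rep_grid[common] <- as.numeric((crit(map_a) & crit(map_b))[common])
  structure(list(grid = rep_grid,
                 mask = voxel_mask("replication", common,
                                   space = map_a$mask$space),
                 n_replicated = sum(rep_grid[common] == 1),
                 config = config),
            class = "replication_map")
}

#' Voxelwise two-step group inference on searchlight maps
#'
#' Computes the group-mean map, then for each voxel tests the observed
#' group mean against bootstrap draws of the subjects' permutation
#' accuracies. Per draw one permutation index is chosen per subject and
#' reused across all voxels, preserving the spatial structure of the
#' null maps; p values are then BH-FDR corrected over the in-mask
#' family.
#'
#' @param maps list of per-subject `accuracy_map`s.
#' @param null_maps list of matrices from [searchlight_null_maps()],
#'   aligned with `maps`.
#' @param config an [inference_config()].
#' @return the group `accuracy_map` with extra fields `p`, `q`
#'   (3D arrays, NaN outside mask) and `significant` (logical grid).
#' @export
group_map_inference <- function(maps, null_maps,
                                config = inference_config()) {
  stopifnot(length(maps) == length(null_maps), length(maps) >= 1)
  grp <- group_mean_map(maps)
  centers <- which(grp$mask$grid)
  ns <- length(maps)
  nd <- config$n_draws
  obs <- grp$grid[centers]
  # per-subject accuracy matrices restricted to the common centres
  nm <- lapply(seq_len(ns), function(i) {
    ctr_i <- attr(null_maps[[i]], "centers")
    m <- null_maps[[i]][match(centers, ctr_i), , drop = FALSE]
    if (anyNA(m)) stop("null maps do not cover the group mask")
    m
  })
  n_perm <- ncol(nm[[1]])
  p <- with_substream(config$seed, .STREAM_BOOT, {
    idx <- matrix(sample.int(n_perm, ns * nd, replace = TRUE), ns, nd)
    exceed <- numeric(length(centers))
    for (dr in seq_len(nd)) {
      dm <- Reduce(`+`, lapply(seq_len(ns),
                               function(i) nm[[i]][, idx[i, dr]])) / ns
      exceed <- exceed + (dm >= obs - 1e-9)
    }
    (1 + exceed) / (nd + 1)
  })
  fdr <- fdr_correct(p, config$alpha)
  pm <- array(NaN, dim(grp$grid)); pm[centers] <- p
  qm <- array(NaN, dim(grp$grid)); qm[centers] <- fdr$q
  sg <- array(FALSE, dim(grp$grid)); sg[centers] <- fdr$significant
  grp$p <- pm
  grp$q <- qm
  grp$significant <- sg
  grp$provenance$inference <- config
  grp
}
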