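#' Trial selection predicate
#'
#' A conjunction of column filters applied to a trial table; `NULL`
#' fields are unconstrained.
#'
#' @param modality character vector of modalities to keep, or `NULL`.
#' @param emotion character vector of emotions to keep, or `NULL`.
#' @param block integer vector of blocks to keep, or `NULL`.
#' @return a `trial_selection`.
#' @export
trial_selection <- function(modality = NULL, emotion = NULL, block = NULL) {
  structure(list(modality = modality, emotion = emotion, block = block),
            class = "trial_selection")
}

#' Row indices of a selection in a trial table
#' @param trials a `trial_table`.
#' @param selection a `trial_selection`.
#' @return integer row indices (acquisition order).
#' @export
select_trials <- function(trials, selection) {
  stopifnot(inherits(selection, "trial_selection"))
  keep <- rep(TRUE, nrow(trials))
  for (col in c("modality", "emotion", "block")) {
    if (!is.null(selection[[col]]))
      keep <- keep & trials[[col]] %in% selection[[col]]
  }
  which(keep)
}

#' Decoding specification
#'
#' What to decode and how: the label column (`"emotion"` for the main
#' fear-vs-anger analyses, `"modality"` for pairwise modality
#' classification), train/test trial selections, and the validation
#' scheme. `cv = "leave_one_block_out"` requires identical train and
#' test selections (each fold holds out one block); `cv = "none"` is the
#' directional cross-modal case and requires disjoint train and test
#' selections, which is enforced at decode time as a leakage guard.
#'
#' @param label_column `"emotion"` or `"modality"`.
#' @param train a `trial_selection` for the training trials.
#' @param test a `trial_selection` for the test trials; defaults to
#'   `train` (required for cross-validated specs).
#' @param cv `"leave_one_block_out"` or `"none"`.
#' @param classifier a [classifier_spec()].
#' @param name optional analysis label carried into outputs.
#' @return a `decoding_spec`.
#' @export
decoding_spec <- function(label_column = c("emotion", "modality"),
                          train, test = train,
                          cv = c("leave_one_block_out", "none"),
                          classifier = classifier_spec(),
                          name = NULL) {
  label_column <- match.arg(label_column)
  cv <- match.arg(cv)
  stopifnot(inherits(train, "trial_selection"),
            inherits(test, "trial_selection"),
            inherits(classifier, "classifier_spec"))
  if (cv == "leave_one_block_out" && !identical(unclass(train), unclass(test)))
    stop("leave-one-block-out requires identical train and test selections")
  structure(list(label_column = label_column, train = train, test = test,
                 cv = cv, classifier = classifier, name = name),
            class = "decoding_spec")
}

#' Extract a feature matrix from masked betas
#'
#' Features are the in-mask voxels (intersection of the given mask with
#' the dataset's brain mask) in a fixed canonical order (ascending
#' column-major voxel index), so column order is reproducible regardless
#' of how the mask was built. Rows are selected trials in acquisition
#' order.
#'
#' @param dataset a `subject_dataset`.
#' @param mask a `voxel_mask` of matching dims.
#' @param selection a `trial_selection` (must select >= 1 trial).
#' @return numeric matrix (trials x voxels) with attributes `rows`
#'   (trial-table row indices) and `voxels` (linear voxel indices).
#' @export
extract_features <- function(dataset, mask, selection = trial_selection()) {
  stopifnot(inherits(dataset, "subject_dataset"),
            inherits(mask, "voxel_mask"))
  if (!identical(dim(mask$grid), dim(dataset$brain_mask)))
    stop("grid mismatch: mask dims differ from dataset")
  rows <- select_trials(dataset$trials, selection)
  if (length(rows) == 0) stop("empty selection")
  vox <- which(mask$grid & dataset$brain_mask)
  if (length(vox) == 0) stop("empty mask: no mask voxel inside brain mask")
  d <- dim(dataset$betas)
  flat <- matrix(dataset$betas, prod(d[1:3]), d[4])
  X <- t(flat[vox, rows, drop = FALSE])
  attr(X, "rows") <- rows
  attr(X, "voxels") <- vox
  X
}

#' Leave-one-block-out folds
#'
#' One fold per block in the selection: the fold's test set is that
#' block's trials, its training set all other selected trials. Folds
#' partition the selection.
#'
#' @param trials a `trial_table`.
#' @param selection a `trial_selection`.
#' @return list of folds, each `list(train=, test=)` of trial-table row
#'   indices.
#' @export
leave_one_block_out_folds <- function(trials, selection = trial_selection()) {
  rows <- select_trials(trials, selection)
  if (length(rows) == 0) stop("empty selection")
  blocks <- trials$block[rows]
  ub <- sort(unique(blocks))
  if (length(ub) < 2)
    stop("cannot cross-validate: selection spans a single block")
  lapply(ub, function(b) {
    list(train = rows[blocks != b], test = rows[blocks == b])
  })
}

# Internal decode engine shared by decode(), the searchlight and the
# permutation null: X is (n_used_trials x voxels); labels a character
# vector aligned with X rows; folds indexed into X rows. Returns fold
# fraction-correct for each label column of Y.
.fold_setup <- function(dataset, spec) {
  trials <- dataset$trials
  if (spec$cv == "leave_one_block_out") {
    folds <- leave_one_block_out_folds(trials, spec$train)
    rows <- sort(unique(unlist(lapply(folds, function(f) c(f$train, f$test)))))
  } else {
    tr <- select_trials(trials, spec$train)
    te <- select_trials(trials, spec$test)
    if (length(tr) == 0 || length(te) == 0) stop("empty selection")
    if (length(intersect(tr, te)) > 0)
      stop("train and test selections overlap (leakage guard)")
    folds <- list(list(train = tr, test = te))
    rows <- sort(unique(c(tr, te)))
  }
  # re-index folds relative to `rows`
  pos <- match(seq_len(nrow(trials)), rows)
  rel <- lapply(folds, function(f)
    list(train = pos[f$train], test = pos[f$test]))
  labels <- trials[[spec$label_column]][rows]
  cls <- sort(unique(labels))
  if (length(cls) != 2)
    stop("decoding requires exactly 2 classes, got ",
         length(cls), " (", paste(cls, collapse = ", "), ")")
  for (f in rel) {
    if (length(unique(labels[f$train])) < 2)
      stop("single-class training fold")
  }
  # positive class = alphabetically last ("fear" beats "anger"); ties at
  # decision value 0 go to the alphabetically first class
  list(rows = rows, folds = rel, labels = labels, classes = cls,
       y = ifelse(labels == cls[2], 1L, -1L))
}

.fold_fracs <- function(X, Ymat, folds, C) {
  tr <- lapply(folds, `[[`, "train")
  te <- lapply(folds, `[[`, "test")
  .fold_accuracy_cpp(X, Ymat, tr, te, C, tie_class = -1L)
}

#' Run a binary decoding analysis on one subject
#'
#' Trains a linear max-margin classifier per fold (or once for
#' cross-modal specs), predicts the held-out/test trials, and reports
#' fold accuracies (percent), their mean, and the AUC from decision
#' values pooled across folds (positive class = alphabetically last
#' label, i.e. "fear"). Deterministic given its inputs. A decision value
#' of exactly zero is classified as the alphabetically first class.
#'
#' @param dataset a `subject_dataset`.
#' @param mask a `voxel_mask` defining the feature voxels.
#' @param spec a `decoding_spec`.
#' @return a `decoding_result` with fields `mean_accuracy` (percent),
#'   `fold_accuracies`, `auc`, `n_train`, `n_test`, `decision_values`.
#' @export
decode <- function(dataset, mask, spec) {
  stopifnot(inherits(spec, "decoding_spec"))
  setup <- .fold_setup(dataset, spec)
  Xall <- extract_features(dataset, mask,
                           selection = trial_selection())  # all trials
  X <- Xall[setup$rows, , drop = FALSE]
  C <- spec$classifier$C
  scaling <- spec$classifier$scaling

  if (scaling == "none") {
    fracs <- .fold_fracs(X, matrix(setup$y, ncol = 1), setup$folds, C)[, 1]
  } else {
    fracs <- vapply(setup$folds, function(f) {
      sc <- .scale_train(X, f$train)
      .fold_fracs(sc, matrix(setup$y, ncol = 1), list(f), C)[1, 1]
    }, numeric(1))
  }

  # decision values per fold for the pooled-rank AUC
  dv_list <- lapply(setup$folds, function(f) {
    Xf <- if (scaling == "none") X else .scale_train(X, f$train)
    fit <- .linear_svc_fit_cpp(Xf[f$train, , drop = FALSE],
                               setup$y[f$train], C)
    as.numeric(Xf[f$test, , drop = FALSE] %*% fit$w - fit$rho)
  })
  dvs <- data.frame(
    fold = rep(seq_along(setup$folds),
               vapply(setup$folds, function(f) length(f$test), integer(1))),
    decision_value = unlist(dv_list),
    label = setup$labels[unlist(lapply(setup$folds, `[[`, "test"))],
    stringsAsFactors = FALSE
  )
  auc <- if (nrow(dvs) >= 2 && length(unique(dvs$label)) == 2)
    compute_auc(dvs$decision_value, dvs$label, positive = setup$classes[2])
  else NA_real_

  structure(list(
    mean_accuracy = 100 * mean(fracs),
    fold_accuracies = 100 * fracs,
    auc = auc,
    n_train = vapply(setup$folds, function(f) length(f$train), integer(1)),
    n_test = vapply(setup$folds, function(f) length(f$test), integer(1)),
    decision_values = dvs,
    positive_class = setup$classes[2],
    spec = spec
  ), class = "decoding_result")
}

.scale_train <- function(X, train_idx) {
  mu <- colMeans(X[train_idx, , drop = FALSE])
  s <- apply(X[train_idx, , drop = FALSE], 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(X, 2, mu, `-`), 2, s, `/`)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> mean accuracy %.1f%% (folds: %s), AUC %s\n",
              x$mean_accuracy,
              paste(sprintf("%.0f", x$fold_accuracies), collapse = "/"),
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Area under the ROC curve from decision values
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive-class score exceeds a random negative-class score, with ties
#' credited 0.5. Invariant under strictly increasing transforms of the
#' scores.
#'
#' @param decision_values numeric scores (larger = more positive-class).
#' @param labels class labels aligned with scores (exactly 2 classes).
#' @param positive which label is the positive class; default the
#'   alphabetically last.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(decision_values, labels,
                        positive = sort(unique(labels))[
                          length(unique(labels))]) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) stop("AUC requires exactly 2 classes")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(decision_values, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
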