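test_that("the linear SVC agrees with libsvm on random problems", {
  skip_if_not_installed("e1071")
  set.seed(3, kind = "Mersenne-Twister")
  n_dv_mismatch <- 0; n_pred_mismatch <- 0
  for (r in 1:100) {
    p <- sample(c(5, 20, 60), 1)
    X <- matrix(rnorm(16 * p), 16, p)
    y <- sample(rep(c(-1L, 1L), 8))
    Xt <- matrix(rnorm(6 * p), 6, p)
    fit <- crossmvpa:::.linear_svc_fit_cpp(X, y, 1)
    dv <- as.numeric(Xt %*% fit$w - fit$rho)
    m <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                    scale = FALSE)
    dvs <- attr(predict(m, Xt, decision.values = TRUE), "decision.values")
    ref <- if (colnames(dvs) == "-1/1") -dvs[, 1] else dvs[, 1]
    # libsvm terminates at a KKT gap of 1e-3; its decision values carry
    # that slack scaled by the data, so allow an order of margin
    if (max(abs(dv - ref)) > 1e-2) n_dv_mismatch <- n_dv_mismatch + 1
    if (any(sign(dv) != sign(ref) & pmin(abs(dv), abs(ref)) > 1e-2))
      n_pred_mismatch <- n_pred_mismatch + 1
  }
  expect_equal(n_dv_mismatch, 0)
  expect_equal(n_pred_mismatch, 0)
})

test_that("the solver is deterministic and handles degenerate input", {
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rep(c(-1L, 1L), 6)
  f1 <- crossmvpa:::.linear_svc_fit_cpp(X, y, 1)
  f2 <- crossmvpa:::.linear_svc_fit_cpp(X, y, 1)
  expect_identical(f1, f2)
  # constant features: zero weight vector, zero decision values
  fc <- crossmvpa:::.linear_svc_fit_cpp(matrix(1, 12, 4), y, 1)
  expect_equal(as.numeric(fc$w), rep(0, 4))
  expect_equal(fc$rho, 0)
})

test_that("feature extraction uses canonical voxel order and guards masks", {
  fx <- noiseless_subject()
  ds <- fx$dataset
  X <- extract_features(ds, fx$mask,
                        trial_selection(modality = "execution"))
  expect_equal(dim(X), c(20, sum(fx$mask$grid)))
  expect_equal(attr(X, "rows"),
               which(ds$trials$modality == "execution"))

  # column order is independent of how the mask was assembled
  d <- dim(ds$brain_mask)
  g1 <- array(FALSE, d); g1[1:5] <- TRUE
  g2 <- array(FALSE, d); g2[30:40] <- TRUE
  u1 <- combine_masks(list(voxel_mask("a", g1), voxel_mask("b", g2)), "u")
  u2 <- combine_masks(list(voxel_mask("b", g2), voxel_mask("a", g1)), "u")
  expect_identical(extract_features(ds, u1), extract_features(ds, u2))

  expect_error(extract_features(ds, fx$mask,
                                trial_selection(block = 99)),
               "empty selection")
  brain <- ds; brain$brain_mask[] <- FALSE; brain$brain_mask[1] <- TRUE
  outside <- array(FALSE, d); outside[d[1] * d[2] * d[3]] <- TRUE
  expect_error(extract_features(brain, voxel_mask("o", outside)),
               "empty mask")
})

test_that("leave-one-block-out folds partition the selection", {
  tt <- make_design("study1")
  sel <- trial_selection(modality = "execution")
  folds <- leave_one_block_out_folds(tt, sel)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$train, 16)
    expect_length(f$test, 4)
    expect_length(intersect(f$train, f$test), 0)
  }
  tests <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(tests, select_trials(tt, sel))

  toy <- trial_table("t", rep("execution", 4),
                     c("fear", "anger", "fear", "anger"), c(1, 1, 2, 2))
  tf <- leave_one_block_out_folds(toy)
  expect_length(tf, 2)
  expect_equal(lengths(lapply(tf, `[[`, "test")), c(2L, 2L))

  expect_error(leave_one_block_out_folds(tt, trial_selection(block = 1)),
               "cannot cross-validate")
})

test_that("decode recovers a noiseless pattern perfectly within modality", {
  fx <- noiseless_subject()
  r <- decode(fx$dataset, fx$mask,
              default_analysis_matrix()$within_execution)
  expect_equal(r$mean_accuracy, 100)
  expect_equal(r$auc, 1)
  expect_length(r$fold_accuracies, 5)
  expect_equal(r$mean_accuracy, mean(r$fold_accuracies))
  expect_equal(r$n_train, rep(16L, 5))
  expect_equal(r$n_test, rep(4L, 5))
})

test_that("sign-swapped test patterns give zero cross-modal accuracy", {
  w <- c(2, -1, 0.5, 1, -2, 0.3, 1.1, -0.7)
  fx <- exact_pattern_dataset(list(execution = w, imitation = -w),
                              roi = default_roi(c(6, 6, 6), n = 8))
  r <- decode(fx$dataset, fx$mask,
              default_analysis_matrix()$train_execution_test_imitation)
  expect_equal(r$mean_accuracy, 0)
  expect_equal(r$auc, 0)
})

test_that("swapping test labels maps accuracy and AUC to their complements", {
  # fixed classifier, relabelled balanced test set: a -> 100 - a, u -> 1 - u
  coh <- small_cohort()
  ds <- coh[[1]]
  spec <- default_analysis_matrix()$train_execution_test_imitation
  r <- decode(ds, small_mask(), spec)
  flipped <- ds
  test_rows <- ds$trials$modality == "imitation"
  flipped$trials$emotion[test_rows] <-
    ifelse(ds$trials$emotion[test_rows] == "fear", "anger", "fear")
  rf <- decode(flipped, small_mask(), spec)
  expect_equal(rf$mean_accuracy, 100 - r$mean_accuracy)
  expect_equal(rf$auc, 1 - r$auc)

  # retraining after a global swap is symmetric: accuracy is unchanged
  swapped <- ds
  swapped$trials$emotion <- ifelse(ds$trials$emotion == "fear",
                                   "anger", "fear")
  expect_equal(decode(swapped, small_mask(), spec)$mean_accuracy,
               r$mean_accuracy)
})

test_that("randomly relabelled null data decodes at chance on average", {
  cfg <- synthetic_config(grid_dims = c(6, 6, 6), n_subjects = 1,
                          effect_amplitude = 0, seed = 8)
  ds <- generate_subject(cfg, 1)
  mask <- roi_masks_from_config(cfg)[[1]]
  spec <- default_analysis_matrix()$within_imitation
  accs <- vapply(1:200, function(s) {
    shuffled <- ds
    rows <- which(ds$trials$modality == "imitation")
    set.seed(s)
    # shuffle within block to keep the design invariant valid
    for (b in unique(ds$trials$block[rows])) {
      idx <- rows[ds$trials$block[rows] == b]
      shuffled$trials$emotion[idx] <- sample(ds$trials$emotion[idx])
    }
    decode(shuffled, mask, spec)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 2)
})

test_that("decoding guards against leakage and degenerate folds", {
  fx <- noiseless_subject()
  expect_error(
    decoding_spec("emotion", trial_selection(modality = "execution"),
                  test = trial_selection(modality = "imitation"),
                  cv = "leave_one_block_out"),
    "identical train and test")
  overlap <- decoding_spec("emotion",
                           trial_selection(modality = "execution"),
                           test = trial_selection(block = 1:5),
                           cv = "none")
  expect_error(decode(fx$dataset, fx$mask, overlap), "overlap")
})

test_that("pairwise modality classification runs through the same engine", {
  coh <- small_cohort()
  spec <- decoding_spec(
    "modality",
    trial_selection(modality = c("execution", "observation")),
    cv = "leave_one_block_out")
  r <- decode(coh[[1]], small_mask(), spec)
  expect_true(r$mean_accuracy >= 0 && r$mean_accuracy <= 100)
  expect_length(r$fold_accuracies, 5)

  # a modality-specific mean offset makes the pair perfectly separable
  ds <- coh[[1]]
  vox <- which(small_mask()$grid)
  d <- dim(ds$betas)
  flat <- matrix(ds$betas, prod(d[1:3]), d[4])
  exec_rows <- which(ds$trials$modality == "execution")
  flat[vox[1], exec_rows] <- flat[vox[1], exec_rows] + 10
  ds$betas <- array(flat, d)
  expect_equal(decode(ds, small_mask(), spec)$mean_accuracy, 100)
})

test_that("AUC follows the rank statistic with ties credited one half", {
  expect_equal(compute_auc(c(1, 2, 3, 10), c("anger", "anger", "fear", "fear")), 1)
  expect_equal(compute_auc(c(0.2, 0.8, 0.5, 0.5),
                           c("fear", "fear", "anger", "anger")), 0.5)
  # invariance under strictly increasing transforms
  dv <- rnorm(20); lab <- sample(rep(c("fear", "anger"), 10))
  expect_equal(compute_auc(exp(dv) + 3, lab), compute_auc(dv, lab))
  # complement under label swap
  swapped <- ifelse(lab == "fear", "anger", "fear")
  expect_equal(compute_auc(dv, swapped), 1 - compute_auc(dv, lab))
  expect_error(compute_auc(1:3, c("fear", "fear", "fear")), "2 classes")
})

test_that("train-fitted z-scoring is available and recorded", {
  coh <- small_cohort()
  spec <- decoding_spec(
    "emotion", trial_selection(modality = "execution"),
    cv = "leave_one_block_out",
    classifier = classifier_spec(scaling = "zscore_train"))
  r <- decode(coh[[1]], small_mask(), spec)
  expect_true(r$mean_accuracy >= 0 && r$mean_accuracy <= 100)
  expect_equal(r$spec$classifier$scaling, "zscore_train")
})
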