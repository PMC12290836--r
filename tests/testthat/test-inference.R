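# exact enumeration oracle for the bootstrap null of the group mean:
# every combination of one permutation value per subject is equiprobable
exact_tail_prob <- function(perm_matrix, observed) {
  grids <- lapply(seq_len(nrow(perm_matrix)), function(i) perm_matrix[i, ])
  combos <- as.matrix(expand.grid(grids))
  mean(rowMeans(combos) >= observed - 1e-9)
}

test_that("the identity permutation reproduces the observed accuracy", {
  coh <- small_cohort()
  mask <- small_mask()
  am <- default_analysis_matrix()
  for (a in c("within_imitation", "train_execution_test_imitation")) {
    spec <- am[[a]]
    obs <- decode(coh[[1]], mask, spec)$mean_accuracy
    setup <- crossmvpa:::.fold_setup(coh[[1]], spec)
    nv <- subject_null(coh[[1]], mask, spec, inference_config(n_perm = 1),
                       permutations = list(setup$labels))
    expect_identical(nv[1], obs)
  }
})

test_that("permutations preserve class balance and respect blocks", {
  coh <- small_cohort()
  spec <- default_analysis_matrix()$within_imitation
  ds <- coh[[1]]
  setup <- crossmvpa:::.fold_setup(ds, spec)
  cfg <- inference_config(n_perm = 25, seed = 3)
  Y <- crossmvpa:::.permutation_matrix(ds, spec, setup, cfg, stream = 1)
  expect_equal(dim(Y), c(20, 25))
  blocks <- ds$trials$block[setup$rows]
  for (j in 1:25) {
    for (b in unique(blocks))
      expect_equal(sum(Y[blocks == b, j]), 0)  # 2 fear + 2 anger per block
  }
  # cross-modal: test labels never permuted
  spec2 <- default_analysis_matrix()$train_execution_test_imitation
  setup2 <- crossmvpa:::.fold_setup(ds, spec2)
  Y2 <- crossmvpa:::.permutation_matrix(ds, spec2, setup2, cfg, stream = 1)
  test_rows <- setup2$folds[[1]]$test
  for (j in 1:25) expect_equal(Y2[test_rows, j], setup2$y[test_rows])
})

test_that("a strong planted signal beats all its permutations", {
  coh <- small_cohort()
  mask <- small_mask()
  spec <- default_analysis_matrix()$within_execution
  cfg <- inference_config(n_perm = 100, seed = 7)
  obs <- decode(coh[[1]], mask, spec)$mean_accuracy
  nv <- subject_null(coh[[1]], mask, spec, cfg, stream = 1)
  expect_length(nv, 100)
  expect_true(all(nv < obs))
})

test_that("bootstrap p values hit their closed-form extremes", {
  cfg <- inference_config(n_perm = 4, n_draws = 5000, seed = 1)
  pm <- matrix(c(40, 45, 48, 49, 42, 44, 46, 47), 2, 4, byrow = TRUE)
  r <- group_bootstrap_p(60, pm, cfg)
  expect_equal(r$p, 1 / (cfg$n_draws + 1))
  expect_true(r$significant)

  pm_tie <- matrix(55, 3, 4)
  r2 <- group_bootstrap_p(55, pm_tie, cfg)
  expect_equal(r2$p, 1)
  expect_false(r2$significant)

  expect_error(group_bootstrap_p(50, matrix(numeric(0), 0, 0), cfg),
               "non-empty")
})

test_that("bootstrap p agrees with exact enumeration on small instances", {
  cfg <- inference_config(n_perm = 2, n_draws = 2e4, seed = 5)
  cases <- list(
    list(pm = matrix(c(40, 60, 40, 60), 2, 2, byrow = TRUE), obs = 60),
    list(pm = matrix(c(45, 55, 50, 50, 40, 60), 3, 2, byrow = TRUE),
         obs = 52),
    list(pm = matrix(c(48, 52, 49, 51, 50, 50, 47, 53), 4, 2,
                     byrow = TRUE), obs = 50.5)
  )
  for (cs in cases) {
    q <- exact_tail_prob(cs$pm, cs$obs)
    expected_p <- (1 + cfg$n_draws * q) / (cfg$n_draws + 1)
    se <- sqrt(q * (1 - q) / cfg$n_draws)
    r <- group_bootstrap_p(cs$obs, cs$pm, cfg)
    expect_lt(abs(r$p - expected_p), 3 * se + 1e-12)
  }
  # the documented small instance: draw means {40,50,50,60}, p ~ 0.25
  r <- group_bootstrap_p(60, matrix(c(40, 60, 40, 60), 2, 2, byrow = TRUE),
                         cfg)
  expect_lt(abs(r$p - 0.25), 3 * sqrt(0.25 * 0.75 / cfg$n_draws) + 1e-3)
})

test_that("p is monotone decreasing in the observed mean", {
  cfg <- inference_config(n_perm = 10, n_draws = 5000, seed = 9)
  set.seed(4)
  pm <- matrix(50 + rnorm(50, sd = 5), 5, 10)
  ps <- vapply(c(45, 50, 52, 55, 60), function(o)
    group_bootstrap_p(o, pm, cfg)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("null permutation p values are calibrated at the chosen level", {
  spec <- default_analysis_matrix()$within_imitation
  cfg0 <- synthetic_config(grid_dims = c(6, 6, 6), n_subjects = 5,
                           effect_amplitude = 0, seed = 0)
  mask <- roi_masks_from_config(cfg0)[[1]]
  rej <- vapply(1:100, function(k) {
    cfg <- synthetic_config(grid_dims = c(6, 6, 6), n_subjects = 5,
                            effect_amplitude = 0, seed = 3000 + k)
    coh <- generate_cohort(cfg)
    ic <- inference_config(n_perm = 20, n_draws = 2000, seed = 3000 + k)
    roi_group_test(coh, mask, spec, ic)$group$significant
  }, logical(1))
  # 99% binomial band around 0.05 for 100 replicates
  expect_lte(mean(rej), 0.11)
})

test_that("BH correction behaves at its boundary cases and under the null", {
  r1 <- fdr_correct(0.04, alpha = 0.05)
  expect_true(r1$significant)
  r2 <- fdr_correct(rep(0.001, 100), alpha = 0.05)
  expect_true(all(r2$significant))
  # q monotone in p and order-invariant
  set.seed(6)
  p <- runif(50)
  q <- fdr_correct(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  perm <- sample(50)
  expect_equal(fdr_correct(p[perm])$q, q[perm])
  # under a global null, any-rejection rate stays near alpha
  any_rej <- vapply(1:500, function(k) {
    set.seed(k)
    any(fdr_correct(runif(100))$significant)
  }, logical(1))
  expect_lte(mean(any_rej), 0.08)
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("replication overlap is a symmetric thresholded conjunction", {
  d <- c(6, 6, 6)
  mk_map <- function(vals_at, sig_at = NULL) {
    g <- array(45, d)
    g[vals_at] <- 75
    m <- structure(list(grid = g,
                        mask = voxel_mask("m", array(TRUE, d)),
                        provenance = list()),
                   class = "accuracy_map")
    if (!is.null(sig_at)) {
      s <- array(FALSE, d); s[sig_at] <- TRUE
      m$significant <- s
    }
    m
  }
  a <- mk_map(1:10)
  b <- mk_map(6:15)
  cfg <- replication_config(require_significance = FALSE)
  ov <- replication_overlap(a, b, cfg)
  expect_equal(which(ov$grid == 1), 6:10)
  expect_equal(ov$n_replicated, 5)
  # symmetry and idempotence
  ov2 <- replication_overlap(b, a, cfg)
  expect_equal(ov$grid, ov2$grid)
  self <- replication_overlap(a, a, cfg)
  expect_equal(which(self$grid == 1), which(a$grid >= 60))
  # disjoint supra-threshold sets
  expect_equal(replication_overlap(mk_map(1:5), mk_map(20:25),
                                   cfg)$n_replicated, 0)
  # significance requirement gates the conjunction
  as <- mk_map(1:10, sig_at = 1:8)
  bs <- mk_map(6:15, sig_at = 6:15)
  ovs <- replication_overlap(as, bs, replication_config())
  expect_equal(which(ovs$grid == 1), 6:8)
  expect_error(replication_overlap(a, bs, replication_config()),
               "lacks a significance grid")
  # geometry guard
  small <- mk_map(1:3)
  small$grid <- array(45, c(5, 5, 5))
  expect_error(replication_overlap(a, small, cfg), "grid mismatch")
  expect_error(replication_config(accuracy_threshold = 50))
})

test_that("voxelwise two-step inference flags the planted region", {
  cfg <- synthetic_config(grid_dims = c(7, 7, 7), n_subjects = 8,
                          roi_specs = list(default_roi(c(7, 7, 7), n = 8)),
                          seed = 41)
  coh <- generate_cohort(cfg)
  spec <- default_analysis_matrix()$within_imitation
  sph <- sphere_offsets(2)
  brain <- voxel_mask("brain", coh[[1]]$brain_mask)
  ic <- inference_config(n_perm = 30, n_draws = 2000, seed = 41)
  maps <- lapply(coh, searchlight_map, analysis_mask = brain, spec = spec,
                 sphere = sph)
  nulls <- lapply(seq_along(coh), function(i)
    searchlight_null_maps(coh[[i]], brain, spec, sph, ic,
                          stream = crossmvpa:::.stream_perm(i)))
  gm <- group_map_inference(maps, nulls, ic)
  roi <- array(FALSE, cfg$grid_dims)
  roi[cfg$roi_specs[[1]]$voxels] <- TRUE
  expect_true(mean(gm$significant[roi]) >= 0.8)
  expect_true(all(gm$q[gm$mask$grid] >= gm$p[gm$mask$grid] - 1e-12))
})
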