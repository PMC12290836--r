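#' The standard 7-analysis decoding matrix
#'
#' Emotion decoding within each experimental modality (leave-one-block-
#' out CV) plus the four directional cross-modal analyses. Training is
#' restricted to execution and observation — imitation, being a compound
#' of both subprocesses, is only ever a test set.
#'
#' @param classifier a [classifier_spec()].
#' @return named list of `decoding_spec`s.
#' @export
default_analysis_matrix <- function(classifier = classifier_spec()) {
  within <- function(m) decoding_spec(
    "emotion", trial_selection(modality = m), cv = "leave_one_block_out",
    classifier = classifier, name = paste0("within_", m))
  cross <- function(tr, te) decoding_spec(
    "emotion", trial_selection(modality = tr),
    test = trial_selection(modality = te), cv = "none",
    classifier = classifier, name = paste0("train_", tr, "_test_", te))
  list(
    within_execution = within("execution"),
    within_observation = within("observation"),
    within_imitation = within("imitation"),
    train_execution_test_imitation = cross("execution", "imitation"),
    train_execution_test_observation = cross("execution", "observation"),
    train_observation_test_imitation = cross("observation", "imitation"),
    train_observation_test_execution = cross("observation", "execution")
  )
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: cohorts (synthetic
#' configs or on-disk data), the analysis matrix, ROI masks, optional
#' searchlight and replication stages, and the inference settings. All
#' randomness derives from the cohort/inference seeds, so a rerun is
#' bit-identical.
#'
#' @param cohorts named list; each element a `synthetic_config` or a
#'   list of `subject_dataset`s.
#' @param analyses named list of `decoding_spec`s; default
#'   [default_analysis_matrix()].
#' @param rois named list of `voxel_mask`s, or `NULL` to derive the
#'   planted-ROI masks from each synthetic cohort config.
#' @param inference an [inference_config()].
#' @param searchlight `NULL` (off) or a list with optional fields
#'   `radius` (default 3), `analyses` (names into `analyses`, default
#'   the within-modality ones), `inference` (logical; voxelwise two-step
#'   inference, default `FALSE`).
#' @param replication `NULL` (off) or a list with `pairs` (list of
#'   2-vectors of cohort names) and `config` (a [replication_config()]).
#' @param output_dir where to write tables/maps/manifest, or `NULL` to
#'   skip writing.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(cohorts,
                              analyses = default_analysis_matrix(),
                              rois = NULL,
                              inference = inference_config(),
                              searchlight = NULL,
                              replication = NULL,
                              output_dir = NULL) {
  stopifnot(length(cohorts) >= 1, !is.null(names(cohorts)),
            all(nzchar(names(cohorts))))
  if (anyDuplicated(names(analyses)))
    stop("analysis names must be unique")
  if (!is.null(replication)) {
    for (p in replication$pairs)
      if (!all(p %in% names(cohorts)))
        stop("replication pair references undeclared cohort: ",
             paste(p, collapse = ", "))
    if (is.null(replication$config))
      replication$config <- replication_config()
  }
  structure(list(cohorts = cohorts, analyses = analyses, rois = rois,
                 inference = inference, searchlight = searchlight,
                 replication = replication, output_dir = output_dir),
            class = "experiment_config")
}

.resolve_cohort <- function(x) {
  if (inherits(x, "synthetic_config")) generate_cohort(x)
  else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                    "subject_dataset"))) x
  else stop("cohort must be a synthetic_config or list of subject_datasets")
}

.analysis_valid_for <- function(spec, trials) {
  sel_ok <- function(sel) length(select_trials(trials, sel)) > 0
  sel_ok(spec$train) && sel_ok(spec$test)
}

#' Run the full experiment
#'
#' For every cohort: per-subject decoding of every (ROI x analysis)
#' cell, ROI-level two-step permutation inference, optional searchlight
#' maps (per-subject, group mean, optional voxelwise inference), and
#' replication-overlap maps for the configured cohort pairs. Analyses
#' whose selections are empty in a cohort's design (e.g. cross-modal
#' analyses in the two-condition design) are skipped with a note.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress (default TRUE).
#' @return an `experiment_bundle`: `list(table, roi_results, maps,
#'   group_maps, replication, manifest)`. If `config$output_dir` is set,
#'   the table (TSV), maps (NIfTI) and manifest (JSON-like YAML) are
#'   also written there.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  rows <- list()
  roi_results <- list()
  group_maps <- list()
  subj_maps <- list()

  for (cname in names(config$cohorts)) {
    cohort <- .resolve_cohort(config$cohorts[[cname]])
    say("[%s] cohort of %d subjects", cname, length(cohort))
    rois <- config$rois
    if (is.null(rois)) {
      cc <- config$cohorts[[cname]]
      if (!inherits(cc, "synthetic_config"))
        stop("rois = NULL requires synthetic cohorts")
      rois <- roi_masks_from_config(cc)
    }
    trials1 <- cohort[[1]]$trials
    for (aname in names(config$analyses)) {
      spec <- config$analyses[[aname]]
      if (!.analysis_valid_for(spec, trials1)) {
        say("[%s] %s: skipped (selection empty in this design)",
            cname, aname)
        next
      }
      for (rname in names(rois)) {
        rr <- roi_group_test(cohort, rois[[rname]], spec,
                             config$inference)
        roi_results[[paste(cname, rname, aname, sep = "|")]] <- rr
        imb <- any(vapply(seq_along(cohort), function(i) {
          su <- .fold_setup(cohort[[i]], spec)
          any(vapply(su$folds, function(f)
            abs(mean(su$y[f$train]) ) > 1e-12, logical(1)))
        }, logical(1)))
        if (imb) warning("class-imbalanced training fold in ",
                         cname, "/", aname)
        rows[[length(rows) + 1]] <- data.frame(
          cohort = cname, roi = rname, analysis = aname,
          accuracy = rr$group$observed, auc = rr$mean_auc,
          p = rr$group$p, q = NA_real_,
          significant = rr$group$significant,
          n_subjects = length(cohort), stringsAsFactors = FALSE)
        say("[%s] %s / %s: %.1f%% (p = %.4g%s)", cname, rname, aname,
            rr$group$observed, rr$group$p,
            if (rr$group$significant) ", significant" else "")
      }
    }

    if (!is.null(config$searchlight)) {
      sl <- config$searchlight
      radius <- if (is.null(sl$radius)) 3 else sl$radius
      sphere <- sphere_offsets(radius)
      amask <- if (!is.null(sl$analysis_mask)) sl$analysis_mask
               else voxel_mask("brain", cohort[[1]]$brain_mask)
      sl_analyses <- if (!is.null(sl$analyses)) sl$analyses
                     else grep("^within_", names(config$analyses),
                               value = TRUE)
      for (aname in sl_analyses) {
        spec <- config$analyses[[aname]]
        if (!.analysis_valid_for(spec, trials1)) next
        say("[%s] searchlight %s (radius %g)", cname, aname, radius)
        maps <- lapply(cohort, searchlight_map, analysis_mask = amask,
                       spec = spec, sphere = sphere)
        subj_maps[[paste(cname, aname, sep = "|")]] <- maps
        if (isTRUE(sl$inference)) {
          nulls <- lapply(seq_along(cohort), function(i)
            searchlight_null_maps(cohort[[i]], amask, spec, sphere,
                                  config$inference,
                                  stream = .stream_perm(i)))
          gm <- group_map_inference(maps, nulls, config$inference)
        } else {
          gm <- group_mean_map(maps)
        }
        group_maps[[paste(cname, aname, sep = "|")]] <- gm
      }
    }
  }

  replication <- list()
  if (!is.null(config$replication)) {
    for (p in config$replication$pairs) {
      for (key_a in names(group_maps)) {
        if (!startsWith(key_a, paste0(p[1], "|"))) next
        aname <- sub("^[^|]*\\|", "", key_a)
        key_b <- paste(p[2], aname, sep = "|")
        if (!key_b %in% names(group_maps)) next
        ov <- replication_overlap(group_maps[[key_a]],
                                  group_maps[[key_b]],
                                  config$replication$config)
        replication[[paste(p[1], p[2], aname, sep = "|")]] <- ov
        say("replication %s vs %s (%s): %d voxels", p[1], p[2], aname,
            ov$n_replicated)
      }
    }
  }

  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cohort = character(), roi = character(),
               analysis = character(), accuracy = numeric(),
               auc = numeric(), p = numeric(), q = numeric(),
               significant = logical(), n_subjects = integer())
  manifest <- list(
    package_version = as.character(utils::packageVersion("crossmvpa")),
    cohorts = lapply(config$cohorts, function(x)
      if (inherits(x, "synthetic_config")) unclass(x) else
        list(n_subjects = length(x), source = "in-memory")),
    inference = unclass(config$inference),
    analyses = names(config$analyses),
    searchlight = config$searchlight[c("radius", "inference")],
    replication_pairs = config$replication$pairs,
    design_flags = list(
      feature_scaling = config$analyses[[1]]$classifier$scaling,
      sphere_convention = "squared norm strictly below radius^2",
      permutation = config$inference$permutation_unit,
      p_smoothing = "add-one",
      tie_rule = "decision value 0 -> alphabetically first class")
  )
  bundle <- structure(list(table = table, roi_results = roi_results,
                           maps = subj_maps, group_maps = group_maps,
                           replication = replication,
                           manifest = manifest),
                      class = "experiment_bundle")
  if (!is.null(config$output_dir)) .write_bundle(bundle, config)
  bundle
}

.write_bundle <- function(bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_result_table(bundle$table,
                     file.path(config$output_dir, "roi_results.tsv"))
  for (key in names(bundle$group_maps)) {
    gm <- bundle$group_maps[[key]]
    fn <- file.path(config$output_dir,
                    paste0("group_", gsub("[^A-Za-z0-9_.-]", "_", key),
                           ".nii"))
    write_map(gm$grid, gm$mask, fn)
  }
  for (key in names(bundle$replication)) {
    ov <- bundle$replication[[key]]
    fn <- file.path(config$output_dir,
                    paste0("replication_",
                           gsub("[^A-Za-z0-9_.-]", "_", key), ".nii"))
    write_map(ov$grid, ov$mask, fn)
  }
  yaml::write_yaml(bundle$manifest,
                   file.path(config$output_dir, "manifest.yaml"))
  invisible(NULL)
}

#' Summarize an experiment bundle
#'
#' Prints the cohort x ROI x analysis accuracy/AUC table and, for each
#' replication map, its clusters (26-connected components) with sizes
#' and center-of-mass voxel coordinates.
#'
#' @param bundle an `experiment_bundle`.
#' @return invisibly, `list(table, clusters)`.
#' @export
summarize_results <- function(bundle) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  tab <- bundle$table
  cat("== ROI decoding results ==\n")
  print(format(tab, digits = 3), row.names = FALSE)
  clusters <- list()
  for (key in names(bundle$replication)) {
    ov <- bundle$replication[[key]]
    cl <- .connected_components(!is.na(ov$grid) & ov$grid == 1)
    clusters[[key]] <- cl
    cat(sprintf("\n== Replication %s ==\n", key))
    if (nrow(cl) == 0) {
      cat("no replicated voxels\n")
    } else {
      for (i in seq_len(nrow(cl)))
        cat(sprintf("cluster %d: %d voxels, center of mass (%.1f, %.1f, %.1f)\n",
                    i, cl$size[i], cl$x[i], cl$y[i], cl$z[i]))
    }
  }
  invisible(list(table = tab, clusters = clusters))
}

# 26-connectivity connected components of a 3D logical array
.connected_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  res <- list()
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    members <- start
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(v, d)
      nb <- sweep(off, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[mask[lin] & lab[lin] == 0L]
      lab[new] <- nxt
      queue <- c(queue, new)
      members <- c(members, new)
    }
    co <- arrayInd(members, d)
    res[[nxt]] <- data.frame(size = length(members),
                             x = mean(co[, 1]), y = mean(co[, 2]),
                             z = mean(co[, 3]))
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(size = integer(), x = numeric(), y = numeric(),
                  z = numeric())
}

#' Read an experiment configuration from YAML
#'
#' Supports synthetic cohorts: the YAML mirrors [synthetic_config()]
#' fields per cohort plus `inference`, `searchlight` and `replication`
#' blocks.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$cohorts)) stop("config error: no cohorts")
  cohorts <- lapply(y$cohorts, function(cc) {
    args <- cc
    if (!is.null(args$grid_dims)) args$grid_dims <- as.integer(args$grid_dims)
    if (!is.null(args$pattern_sharing))
      args$pattern_sharing <- unlist(args$pattern_sharing)
    if (!is.null(args$roi_specs))
      args$roi_specs <- lapply(args$roi_specs, function(r)
        list(name = r$name, voxels = matrix(unlist(r$voxels), ncol = 3,
                                            byrow = TRUE)))
    do.call(synthetic_config, args)
  })
  inf <- if (is.null(y$inference)) inference_config()
         else do.call(inference_config, y$inference)
  repl <- NULL
  if (!is.null(y$replication)) {
    repl <- list(pairs = y$replication$pairs,
                 config = do.call(replication_config,
                                  y$replication$config %||% list()))
  }
  experiment_config(cohorts = cohorts, inference = inf,
                    searchlight = y$searchlight, replication = repl,
                    output_dir = y$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
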