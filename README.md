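# crossmvpa

Within-subject multivoxel pattern analysis (MVPA) of emotional content,
within and across action modalities, for trial-wise fMRI
parameter-estimate ("beta") volumes — plus a synthetic-data generator
with a planted, known ground truth so the whole pipeline is testable
without access to restricted neuroimaging data.

## The problem

Do execution, observation and imitation of emotional facial expressions
share a neural code for *which* emotion is being expressed? The
multivariate test is cross-modal decoding: a linear classifier trained
to separate fear from anger in one modality is tested on trials of
another. Above-chance transfer implies a common, action-specific
representation. `crossmvpa` implements the full analysis chain:

* **Decoding** — linear soft-margin SVM (fixed `C = 1`, deterministic
  SMO solver), leave-one-block-out cross-validation within a modality,
  directional train/test across modalities; accuracy in percent
  (chance = 50% for the balanced designs) and pooled-rank AUC.
* **Searchlight** — the decoder applied in a sphere around every voxel
  (radius 3 ⇒ 93 voxels per sphere, strict-inequality convention),
  accuracy assigned to the centre; per-subject and group-mean maps.
* **Group inference** — two-step permutation scheme: per subject, 100
  label permutations re-running the full analysis; per group, 10⁵
  bootstrap draws of one permutation accuracy per subject, with the
  observed group mean tested right-tailed
  (`p = (1 + #{draws ≥ observed}) / (n_draws + 1)`); voxelwise BH-FDR
  at α = .05 for searchlight maps.
* **Replication** — voxelwise conjunction of group maps at the ≥ 60%
  accuracy threshold across sessions/samples.
* **Synthetic cohorts** — the paradigm's exact trial economy
  (3 modalities × 5 blocks × 4 trials plus 30 control trials, or the
  two-condition follow-up design) with planted emotion patterns that
  are shared, orthogonal ("distinct") or absent per modality.

Data interfaces are the field's standard formats: NIfTI volumes and
masks, BIDS-style events TSV, TSV result tables, YAML run configs.

## Worked example

```r
library(crossmvpa)

# a 12-subject cohort with a pattern shared by execution and imitation,
# and nothing planted in observation
cfg <- synthetic_config(n_subjects = 12, seed = 7)
cohort <- generate_cohort(cfg)
roi <- roi_masks_from_config(cfg)$planted

# train on execution, test on imitation (no CV needed: disjoint sets)
spec <- default_analysis_matrix()$train_execution_test_imitation
decode(cohort[[1]], roi, spec)
#> <decoding_result> mean accuracy 95.0% (folds: 95), AUC 1.000

# group-level two-step permutation inference
res <- roi_group_test(cohort, roi, spec, inference_config(seed = 7))
res$group
#> <group_result> observed 94.2%, p = 1e-05 * (12 subjects, 100000 draws)
```

The first call trains on the 20 execution trials of subject 1 and
classifies that subject's 20 imitation trials: 19/20 correct (95%),
perfect ranking (AUC 1) — the planted pattern transfers across
modalities because the generator made it shared. The group test
re-runs the decode under 100 within-block label permutations per
subject, bootstraps 10⁵ null group means, and finds none at or above
the observed 94.2%, so p is the smallest value the draw count allows
(1/(10⁵+1)) and the result is flagged significant at α = .05.

The `analysis/` scripts run the full study workflow on synthetic
cohorts — `01_simulate.R` (cohorts + on-disk round trip),
`02_roi_decoding.R` (the 7-analysis × cohort ROI table),
`03_searchlight_maps.R` (group searchlight maps),
`04_group_inference.R` (voxelwise two-step inference + FDR),
`05_replication.R` (cross-cohort overlap maps) — writing their outputs
under `results/`.

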