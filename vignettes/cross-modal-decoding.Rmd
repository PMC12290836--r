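---
title: "Cross-modal decoding of emotional content: models, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal decoding of emotional content: models, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmvpa)
```

## The scientific question

When a person executes, observes or imitates an emotional facial
expression, are the fine-grained neural activity patterns that encode
*which* emotion it is (fear or anger) shared across those action
modalities? A shared code is the multivariate signature of a common,
action-specific representation — the central claim of mirror-neuron
accounts of emotion understanding. The operational test is
**cross-modal decoding**: train a classifier to separate fear from
anger using trials of one modality and test it on trials of another.
Transfer above chance implies a representation common to both.

`crossmvpa` implements this analysis chain end to end for trial-wise
parameter-estimate ("beta") volumes:

1. **Within-modality decoding** — leave-one-block-out cross-validated
   linear SVM classification of emotion within execution, observation
   and imitation.
2. **Cross-modal decoding** — directional train/test between
   modalities, with training restricted to execution and observation
   (imitation, as a compound of both, is only a test set).
3. **Searchlight mapping** — the same decoders run in a sphere around
   every brain voxel, the accuracy assigned to the sphere's centre.
4. **Two-step permutation inference** — subject-level label
   permutations plus group-level bootstrap, with BH-FDR over voxels.
5. **Replication overlap** — conjunction of supra-threshold voxels
   across sessions or samples.

Because the original fMRI recordings are not publicly archivable, the
package ships a synthetic-data generator that reproduces the study's
trial economy with a *known, planted* ground truth, so that every stage
of the pipeline has a recoverable target and testable error rates.

## The decoder

The classifier is a soft-margin linear support-vector machine with the
regularization constant fixed at `C = 1` — the common neuroimaging
default; no hyperparameter search is performed. The dual problem is
solved by a deterministic SMO (maximal-violating-pair) solver with a
tight KKT tolerance (`1e-8`), so a fit is a pure function of its
inputs; the test suite cross-checks decision values against libsvm on
random problems. Features are the in-mask voxels in a canonical
(ascending voxel index) order; betas enter unscaled by default, and an
opt-in train-fitted z-scoring (`classifier_spec(scaling =
"zscore_train")`) is recorded in all outputs. A decision value of
exactly zero — which occurs for degenerate constant features — is
assigned to the alphabetically first class ("anger"), making the
tie-break explicit and deterministic.

Accuracy is the raw fraction correct in percent, averaged over folds.
Every design this package accepts is class-balanced within block, so
raw accuracy equals balanced accuracy and chance is 50%. The AUC is the
rank statistic (ties credited 0.5) on decision values pooled across
folds, with "fear" as the positive class. Pooling before ranking was
chosen over per-fold averaging because four-trial folds make per-fold
ROC estimates extremely coarse; the choice is recorded in the result
object rather than hidden.

## Cross-validation and the leakage guard

Within-modality analyses use leave-one-block-out cross-validation: one
fold per acquisition block, the held-out block never contributes to
training. In the default design that is 5 folds of 16 training and 4
test trials. Cross-modal analyses need no cross-validation — train and
test sets are distinct by construction — and the package *enforces*
disjointness: a `cv = "none"` specification whose train and test
selections share trials is an error, not a warning.

## The searchlight

`sphere_offsets(radius)` enumerates integer offsets with squared norm
*strictly* below `radius^2`. The strict convention is pinned by the
sphere size it implies: radius 3 gives 93 voxels per searchlight (the
non-strict alternative gives 123). At grid and mask edges, spheres are
truncated to in-grid, in-mask voxels rather than dropping the centre —
this keeps full map coverage and matches common toolbox behaviour; the
per-sphere feature count is recorded in the map's provenance. Centres
are mutually independent, so any execution order produces a
bit-identical map; the test suite verifies the map against brute-force
per-centre decoding on a small grid.

## Two-step group inference

Classification accuracy is not normally distributed across subjects,
and a subject's accuracy has its own nontrivial null distribution, so
group inference is non-parametric throughout:

1. **Subject level.** Emotion labels are shuffled within block within
   modality (`n_perm = 100` by default) and the *entire* analysis —
   fold structure included — is re-run per permutation. Shuffling
   within block preserves both the CV fold membership and the class
   balance. For cross-modal analyses only training labels are permuted;
   test labels are facts of the data. For cross-validated analyses one
   permutation is applied to the selected trials before folding (the
   alternative, re-permuting per fold, would break the "same analysis,
   different labels" logic); the scheme is recorded in the run
   manifest. A whole-block label-flip variant is available as
   `permutation_unit = "block_flip"`.
2. **Group level.** `n_draws = 1e5` bootstrap draws each pick one
   permutation accuracy per subject (uniformly, with replacement) and
   average them, giving a null distribution of group means. The
   observed group mean is tested right-tailed:
   `p = (1 + #{draws >= observed}) / (n_draws + 1)`. The add-one
   smoothing keeps p strictly positive from finite draws. Accuracy
   values are discrete, so ties between the observed mean and draw
   means are real events; the comparison uses a small numeric tolerance
   (`1e-9` percent) so equal values count as ties regardless of
   floating-point summation order — ties inflate p, which errs on the
   conservative side.

ROI analyses are reported at the uncorrected permutation p (two ROI
systems; no multiplicity correction is applied at the ROI level), while
searchlight maps are corrected voxelwise with Benjamini–Hochberg FDR at
`alpha = 0.05`. For voxelwise inference the per-draw permutation choice
is made once per subject and reused across all voxels, preserving the
spatial structure of the null maps. The test suite verifies the
rejection rate of the full ROI chain on 400 null cohorts (it sits
inside the 95% binomial interval around 0.05) and checks the bootstrap
p against exhaustive enumeration on small instances.

## Replication overlap

Replication across sessions or samples is defined voxelwise: a voxel
replicates when its group-mean accuracy reaches the threshold (default
60%) in both cohorts. By default the conjunction additionally requires
FDR significance in each cohort (`require_significance = TRUE`);
threshold-only mode is a flag, and is what the bundled analysis scripts
use when voxelwise permutation nulls have not been computed. The
threshold must exceed 50 — an overlap of chance-level voxels measures
nothing.

## The synthetic generator

`synthetic_config()` describes a cohort; `generate_cohort()` builds it.
The design replicates the paradigm's trial economy:

* **study1** — imitation, observation and execution, each 5 blocks of
  4 trials (2 fear + 2 anger per block; 10 + 10 per modality), with
  three 2-trial control blocks interleaved after each cycle (30 control
  trials in 15 blocks). Emotion order is pseudorandomized within block;
  block order is fixed.
* **study2** — imitation and control only, 5 blocks of 4 trials each
  (10 fear, 10 anger per condition).

Each trial's beta volume is `sign(emotion) * A * w_m + noise`, with
`sign(fear) = +1`, `A = effect_amplitude`, and `w_m` the modality's
unit-norm spatial pattern over the ROI voxels: the cohort reference
pattern where `pattern_sharing` says `"shared"`, a pattern
orthogonalized against the reference where `"distinct"`, zero where
`"null"`. Orthogonalization makes cross-decoding of a
shared/distinct pair *exactly* chance in expectation — a clean negative
control. Subjects perturb the cohort patterns with Gaussian jitter
(sd `subject_pattern_jitter`) and re-normalize, so shared modalities
within a subject still carry one common pattern while subjects differ
from one another. Encoding fear/anger as a sign flip of one pattern is
the simplest linearly separable ground truth; an independent-patterns
variant (`emotion_coding = "two_pattern"`) exists for robustness
checks.

Noise is i.i.d. Gaussian over voxels and trials (`noise_sd`), matching
the fact that no spatial smoothing is applied to the beta images; an
optional Gaussian smoothing of the noise field exists but is off by
default. What the generator deliberately does **not** model: BOLD
dynamics and temporal autocorrelation, anatomical structure, spatially
correlated noise, inter-subject anatomical misalignment, and
session-level nonstationarities. Passing tests therefore demonstrate
that the *pipeline* is correct and calibrated — not that real data
would yield any particular accuracy.

### Default parameter choices

| parameter | default | rationale |
|---|---|---|
| `grid_dims` | 20×20×20 voxels | large enough for radius-3 spheres and a background far from the ROI, small enough for fast cohorts |
| ROI | 20 voxels at the grid centre | matches the scale at which a 93-voxel sphere mixes signal and noise voxels |
| `effect_amplitude` / `noise_sd` | 1.0 / 0.5 | no effect-size estimates exist for the original data; this ratio is chosen for test power: within-modality group accuracy lands in the 80–95% range, comfortably away from both chance and ceiling |
| `subject_pattern_jitter` | 0.2 | mild inter-subject pattern variability; keeps within-subject decoding the dominant signal source, as in the within-subject design |
| `n_subjects` | 20 | the scale of the original samples |
| `n_perm`, `n_draws` | 100, 1e5 | the published inference settings |

Deterministic behaviour is part of the contract: every random stage
draws from a named L'Ecuyer-CMRG substream of one master seed (pattern,
design, per-subject noise, per-subject permutations, bootstrap), so
cohorts are reproducible, subjects are order-independent, and partial
re-runs agree with full runs.

## Numerical and degenerate-input policy

* Betas must be finite inside the brain mask; out-of-mask voxels are
  never features and are written as NaN in all maps.
* Decoding requires both classes in every training fold; single-class
  folds, empty selections, empty mask intersections, single-block CV
  selections and mismatched grids are errors with specific messages.
* A constant feature block (e.g. a zero-signal, zero-noise volume)
  yields zero decision values for every test trial; the tie rule then
  classifies everything as "anger", which on balanced test sets gives
  exactly 50% — the correct "no information" answer.
* With fewer than two test trials (or one test class) the AUC is
  reported as `NA` while accuracy is still returned.

## Problem sizes used in the bundled checks

The test suite and the analysis scripts run entirely on synthetic
cohorts sized for quick iteration: ROI analyses use 8–10-voxel-per-side
grids (the ROI decoder only ever sees the masked voxels, so grid size
is immaterial there), searchlight demonstrations use 12³ grids with the
full radius-3 sphere, and the type-I calibration uses 400 null cohorts
of 20 subjects at `n_perm = 50`, `n_draws = 1e4`. The voxelwise
two-step inference demonstration uses reduced permutation counts
(`n_perm = 30`, `n_draws = 5000`) since its cost scales with the number
of mapped voxels. These are the package's chosen demonstration sizes;
all settings scale up by changing the corresponding config fields.

## Known limitations

* Group searchlight inference recomputes the subject null per voxel;
  at `n_perm = 100` on a full-resolution brain this is an overnight
  computation, as it is in any faithful implementation of this scheme.
* The generator's i.i.d. noise makes searchlight background accuracies
  slightly better behaved than real, spatially smooth noise would be;
  background false-positive rates on real data depend on the FDR step,
  not on the generator.
* Only binary labels are supported (fear/anger, or any two-level
  column); the source analyses are all binary, and multi-class
  decoding is out of scope.
* ROI masks are taken as given binary volumes; atlas retrieval and
  registration are out of scope.
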