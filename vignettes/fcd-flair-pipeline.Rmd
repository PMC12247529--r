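---
title: "Evaluating FCD type II lesion segmentation on FLAIR MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating FCD type II lesion segmentation on FLAIR MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdseg)
```

## The problem

Focal cortical dysplasia (FCD) type II is a malformation of cortical
development and one of the most common causes of drug-resistant focal
epilepsy. Its lesions are hyperintense on FLAIR MRI, frequently frontal,
often subtle, and small relative to the brain — which makes both manual
annotation and automated segmentation hard, and makes the *evaluation* of a
segmenter statistically delicate: plain overlap scores are unstable or
undefined on tiny or empty lesion masks.

`fcdseg` implements the analysis scaffold of such a segmentation study as a
reusable package: preprocessing, lesion-focused slice selection, the
pseudo-Dice metric family, a 5-fold cross-validation harness with a
pluggable segmenter, and the fold-level statistics. The deep network that a
production study would train (an nnU-Net-style encoder–decoder) is
deliberately *not* re-implemented: it enters only through a segmenter
interface, with cheap deterministic stand-ins used for testing, and an
adapter that can parse an externally trained nnU-Net's progress log.

## Preprocessing

`preprocess_case()` applies four stages in a fixed order:

1. **Spatial resampling** (`resample_volume()`). Scans in a real cohort vary
   in matrix size and voxel spacing, so all cases are interpolated to a
   common spacing, default 1 mm isotropic (the common grid is a package
   choice; any target can be configured). The new shape per axis is
   `round(old_shape × old_spacing / new_spacing)`, minimum 1, and the
   affine's direction columns are rescaled so world extent is preserved to
   within a voxel. Interpolation is separable per axis: nearest (order 0),
   linear (order 1), or natural cubic spline (orders 2–3, the default).
   Masks are *always* resampled with nearest-neighbour so the label set
   {0, 1} survives — no interpolation-induced fractional labels, which the
   tests assert after every stage.
2. **Skull stripping** (`skull_strip()`). No specific tool is assumed;
   the built-in method is deterministic and dependency-light: Otsu
   threshold on the global intensity histogram, morphological closing with
   a 1-voxel face-connected structuring element, largest 3D connected
   component, interior hole filling. This is adequate for phantoms and for
   any image in which brain tissue is the dominant bright structure; for
   clinical data a dedicated stripper can replace it (the stage is a
   configuration switch). A constant image has no separating threshold and
   raises a degenerate-input error.
3. **Intensity normalization** (`normalize_intensity()`). Per-volume
   z-scoring within the brain mask: in-mask mean 0 and sd 1, voxels outside
   set to 0. This removes scanner scale and makes a single intensity
   threshold meaningful across cases. The operation is idempotent and
   invariant under positive affine intensity maps, both tested to 1e-6.
4. **Mask binarization** (`binarize_mask()`). Lesion voxels are 1, all
   others 0; values strictly above the threshold (default 0.5) become 1.

## Slice selection

An MRI volume has many axial slices but only a few carry visible lesion.
`select_case()` scores every axial slice, keeps the top `k = 5`, and
compiles them into a new 3D slab, concentrating training signal in
lesion-rich slices. Two score criteria are exposed because the procedure
can be read two ways: `lesion_area` (per-slice lesion-voxel count — the
default when ground truth is available, i.e. for training data) and
`peak_intensity` (per-slice maximum intensity — usable when no mask exists,
e.g. at inference, where selecting by the ground-truth mask would leak
labels). A third variant, `lesion_intensity` (sum of image intensity under
the mask), operationalizes "most visible lesion" differently and is kept
behind the same interface.

Numerical choices: ties in the ranking break toward the lower slice index
(determinism); selected slices are kept in ascending anatomical order, not
score order, to preserve spatial coherence; the slab's axial translation is
moved to the first selected slice's world position while the nominal axial
spacing is retained even for non-adjacent slices — the true gaps are
recorded in a `slice_gaps` attribute rather than faked in the affine.
Slice indices are 1-based throughout, the R convention.

Selection with `lesion_area` and `k` at least the number of lesion-bearing
slices provably retains every lesion voxel, and selection is always
enriching (slab lesion fraction ≥ whole-volume lesion fraction); both are
tested on every fixture.

## The metric family

For prediction mask A and ground-truth mask B (voxel sets):

* **Dice similarity coefficient**: `DSC = 2|A∩B| / (|A| + |B|)`; undefined
  for two empty masks.
* **Pseudo-Dice score**: the default form is
  `PDS = 2(|A∩B| + ε)/(|A| + |B| + ε)`, with ε = 1e-5 by default. Written
  this way, the smoothing constant appears inside the doubled numerator:
  the score is total (two empty masks give 2ε/ε = 2) but can slightly
  exceed 1 at perfect overlap and is bounded by 2. The conventional
  smoothed Dice, `(2|A∩B| + ε)/(|A| + |B| + ε)`, which stays in [0, 1] and
  gives 1 for two empty masks, is available as
  `pds_variant = "standard_smooth"`. Both forms are implemented and tested
  — including the >1 behaviour of the default form — and both converge to
  DSC as ε → 0; the discrepancy between them is documented here rather than
  silently resolved, and reports state which variant they used.
* **Mean PDS**: the arithmetic mean of a PDS trace, whether the trace is
  indexed by test case or by epoch (both granularities occur in practice;
  the harness records per-epoch means of per-case scores, and persists the
  per-case values too).
* **Moving-average PDS**: the mean of the `w` most recent values ending at
  epoch `t` (positions `t−w+1..t`, 1-based), used to monitor training
  stability. The default window `w = 10` is a reporting choice.

Report tables round half-up to 2 decimals (`round_half_up()`), matching the
precision of published fold tables.

## Cross-validation harness

`make_folds()` assigns cases to `k = 5` folds randomly but balanced (sizes
differ by at most one), deterministically from a seed; no stratification is
applied. `run_fold()` trains the configured segmenter on the out-of-fold
cases and evaluates the mean validation pseudo-Dice after every epoch; the
fold summary (mean of the trace; raw final-epoch value — not a moving
average) is a pure function of the trace. The default training schedule
mirrors the conventions of self-configuring segmentation frameworks:
100 epochs, batch size 4, learning rate 0.01, SGD momentum 0.99 with
Nesterov acceleration; only the trainable segmenter consumes the optimizer
fields.

Three segmenter bindings exist:

* `segmenter_threshold()` (default): fits, by grid search on the training
  cases, the single intensity threshold in normalized units that maximizes
  mean training Dice; prediction is `intensity > threshold`. Because FLAIR
  lesions are by construction the brightest structure, this recovers
  phantom lesions with Dice well above 0.9. A linear annealing schedule
  from threshold 0 to the fitted value generates an improving per-epoch
  trace, emulating a training trajectory deterministically.
* `segmenter_logistic()`: a genuinely trained model — voxelwise logistic
  regression on intensity, minibatch SGD with the schedule above, case
  order shuffled from the run seed. It exists to exercise the stochastic
  training path (determinism given seed, optimizer plumbing) at desk scale.
* `segmenter_nnunet()`: external adapter. Fitting errors with an install
  hint when the executable is absent; `parse_nnunet_progress()` turns an
  existing progress log into a per-epoch trace that feeds the same
  summaries.

`summarize_study()` produces the fold table (one row per fold: mean PDS,
final-epoch PDS) plus the statistical analysis below; identical folds make
the paired test degenerate, which is surfaced as a warning while the table
is still emitted.

## Fold-level statistics

`describe_scores()` reports mean, sample standard deviation (divisor n−1),
and median. `ci95()` uses the Student-t critical value with n−1 degrees of
freedom, `mean ± t(0.975, n−1)·sd/√n` — not the normal approximation: with
five folds the difference is material, and only the t-based interval is
consistent with the reference fold table shipped in
`fcd_reference_folds()`. `paired_t()` is the two-sided paired t-test on the
per-fold differences (delegating to `stats::t.test`), used to ask whether
final-epoch scores systematically exceed training-average scores. Its
type-I error at n = 5 is verified by simulation (10,000 null pairs) to sit
at the nominal 5%.

## The phantom generator

`generate_phantom()` builds what the pipeline needs and nothing more: a
bright ellipsoidal "brain" (semi-axes 42% of the volume extents) with
Gaussian tissue texture (mean 100, sd 5, arbitrary units — normalization
removes scale), near-zero noisy background, and ellipsoidal lesion blobs
whose base intensity is multiplied by a contrast factor (default 1.8,
a clearly hyperintense lesion against tissue noise). Lesions are placed
"cortically" — at 55–80% of the radial distance to the brain surface, away
from the axial poles — span a configurable number of axial slices (default
5, matching the default slab size), and fall in the anterior half of the
first in-plane axis with probability 0.624, emulating the reported
frontal-lobe predilection of FCD II as a marginal frequency, not as
anatomy. Additive Gaussian noise (sd 5) is applied everywhere. Placement
that cannot keep the blob inside the brain after 100 draws raises a
placement error rather than silently shrinking the lesion.

`generate_cohort()` draws per-case matrix sizes (default 40–56 in-plane,
28–36 axial) and in-plane spacings (0.8–1.2 mm) to emulate a cohort of
variably sized scans; axial spacing defaults to 1.0 mm so that resampling
to the 1 mm target never changes which axial slices bear lesion, keeping
the slab-retention guarantee exact while in-plane resampling is still
exercised. Each case gets its own seed derived from the cohort seed;
cohorts are bitwise reproducible.

**What the phantoms do not emulate** — and hence what passing tests do not
show about clinical data: real cortical geometry and tissue classes, bias
fields, partial-volume effects, subtle low-contrast lesions, annotation
noise, or any correlation between lesion size and location. Results on
phantoms validate the *pipeline arithmetic* (geometry handling, metric
definitions, fold bookkeeping, statistics), not clinical segmentation
accuracy; the reference fold scores in `fcd_reference_folds()` come from a
real GPU-trained study and are used here only as input to the statistical
layer.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own testing conditions: phantoms of roughly 32–56 voxels per
axis, cohorts of 5–20 cases, 1,000 random 6×6×6 mask pairs for the
brute-force metric checks, 10,000 simulated null pairs for the t-test
calibration, and a 1,000-case in-memory cohort for the frontal-frequency
calibration. A full study (20 phantoms, 5 folds, 100 epochs) completes in
well under a minute on one CPU.

## Known limitations

* The skull stripper is histogram-based and assumes brain is the dominant
  bright structure; it is not a substitute for a validated clinical tool.
* 3D morphology and resampling are implemented in plain R with vectorised
  operations; they are sized for phantom-scale volumes, not for batch
  processing of high-resolution clinical scans.
* Whether slice selection at inference should see the ground-truth mask is
  a study-design question the package surfaces (two criteria) but cannot
  answer.
* Cross-modality registration (masks drawn on a different grid than the
  FLAIR) is out of scope: inputs must be voxel-aligned pairs.
* 4D time series, DICOM ingestion and BIDS layout validation are
  out of scope.
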