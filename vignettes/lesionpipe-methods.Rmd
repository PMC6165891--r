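---
title: "Methods: harmonization, white-matter lesion correction and lesion load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonization, white-matter lesion correction and lesion load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionpipe)
```

`lesionpipe` processes per-subject pairs of a T1-weighted MRI and one or more
binary stroke-lesion masks through four gated stages: orientation
harmonization, white-matter lesion correction, lesion load calculation, and
visual quality control. This vignette is the package's account of the models
and procedures behind each stage, the parameters that matter, and the design
choices made where the design was genuinely open.

## Storage conventions and harmonization

NIfTI files store anatomy in either the *neurological* convention (patient's
left on the displayed left) or the *radiological* convention (left on the
displayed right). The header-level criterion used throughout is the sign of
the determinant of the affine's 3×3 spatial block: negative means
radiological. The affine itself is taken from the sform when its code is
nonzero, else the qform, else a voxel-size-scaled identity; inconsistent
qform/sform pairs are used as-is (sform wins) with a logged warning and no
attempted repair — wrong headers cannot be repaired from header content
alone.

`to_radiological()` flips the voxel axis dominant along world left–right and
updates the affine so every voxel center keeps its world coordinate: anatomy
is never moved, only storage order changes. `to_canonical()` additionally
permutes/flips axes so the affine is closest to diagonal (per-column dominant
world axis, ties broken toward the lower axis index and logged), preserving
the storage convention. A consequence worth knowing: canonicalizing a grid
whose axes were *oddly* permuted (a single axis swap) yields the x-flipped —
world-equivalent — grid, because odd permutations toggle the determinant sign
and the convention is preserved by contract.

Per subject, all present files (T1, lesion masks, optional brain/WM masks)
must share one convention. If they disagree, the subject is *flagged*, its
files are left untouched, and it is excluded from every later stage; flagged
subjects are listed per-file in `flagged_subjects.csv` for manual review. A
defensible auto-fix exists when only the lesion disagrees with the T1, but
mislabeled headers are indistinguishable from mis-flipped data, so flagging
is the only safe action. Grid-shape mismatches flag the subject likewise
(reason `shape-mismatch`) instead of aborting a multi-subject run.

Optional inputs follow an all-or-none rule: if the run asked to skip brain
extraction or WM segmentation (because masks are supplied) and any one
subject lacks the mask, the producing stage is re-enabled for *all* subjects
and the override is logged prominently, keeping the processing uniform
across the cohort.

## Tissue preparation

Lesion correction needs a normalized T1, a brain mask and a WM mask.

* **Normalization** maps the full volume's `[min, max]` linearly onto
  `[0, 255]` (values stay continuous). The whole head is normalized, not the
  brain only, because normalization precedes skull stripping in the stage
  order; the removal window below is defined on this scale. A constant
  volume degenerates to all zeros with a warning.
* **Brain extraction** is a deterministic stand-in for a full skull
  stripper: Otsu's 256-bin between-class-variance threshold, largest
  6-connected component, morphological closing (2 voxels) and hole filling.
  On the phantom's head geometry — where a dark gap separates the skull
  shell from the brain surface — this recovers the true brain mask at
  Dice ≥ 0.95 (exactly 1.0 at the default noise level in practice). It is
  *not* a general-purpose brain extractor; on clinical data, supply your own
  masks and the pipeline will use them (`provenance = "provided"`).
* **WM segmentation** is a deterministic three-class (CSF/GM/WM) 1-D
  clustering of within-brain intensities: means initialized at the 25/50/75%
  points of the within-brain intensity *range*, Lloyd fixed-point iteration
  to tolerance 1e-6 or 100 iterations, WM = the nonempty class with the
  highest mean. Range-fraction initialization was chosen over percentile
  initialization deliberately: WM is the majority tissue in a T1, so two
  percentile-initialized means land inside the WM intensity cluster and the
  iteration converges to a split of WM rather than the three tissues.
  Range-fraction initialization is equally deterministic and recovers the
  phantom truth exactly in the noiseless limit. Lesion voxels are not
  excluded from the clustering; with an intensity drop of half the WM mean
  they cluster with CSF/GM and do not bias the WM class.

## White-matter lesion correction

Manual tracings often spill into intact white matter. With the T1 normalized
to `[0, 255]` and the mean WM intensity `m` computed over the WM mask, a
user percentage `p` (default 5) defines the removal window

\[ [\, m - \tfrac{255 \cdot p/100}{2},\; m + \tfrac{255 \cdot p/100}{2} \,] \]

and every lesion voxel whose normalized intensity falls inside it
(inclusive) is removed; the survivors are re-binarized as the final mask.
The window is left unclamped — values outside `[0, 255]` cannot match any
normalized voxel, so clamping would only complicate the arithmetic. The mean
is taken over the full WM segmentation by default (lesion voxels that landed
in the WM class included); `wm_mean_exclude_lesion = TRUE` opts into
excluding them. Removal is monotone in `p` (window nesting), the corrected
mask is always a subset of the original, and
`original = removed + surviving` — all asserted as properties in the test
suite. Correction is intended for manual tracings; configuring
`lesion_provenance = "automated"` triggers a warning, since automated
segmenters typically already exclude WM-classified voxels.

The per-run accounting (`lesion_correction_report.csv`) holds one row per
(subject, lesion mask): voxel counts, percent removed, the WM mean and the
window bounds.

## Lesion load

ROIs come from three sources: a directory of template-space ROI masks plus
the template volume; per-subject integer label volumes with a
label-code → ROI-name table (used in subject space, no registration); or any
user-supplied ROI set with its template. ROIs and lesions are binarized
(values > 0), the two masks are summed, voxels below 2 are zeroed, and the
rebinarized overlap — equivalently the voxelwise AND — yields

\[ \text{percent overlap} = 100 \cdot \frac{|\text{lesion} \cap \text{ROI}|}{|\text{ROI}|}. \]

The denominator is the ROI volume, so the statistic reads "how much of this
tract/region is damaged": 100% means the ROI is fully covered, and a lesion
contralateral to a one-hemisphere ROI scores exactly 0. Percentages are
reported on the 0–100 scale.

### Registration

Template-space loads require taking subject volumes into template space. The
estimator is a 12-parameter affine (3 translations/mm, 3 rotations, 3
log-scales, 3 shears) maximizing normalized cross-correlation within the
fixed image's nonzero bounding box (background voxels would otherwise
dominate the metric). Optimization is derivative-free coordinate descent in
a fixed parameter order — fully deterministic, no RNG — over a three-level
pyramid (block-mean downsampling ×4, ×2, ×1; block means rather than
decimation, so coarse levels do not alias noise), initialized by
center-of-mass alignment and intensity-spread scale ratios, with per-level
sweep caps 100/50/25 and step-halving to convergence tolerances of 1/8 voxel
in translation and 0.002 in rotation/log-scale. Masks are always resampled
with nearest-neighbour interpolation (linear interpolation of a mask is
rejected as a parameter error); when the subject grid and affine already
equal the template's, the identity shortcut returns inputs bit-identically.
A per-subject 4×4 world-to-world text transform file bypasses estimation
when provided. The estimator is a documented stand-in: it is not numerically
equivalent to any external registration tool, and phantom-grade recovery
(translations to well under a voxel, rotations to well under a degree,
scales to ~0.1%) should not be extrapolated to clinical anatomy.

## Visual quality control

Every producing stage renders per-subject tri-planar screenshots (axial,
coronal, sagittal slices through the lesion-mask centroid when a lesion
overlay exists, else the volume center — slice selection is the package's
choice) with masks alpha-blended in fixed colors, and concatenates them into
a per-stage HTML gallery: brain extraction, WM segmentation, registration,
lesion correction (original and corrected masks in distinct colors), and
lesion load (lesion over ROI). The authoritative review state is the
`<stage>_review.csv` beside the gallery, not the HTML checkboxes — there is
no server behind the page, and a CSV is bit-stable, scriptable and
diff-able. A filled review CSV is never clobbered by rebuilding a gallery.
In interactive runs the pipeline blocks until every row is filled; in
no-pause runs blank rows default to *passed* with a logged warning. Gating is
monotone: a subject failed at one stage appears in no later stage's outputs.
The gallery feature is also available stand-alone (`visualize_lesions()`),
with no other processing.

## The phantom: what it emulates and what it does not

All tests run on a deterministic head phantom: nested ellipsoids — GM cortex
shell outermost, WM beneath it, a CSF ventricle-like core — inside a bright
skull shell separated from the brain by a dark gap, at 2 mm isotropic
spacing on a 64×80×64 grid (tests mostly use 32×40×32 for speed; the
registration checks use the full grid), stored in neurological convention so
harmonization is exercised by default. Tissue means CSF 40 < GM 110 < WM 180
(background 5, skull 240) with additive Gaussian noise of SD 5; the
ellipsoidal lesion sits in left-hemisphere white matter with intensity
lowered to half the WM mean — between CSF and GM, typical of a chronic
cavity rim. The GM-outside/CSF-inside layering is anatomically the faithful
one, and it matters operationally: hole-filling recovers internal CSF after
thresholding, which an outermost-CSF toy layout would not allow.

Simulated "tracers" perturb the true lesion boundary with seeded random
erosions/dilations (probability and depth growing with `boundary_sd`) and
sprinkle a seeded fraction of peri-lesional *white-matter* voxels into the
mask — exactly the spillover the correction stage is built to remove, so the
inter-rater improvement direction is testable by construction: over 20
seeded replicates with 10 tracers each, mean pairwise Dice after correction
exceeds the uncorrected mean in ≥ 90% of replicates (20/20 in the shipped
configuration, roughly 0.74 → 0.83 at the default settings).

What the phantom does **not** emulate: bias fields, Rician noise, partial
volume, gyral geometry, pathology diversity, or inter-site scanner effects.
Passing tests therefore demonstrate the *correctness of the procedures* —
orientation algebra, window arithmetic, overlap counting, transform
recovery, determinism — not clinical-grade robustness of the brain
extraction, segmentation or registration stand-ins.

## Numerical and degenerate-input choices

* Window bounds inclusive; ties in the canonical-axis choice go to the lower
  axis index (logged); empty effective WM mask, empty ROI, constant
  registration images and sub-3-class brains are stage errors naming the
  subject; empty lesions yield zero-count results with a warning.
* Masks are binarized on read (`> 0` → 1) and written as uint8; intensity
  volumes are written as float64, so write/read round trips are exact and
  re-runs with the same configuration and seed are byte-identical (asserted
  in the suite).
* Multi-lesion filenames follow `<id><LesionID><k>` with `k` from 1; an
  unindexed lesion file coexisting with indexed ones is ambiguous and flags
  the subject rather than guessing.
* Logs are written under `<output>/logs/` (not the package installation
  directory, which may be read-only), one timestamped file per run,
  replaying every option, input, flag, skip override and QC gate in order.
* The run `seed` is recorded and forwarded to phantom generation; the
  pipeline stages themselves are deterministic by construction.

## Known limitations

Single-modality T1 only; NIfTI-1 only (no DICOM/MGZ/NIfTI-2, no 4-D);
affine-only registration (no nonlinear warp, no mutual information);
no bias-field correction or partial-volume modeling; genuinely wrong
headers are flagged, never repaired.
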