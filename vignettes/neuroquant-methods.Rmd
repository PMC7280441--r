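---
title: "Atlas-based PET segmentation and SUV quantification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based PET segmentation and SUV quantification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquant)
```

## The two pipelines

Regional quantification of brain FDG-PET needs a structural parcellation,
and when a labeled atlas provides it there are two ways to connect the
atlas to a subject:

* **RATSI** (register the atlas template to the subject's images): the
  T1-derived *inverse* deformation field pulls the labeled atlas into the
  subject's native space, producing a personalized atlas. The PET data are
  quantified untouched, at acquisition resolution.
* **RSIAT** (register the subject's images to the atlas template): the
  *forward* field pulls the subject's PET into template (MNI) space, where
  the fixed atlas segments it directly. The subject's data are resampled
  onto the template grid.

Both pipelines consume one spatial normalization, estimated from the
subject's T1 against the template reference
(`estimate_normalization()`), and differ only in which direction the
labels and the PET travel. `run_study()` executes both on a simulated
cohort and compares them against the phantom's ground truth.

## Data model and conventions

All volumes are 3D scalar arrays bound to a `grid_spec`: a shape plus a
4x4 affine mapping 0-based voxel indices to world millimetres on RAS
axes. Spacing is derived from the affine. Out-of-domain samples become
background (0) rather than clamped edge values, so warped atlases never
smear edge labels; label maps are stored and compared as exact integers
and may only be interpolated nearest-neighbor, because Dice set
arithmetic needs exact membership.

Deformation fields use the *pull* convention: a field lives on the grid
of its target space and the warped value at voxel `x` is the source
image sampled at `x + d(x)` (displacements in mm, world axes). A
`forward` field lives on the MNI grid and pulls subject images into MNI
(RSIAT); an `inverse` field lives on the subject grid and pulls the
atlas into native space (RATSI). Composition and fixed-point inversion
are defined directly on this convention; field components sampled
off-grid are edge-clamped, since a zero fill would fabricate a step in
the transform. Fields serialize as 4D NIfTI plus a JSON sidecar naming
the direction, so a field cannot silently be applied backwards.

## Registration

`estimate_normalization()` is a conventional multi-resolution scheme:

1. **Affine stage** (default 2 levels, working spacings halving down to
   the template's): 12 parameters (translation, rotation, log-scales,
   shears) initialized at the intensity-centroid offset and optimized by
   BFGS on mean squared difference (MSD), or Nelder-Mead on normalized
   mutual information when `similarity = "nmi"`.
2. **Nonlinear stage** (fluid demons, MSD only): at each working
   resolution (default 8, 4, 2 mm) the update is the classic
   gradient-scaled residual force, capped at one voxel, Gaussian-smoothed
   (`regularization_weight`, default 1.5 voxels — fluid regularization),
   and accepted through a halving line search only if MSD decreases. The
   per-level similarity trace is therefore non-increasing by
   construction, and the whole procedure is deterministic.

At every level the moving image is first smoothed to the level's
physical resolution, matching the anti-alias smoothing of the
downsampled fixed image — otherwise the residual would chase a
sharp-versus-smooth mismatch rather than geometry. The inverse field is
obtained by fixed-point inversion of the forward field (tolerance 0.5
voxel for estimated fields; `invert_field()` defaults to 0.1 voxel and
internally iterates toward a quarter of the requested tolerance so that
compositions of inverted fields stay well inside contract). A
registration that fails to improve on the identity map raises a
diagnostic error carrying the similarity trace.

The contract of this module is field quality — round-trip residuals,
recovery of known translations and smooth warps — not equivalence with
any particular neuroimaging suite; clinical pipelines built on other
registration engines fit behind the same interface.

## SUV quantification

SUV is computed voxelwise as `SUV = r * w / a'`, with `r` the activity
concentration in kBq/mL, `w` the body weight in grams, and `a'` the
injected activity decay-corrected (half-life default 109.77 min for
F-18) from injection to the reference time, which defaults to scan
start — the conventional choice; it is configurable because sites
differ. `regional_quantify()` takes the arithmetic mean and maximum over
the plain mask overlap, with no background exclusion or thresholding. An
empty requested region is a hard per-region error: a silent zero or NaN
would flow into the group statistics unnoticed. Dose conversion uses the
exact definition 1 mCi = 37 MBq.

## Agreement metrics

* **Dice**: `2|A.B| / (|A| + |B|)` on exact voxel sets; undefined (an
  error) for two empty masks.
* **Hausdorff**: symmetric, exact Euclidean, over voxel-center
  coordinates, reported in voxel ("pixel") units; grids are expected
  isotropic (the common-space evaluator resamples to isotropic voxels
  first), and a `hausdorff_mm` column accompanies cross-grid
  comparisons. The implementation reduces the directed distance to
  `A \ B` against the 6-connectivity boundary of `B` — an exact
  reduction (the nearest member of `B` to an outside point is always a
  boundary voxel), unlike the tempting boundary-versus-boundary
  shortcut, which fails for nested shapes. A brute-force all-pairs
  oracle is retained in the tests; exactness is preferred over speed at
  phantom scale. The 100th percentile (true maximum) is the default, and
  HD95 is available as an option.
* **Bland-Altman**: differences `y - x`, limits at bias ± 1.96 SD;
  `fraction_within` counts pairs strictly inside the open interval, so
  ties on a limit line count as outside — a deterministic, documented
  convention.

### Evaluation spaces

`evaluate_in_common_space()` implements the protocol of normalizing all
segmentations into MNI before comparing them. `evaluate_vs_truth()`
instead compares each method in the space where its masks touch the
PET: RATSI and manual segmentations against the truth labels on the
native grid, and RSIAT (the fixed atlas) against the truth labels warped
through the *estimated* forward field, as normalizing a reference
segmentation would in practice.

The distinction matters, and the phantom makes it measurable. When the
forward and inverse fields are exact numerical inverses of each other —
as they are here, and as they effectively are in unified-segmentation
pipelines — the common-space comparison warps the personalized atlas
back into MNI, where it reproduces the fixed atlas almost voxel for
voxel; both methods are then compared to the same warped reference and
tie by construction. Dice is also insensitive to a shrinkage both masks
share, so focal atrophy unrecovered by registration penalizes both
pipelines by the same ratio. On this idealized phantom the two methods
are therefore near-equivalent on Dice, and the tests record that
honestly; the practical advantages of a personalized atlas live in the
asymmetries a real pipeline adds around the warp itself — mask
interpolation and thresholding, bounding boxes, the resolution lost by
pushing native data onto a coarse template grid — of which the phantom
reproduces the resolution term (subject grids are finer than the
template grid) but deliberately not the others.

## Statistical battery

Paired t (Dice/HD between methods), one-way ANOVA (SUVs across the
three segmentation methods), the variance-ratio F-test (homogeneity;
`homogeneous` iff p > 0.05), and the two-sample t-test (pooled when the
F-test declares homogeneity, Welch otherwise) — all two-sided, all at
alpha = 0.05, all uncorrected for multiple comparisons, and the result
objects say so (`correction = "uncorrected"`). The F-test is the plain
variance-ratio test rather than Levene's, and post-hoc method contrasts
are unadjusted pairwise t-tests. Degenerate inputs are explicit errors:
zero-variance differences with nonzero mean (infinite statistic), two
zero-variance samples in the F-test, undersized groups.

## The phantom

`make_atlas_phantom()` builds a geometric, not anatomical, atlas: a
brain-shaped ellipsoid (roughly 75 x 86 x 69 mm half-axes in a 128 mm
field of view) partitioned into 70 contiguous parcels by nearest-seed
assignment with bilaterally mirrored seeds, so left/right homologues are
exact mirror images. Six parcels carry the names CAU_L/R (labels 23/24),
PUT_L/R (25/26) and CGM_L/R (29/30) at plausible positions — caudate and
putamen deep and paramedian, cerebellar gray matter inferior-posterior.
Three fixed *separator* parcels stand in for the cold anatomy that
isolates these targets in vivo — ventricle tissue between the caudate
heads, the internal capsule between caudate and putamen, and the vermis
midline between the cerebellar hemispheres; without them, adjacent hot
parcels meet at shared faces and the partial-volume blur drags a
region's maximum onto its boundary, which no real striatum exhibits.

The reference T1 is tissue-realistic in contrast structure: each
bilateral pair gets one weak intensity (deep parcels nearly isointense,
as deep nuclei are on T1), overlaid with a strong smooth low- and
mid-frequency modulation that emulates gyral/vascular texture. The
registration is thus driven by the brain outline and internal texture
rather than by parcel borders it could not see in vivo.

`make_subject()` draws a smooth random deformation — Gaussian-smoothed
vector noise (14 mm correlation length) scaled to `deform_amplitude`
(default 4 mm, kept below the smallest nucleus radius so the truth stays
invertible; invertibility is asserted by constructing the true forward
field through `invert_field()`) — plus an optional analytic radial
atrophy term per region. The warped parcellation *is* the ground-truth
segmentation. Subject volumes are acquired on a grid `subject_factor`
(default 2) times finer than the template, emulating native-resolution
structural imaging against a coarser template grid.

Uptake: each region receives the activity that makes its true SUV_mean
equal a per-subject draw from the group profile. The profile's named
nuclei carry the PD/MSA group means and SDs of the study the phantom
emulates (strong cerebellar contrast, moderate striatal contrast);
unnamed parcels sit at a mixed-tissue 4.5 +/- 0.8 in both groups, below
every named nucleus, so the targets are locally hottest as in FDG
physiology. Draws share a per-subject global metabolic factor
(`global_cv = 0.25`, capped at 90% of each marginal SD) with independent
residuals, preserving every marginal mean and SD exactly while giving
the inter-regional correlations (~0.7) real cohorts show — fully
independent draws occasionally produce a putamen colder than white
matter, which does not occur in vivo. Activity is converted with fixed
nominal injection metadata (370 MBq decay-corrected, 74 kg, 40-minute
uptake, F-18 half-life), chosen so SUV has a closed-form inverse during
construction and the noiseless pipeline closes the loop exactly. The
scanner is modeled as a Gaussian PSF (`psf_fwhm`, default 4 mm — between
the reconstruction filter and typical clinical resolution) plus additive
Gaussian noise (`noise_sd`, default 0.3 SUV); negative activities clip
to zero. Everything is a pure function of the spec and its seed, with
per-subject seeds derived from the master seed.

What the phantom does **not** emulate: MR physics (bias fields, k-space
artifacts), Poisson sinogram-level PET noise, attenuation effects,
true cortical folding, and the mask-handling asymmetries of specific
clinical software. Passing tests therefore demonstrate the correctness
and calibration of the algorithms under controlled truth, not clinical
performance on patient data.

## Numerical choices

* Gaussian smoothing is FFT-based with 3-sigma zero padding (no
  wrap-around leakage); field smoothing would be biased toward zero at
  the boundary by plain zero padding, which is why demons smooths the
  *update* (fluid) rather than the accumulated field.
* Trilinear sampling clamps the interpolation cell at the array edge;
  the out-of-domain decision (background fill for images, edge clamp for
  displacement components) is made per quantity, as described above.
* Fixed-point inversion takes full steps while they contract and falls
  back to damped half-steps otherwise; failure to reach tolerance is a
  reported error naming the worst residual.
* Voronoi ties (equidistant seeds) resolve to the lower seed index by
  the strict-inequality update; mirrored geometry stays exactly mirrored
  because the mirror plane falls between voxel columns.

## Problem sizes

The shipped tests exercise 32³ and 48³ template grids (subject grids 2x
finer) with cohorts of up to ten subjects, 200 random mask pairs up to
12³ against brute force, 20 random fields for inversion contracts, 100
draw-level Monte-Carlo cohorts for the group contrast, and 1000-replicate
null simulations for test calibration; the acceptance script runs an
8-vs-4-subject study at 48³. These sizes were chosen to make the full
validation cycle convenient on a laptop; all of them scale up by
changing `phantom_spec()` arguments.

## Known limitations

Registration is same-modality MSD-driven (the phantom's subject T1 and
template share an intensity scale); cross-modality normalization would
need the NMI affine stage plus an external nonlinear engine. The demons
field is smooth but carries no diffeomorphic guarantee. Hausdorff on
strongly anisotropic grids is reported in voxel units of unequal
physical size (a warning is raised); the common-space evaluator
resamples to isotropic voxels first. The phantom's parity finding for
the two pipelines (see *Evaluation spaces*) is a statement about
idealized, self-consistent normalization — not evidence that the choice
is irrelevant in clinical software.
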