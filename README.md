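# neuroquant

Atlas-based automatic brain segmentation and regional SUV quantification
for hybrid PET/MR.

Quantifying regional cerebral glucose metabolism from FDG-PET — for
example to separate Parkinson disease (PD) from multiple system atrophy
(MSA) by their uptake patterns — requires a structural parcellation of
each subject's brain. Manual delineation is slow and operator-dependent;
atlas-based automation replaces it, but there are two ways to connect a
labeled atlas to a subject, and they are not equivalent:

* **RATSI** — *register the atlas template to the subject's images*:
  the inverse deformation field from the T1 spatial normalization pulls
  the labeled atlas into native space, producing a **personalized
  atlas**; the PET data are quantified untouched.
* **RSIAT** — *register the subject's images to the atlas template*:
  the forward field pulls the subject's PET into template (MNI) space,
  where the fixed atlas segments it directly; the subject's data are
  resampled onto the template grid.

`neuroquant` implements both pipelines end to end for researchers in
quantitative neuroimaging: deformation-field estimation, inversion and
composition; SUV computation with decay correction,

    SUV = r / (a' / w),        a' = A_inj · 2^(−Δt / T_half),

with `r` the activity concentration (kBq/mL), `a'` the decay-corrected
injected activity (kBq) and `w` the body weight (g); regional
SUV_mean/SUV_max extraction; segmentation-agreement metrics

    DC = 2|A ∩ B| / (|A| + |B|),     HD = max( sup_{a∈A} d(a,B), sup_{b∈B} d(b,A) ),

plus Bland-Altman limits of agreement; and the group-comparison
statistical battery (paired t, one-way ANOVA, variance-ratio F, pooled /
Welch two-sample t with the F-then-t decision rule).

Because no patient data can ship with a package, `neuroquant` includes a
seeded synthetic PET/MR brain phantom: a 70-region bilateral atlas,
subjects with known smooth deformations (and optional focal atrophy),
tissue-realistic T1 contrast, PET partial-volume blur and noise, and a
PD/MSA cohort whose regional uptake follows published group means and
SDs. Every stage of the package is validated against this ground truth.

## Worked example

Simulate one PD-like subject, estimate its normalization, build the
personalized atlas, and quantify regional SUVs:

```r
library(neuroquant)

spec    <- phantom_spec(grid_shape = 48, seed = 42)
atlas   <- make_atlas_phantom(spec)
subject <- make_subject(atlas, group_uptake_profile(), "PD", spec, seed = 7)

norm  <- estimate_normalization(subject$t1, atlas$reference_t1)
ratsi <- ratsi_segment(atlas, norm)

suv <- suv_image(subject$pet, subject$suv_inputs)
regional_quantify(suv, ratsi, nucleus_labels(), names(nucleus_labels()))
#>   label  name suv_mean suv_max voxel_count volume_mm3
#> 1    23 CAU_L     5.88    7.22        1462       3465
#> 2    24 CAU_R     6.79    8.53        1396       3309
#> 3    25 PUT_L     6.85    8.46        2026       4802
#> 4    26 PUT_R     6.74    8.41        2223       5269
#> 5    29 CGM_L     4.12    5.72        2693       6383
#> 6    30 CGM_R     4.85    6.74        2525       5985

evaluate_vs_truth(ratsi, subject$truth_labels, norm,
                  nucleus_labels()[1:4], names(nucleus_labels())[1:4])
#>        name  dice hausdorff_pixels
#> CAU_L CAU_L 0.956             1.41
#> CAU_R CAU_R 0.928             1.00
#> PUT_L PUT_L 0.935             1.41
#> PUT_R PUT_R 0.952             1.41
```

`suv_mean`/`suv_max` are the unitless standardized uptake values over
each region's mask (caudate and putamen hot, cerebellar gray matter
lower — the PD pattern); `dice` near 1 and a Hausdorff distance of about
one voxel say the personalized atlas recovered the subject's (known,
simulated) anatomy to within a voxel at the region boundaries.

`run_study()` runs the whole design — simulate a 20 PD + 8 MSA cohort,
segment every subject with both pipelines, quantify, evaluate against
ground truth, and compute the method and group statistics — and writes
report tables (agreement, quantification, method tests, Bland-Altman,
PD-vs-MSA comparison) as TSV.

A command-line interface over the same functions lives at
`inst/cli/neuroquant.R`:

```sh
Rscript inst/cli/neuroquant.R simulate --out cohort/ --n-pd 4 --n-msa 2 --grid 48
Rscript inst/cli/neuroquant.R run --out study/ --n-pd 4 --n-msa 2 --seed 42
```

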