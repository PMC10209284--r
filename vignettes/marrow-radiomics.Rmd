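---
title: "Radiomics of bone-marrow biopsy sites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics of bone-marrow biopsy sites: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmradiomics)
```

## The question the package addresses

In multiple myeloma, measurable residual disease (MRD) after treatment is
assessed two ways that frequently disagree: multiparameter flow cytometry
(MFC) on a marrow aspirate drawn from a single site — sternum or a posterior
iliac crest — and expert visual reading of a whole-body [18F]FDG PET/CT.
The aspirate samples a few millilitres of marrow; the PET image sees all of
it. `bmradiomics` implements a quantitative pipeline for asking whether the
small region a biopsy needle can reach is *representative* of the whole bone
marrow: it segments the marrow and the three standard biopsy sites from CT,
quantifies the co-registered PET signal inside those masks with a 32-feature
radiomic panel, screens the features against the PET and MFC labels, and
trains a suite of classifiers on the (oversampled) feature table.

Because the clinical cohort behind this analysis design is not publicly
deposited, the package ships a first-class synthetic phantom generator that
reproduces the *structure* of such a cohort — geometry, uptake patterns,
class imbalance and label discordance — so every stage runs, and is tested,
end to end without any data download.

## Segmentation model

The whole bone marrow is segmented from CT alone:

1. threshold at `bone_hu_threshold` (default 150 HU — marrow fat/trabecular
   mixture and compact bone both exceed it, soft tissue does not);
2. morphological closing with a 4 mm ball (physical radius, so the element
   adapts to anisotropic spacing);
3. 3D hole filling;
4. removal of components below 200 voxels;
5. subtraction of compact bone (≥ `compact_bone_hu_threshold`, default
   300 HU) and of the spinal canal.

The canal is identified topologically: it is the largest *interior cavity*
(voxels added by hole filling) whose centroid lies in the posterior half of
the torso bounding box. This is deliberately not a low-HU threshold on the
filled mask — morphological closing creates small soft-tissue fillets at
concave bone junctions, and a purely intensity-based rule would confuse the
largest fillet with the canal when no canal exists.

The biopsy-site rules operate on the marrow mask with the limbs removed:

* **Sternum** — remove the posterior half of the mask (the spine), remove
  everything in the inferior half of the torso bounding box (the pelvis),
  keep the longest component in the axial direction, and intersect it with a
  cube whose top face is flush with the most superior sternum voxel and
  whose x/y centre is the sternum centroid. The cube edge is 40 voxels *of
  the clinical CT grid* (0.9766 × 0.9766 × 2.5 mm); on other grids the edge
  is rescaled per axis so the physical extent (≈ 39 × 39 × 100 mm) is
  preserved.
* **Posterior iliac crest** — remove the superior half of the mask (the
  torso), keep the component occupying the most sagittal (x) slices — the
  pelvis, anatomically the widest bone — divide it into five slabs R1–R5 by
  four equidistant sagittal planes (R1 at the patient's far right), keep
  R1+R2 (right) or R4+R5 (left), and finally remove the anterior half of
  what is kept.

Axis semantics are fixed package-wide: z inferior→superior, y
anterior→posterior, x patient-left→patient-right. NIfTI input in any
orientation is reoriented through its affine on read.

Three conventions were genuinely open and are fixed as follows:

* *Half-space splits* cut at the midpoint of the mask's own bounding box
  (not the volume's), and the boundary slice goes to the low side. Any fixed
  convention works; this one is the simplest to reason about and test.
* *"Widest component in the sagittal plane"* is read as greatest
  left–right extent (occupied x slices), not in-plane area; the pelvis wins
  under either reading, so the choice is not load-bearing on realistic
  anatomy.
* The sternal cube is *intersected* with the sternum mask rather than used
  as a solid region: a solid cube would include non-marrow voxels.
* Pelvis slab planes sit at fractions k/5 of the bounding-box index span,
  with a boundary voxel assigned to the lower slab; a 52-voxel-wide pelvis
  divides as 11/10/10/10/11.

Component selection ties (equal extent) are broken by voxel count, then by
smaller centroid z. Manual expert mask editing, which the clinical workflow
includes, is replaced by an optional `override` mask argument.

## Quantization and the feature panel

PET SUV values inside a mask are quantized uniformly onto `Ng = 64` gray
levels, scaling linearly between 0 and the *cohort-wide* maximum SUVmax:

    R(x) = round(Ng * I(x) / SUVmax_cohort)

rounded half away from zero and clamped below at 1, so every level lies in
1..Ng. The clamp resolves the literal level 0 at I(x) = 0; the cohort-wide
scaling forces a two-pass pipeline (measure the scaling maximum first,
extract features second) and makes features comparable across patients.

The 32-feature panel comprises SUVmax and SUVmean on raw SUV; variance,
skewness and excess kurtosis of the quantized levels (population moments;
a constant region reports skewness = kurtosis = 0); nine GLCM features;
thirteen GLRLM features; and five NGTDM features (Amadasun–King, with
26-neighbourhoods restricted to the mask). Numerical conventions:

* GLCM and GLRLM accumulate the 13 unique 3D directions at Chebyshev
  distance 1 into a **single merged matrix** (the common toolbox behaviour),
  not per-direction feature averaging. The GLCM is symmetrized and
  normalized to sum 1.
* Run percentage uses `13 * Np` in the denominator, since runs are counted
  over 13 directions.
* GLCM SumAverage and Variance use the compact forms
  `½Σ(i+j)p` and `Σ(i−μ)²p` with `μ = ½Σ(i+j)p`; Correlation is defined
  as 0 for a constant region; Entropy uses base-2 logs with `0·log 0 = 0`.
* NGTDM Coarseness is capped at 10⁶ when `Σ pᵢ sᵢ < 10⁻⁶`; Contrast is 0
  when only one level is present; Busyness is 0 when its denominator
  vanishes.
* Exact definitions are pinned by brute-force oracles in the test suite:
  every matrix-based feature is checked against naive loop enumeration on
  random 6×6×6 regions to 10⁻¹⁰.

The GLRLM block includes LRHGE as its thirteenth member and the NGTDM block
includes Coarseness and Busyness, completing the stated five-feature set.

## The synthetic cohort

`phantomSpec()` describes a schematic skeleton — spine cylinder with an
enclosed low-HU canal near the posterior midline, anterior sternum slab,
laterally wide pelvis with two posterior iliac wings, humeral and femoral
cylinders, each a compact-bone shell (700 HU) around marrow (150 HU) —
painted on a CT grid, by default 96 × 96 × 192 voxels at 2 × 2 × 2.5 mm
(a 192 × 192 × 480 mm field of view; `fullSize = TRUE` gives the clinical
512 × 512 / 0.9766 mm matrix). The paired PET grid is 48 × 48 × 96 at
4 × 4 × 5 mm. The shapes are deliberately schematic rather than atlas-based:
the segmentation rules consume only geometric predicates (the sternum is the
longest axial component after the removals; the pelvis is the widest lateral
one), and the phantom satisfies all of them with ≥ 10 mm inter-bone gaps so
that the 4 mm closing cannot bridge structures.

Uptake model: marrow voxels draw a baseline SUV texture independently from
a Gamma distribution with mean 1.5 and SD 0.3, truncated at mean + 5 SD — a
PET-negative read means *no focal uptake*, so the homogeneous field must not
contain focal-like outliers, and the truncation clips only ~3 × 10⁻⁵ of the
mass. Additive Gaussian image noise has SD 0.05; background tissue sits at
SUV 0.2. Putting the Gamma at voxel rather than patient level gives the
PET-negative marrow genuine texture (so histogram and texture features
measure something real there) and makes the pooled PET+/PET− voxel
comparison well-powered; a patient-level baseline would instead make every
pooled comparison hostage to between-case baseline luck. PET-positive cases additionally
receive `1 + Poisson(4)` focal lesions — spheres with Gaussian radial
profiles, radius 6–15 mm, peak SUV 4–12 — confined to the marrow so that any
PET+/PET− texture difference is attributable to marrow heterogeneity. The
guaranteed first lesion is centred inside the case's biopsy-site region and
the remainder are uniform over the marrow: the cohort thereby has the
property the analysis is designed to detect (the biopsy site carries the
PET-status signal, and whole-marrow and biopsy-site features share the
per-case lesion burden). Grid-level label shuffling still yields a clean
null, which is what the calibration tests exercise.

Labels are exact, not stochastic: for the default n = 39 the generator
realizes 31 PET−/8 PET+, 24 MFC−/15 MFC+, twelve discordant PET−/MFC+
cases, and biopsy sites at frequencies 22:15:2 (S:LIC:RIC). The PET+/MFC−
count follows from those marginals (five at the defaults). MFC status has no
imaging correlate in the phantom — it is an assay-side label, and its
discordance with the PET label is exactly what limits MFC-side
classification.

What the phantom does **not** emulate: scanner point-spread and
reconstruction artifacts, attenuation/scatter, anatomical variability beyond
rigid size/position jitter, degenerative bone disease, and genuinely
diffuse (non-focal) infiltration patterns. Tests passing on phantoms
therefore demonstrate the correctness and calibration of the *pipeline*, not
clinical performance on real scans.

## Statistics and classification

Per feature, groups (PET± or MFC±) are compared with a two-sided
Mann–Whitney U test — exact by enumeration when both samples together hold
at most 12 untied observations, otherwise the tie- and continuity-corrected
normal approximation — and the feature–class association is summarized by
Spearman's rank correlation against the class coded 0/1 (positive rho =
larger values in the positive class), with a t-approximate p-value on n − 2
degrees of freedom. Benjamini–Hochberg correction is applied over the
32-feature family of each analysis by default; a pooled correction across
analyses can be obtained by passing the concatenated p-values to
`benjaminiHochberg()` (the appropriate family is a judgement call; both
readings are supported).

Class imbalance is addressed with Safe-Level-SMOTE: synthetic minority
points interpolate between a minority seed and one of its k = 5 nearest
minority neighbours, with the interpolation gap modulated by the "safe
level" (minority density) around each endpoint, so synthesis is pulled
toward safe regions and suppressed entirely when both endpoints are
majority-surrounded. Neighbourhoods use Euclidean distance on min–max
scaled features; synthetic points are generated in the original feature
space. Generation stops at equal class counts.

Eight classifiers (decision tree, SVM with RBF/polynomial/linear kernels,
random forest, neural network, logistic regression, kNN) are evaluated with
stratified five-fold cross-validation. Features are standardized with
training-fold statistics; predictions are pooled across folds; AUC comes
from pooled scores and the remaining five metrics (accuracy, F1, precision,
recall, specificity) from pooled class predictions, with 0/0 ratios defined
as 0. Thresholds 0.7 ("acceptable") and 0.9 ("outstanding") are reported as
flags. Hyperparameters are deliberately plain defaults (cost-1 SVMs, 500
trees, size-8 weight-decayed network, k = 5) exposed through the `hyper`
argument — no tuning is performed.

One protocol point deserves emphasis: the default pipeline oversamples the
whole feature table *before* cross-validation, which leaks synthetic
neighbours of test points into training folds and inflates the oversampled
metrics. This mirrors the analysis protocol the pipeline reproduces. A
leakage-safe alternative (`smote_mode: within_folds`, or
`crossValidate(..., smote = TRUE)`) applies Safe-Level-SMOTE inside the
training folds only and is the mode to prefer for honest performance
estimates.

## Problem sizes and determinism

The test suite exercises the pipeline at sizes chosen to keep a full run
comfortable on one CPU: the default downscaled grids, a 40-case
strong-effect cohort for effect-structure and classifier checks, 50
randomized phantoms for segmentation recovery (all three site masks must
reach Dice ≥ 0.85 against construction-time truth), 200 label permutations
for type-I calibration of the screening, and 100 random 6×6×6 regions for
the brute-force feature oracles. Every stochastic component takes an
explicit seed and restores the caller's RNG state; the pipeline writes a
manifest whose hash changes exactly when a configuration value changes, and
repeated runs with the same seed are bit-identical.

## Known limitations

* Segmentation thresholds and morphology radii are fixed defaults, not
  fitted to scanner-specific CT; real data would need per-site review (the
  `override` hook exists for that).
* The phantom's marrow is homogeneous apart from lesions; real marrow has
  age- and treatment-dependent fat fraction gradients that the histogram
  features would pick up.
* The sternal cube and slab conventions reproduce a published procedure;
  they are not optimized against anatomical ground truth.
* MFC-side classification is expected to fail on the synthetic cohort by
  construction (labels discordant with imaging), as it does in the clinical
  analysis the pipeline mirrors.

```{r example, eval = FALSE}
# a complete run on a small synthetic cohort
cfg <- defaultPipelineConfig(seed = 1, outdir = "demo_run", n = 12)
res <- runPipeline(cfg)
head(res$stats$pet_original)
res$ml$pet_oversampled
```
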