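---
title: "Voxel-wise 3D texture mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise 3D texture mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texmap3d)
```

## The problem

Structural T1-weighted MRI of neurodegenerative disease — amyotrophic
lateral sclerosis (ALS) being the motivating case — often looks normal to
the eye even when pathology is present in the motor cortex and
corticospinal tract. Texture analysis quantifies the spatial organisation of
voxel intensities: their local regularity, contrast and co-occurrence
patterns. This package maps four gray-level co-occurrence matrix (GLCM)
features at every voxel of the brain, producing per-subject 3D texture maps
that can be compared between groups with standard voxel-wise statistics, and
then evaluates any detected regions as candidate biomarkers (ROC, clinical
correlation).

## The texture model

At each in-mask voxel we take the $(2r+1)\times(2r+1)$ in-plane patch
centred on it, in each of the three orthogonal planes of the voxel grid
(axial = array axes 1–2, coronal = 1–3, sagittal = 2–3; for MNI-oriented
volumes these are the anatomical planes). Intensities are first quantized
per volume into $N_g$ equal-width bins over the in-mask range. Within a
patch, every ordered pair of in-mask voxels separated by distance $d$ along
one of the four in-plane directions (0°, 45°, 90°, 135°) is accumulated
symmetrically into a single $N_g \times N_g$ matrix, which is then
normalised to $p(i,j)$ with $\sum_{ij} p(i,j) = 1$. The four features are
the standard co-occurrence statistics

$$\mathrm{Auto} = \sum_{i,j} i\,j\,p(i,j), \qquad
  \mathrm{Savg} = \sum_{k=2}^{2N_g} k\,p_{x+y}(k),$$

$$\mathrm{Sosv} = \sum_{i,j} (i-\mu)^2 p(i,j), \qquad
  \mathrm{Svar} = \sum_{k=2}^{2N_g} (k-\mathrm{Savg})^2\, p_{x+y}(k),$$

with $p_{x+y}(k) = \sum_{i+j=k} p(i,j)$ and $\mu = \sum_{i,j} i\,p(i,j)$
the GLCM grand mean. The per-voxel feature value is the average of the
three per-plane values, taken over planes that contributed at least one
pair. Auto measures the regularity/linear dependency of neighbouring
intensities, Savg the overall intensity level of the texture, and Sosv and
Svar two flavours of contrast (spread about the mean level, and joint
spread of co-occurring levels).

Three conventions here are genuinely open choices, fixed and documented:

* **Deviation centre of Svar.** We centre Svar on Savg, the convention of
  most modern co-occurrence implementations (some older texts centre it on
  other quantities). With this choice Svar is exactly the variance of the
  $i+j$ marginal.
* **Direction pooling.** The four in-plane directions are accumulated into
  one symmetric matrix per plane before computing features, rather than
  averaging per-direction features. In a 3×3 patch a single direction
  yields at most six pairs, so per-direction matrices are frequently
  degenerate; pooling is more stable and rotation-robust.
* **Edge and mask handling.** Pairs with either endpoint outside the
  volume, the patch, or the mask are dropped; a plane with zero pairs is
  excluded from the average; a voxel with no valid plane is `NA`. No
  padding is used, so there are no brain-edge artifacts — at the cost of
  slightly noisier estimates at the rim.

Defaults are $N_g = 8$, $r = 1$ (a 3×3 patch), $d = 1$, no post-smoothing —
the standard configuration for whole-brain T1 texture mapping. `distance`
must satisfy $d \le 2r$ or no pair fits in the patch.

Quantization is per-volume equal-width binning over the in-mask range,
upper edge inclusive. This is the least-assumption scheme when the input
volumes have already been intensity-standardized by preprocessing (this
package consumes normalized volumes and performs no preprocessing itself).
Consequently any strictly increasing intensity transform that preserves bin
membership — in particular any positive affine rescaling — leaves the maps
bit-identical.

## Voxel-wise statistics

Group comparison is a voxel-wise general linear model: texture regressed on
intercept, group, age and sex, with the group effect tested by the partial
*F*-test (full model vs. the model without the group column), df
$(1, n-4)$. With one numerator degree of freedom this *F* is exactly the
squared *t* of the group coefficient; age and sex act as nuisance
covariates. Voxels missing in any subject are dropped listwise and counted.

Multiple comparisons are handled by Benjamini–Hochberg FDR at $q \le 0.05$
over all tested voxels, separately per feature (no cross-feature
adjustment — each feature is reported as its own map, and this choice is
deliberate and documented rather than hidden). Surviving voxels are grouped
into connected components under 26-connectivity (configurable to 6 or 18);
components are kept only when **strictly larger** than `min_cluster_size`
(default 10, i.e. size ≥ 11). Each cluster reports its peak-*F* voxel (ties
broken toward the smallest linear index, making results deterministic), the
peak's world coordinate (the NIfTI affine applied to the 0-based index),
and a direction: the sign of the group coefficient at the peak, i.e.
whether patients' texture is increased or decreased there.

## Region-level biomarker evaluation

For each cluster, per-subject means over the cluster's voxels feed:

* **ROC analysis.** AUC is computed by integrating the empirical ROC curve
  over all candidate cutoffs (midpoints between consecutive distinct
  values, plus sentinels beyond the extremes); this equals the
  pair-counting rank statistic with ties counted ½, and the package
  exposes both routes (`roc_analysis()` and `auc_rank()`) and tests their
  identity. Orientation is chosen so AUC ≥ 0.5; the reported cutoff
  maximizes Youden's $J = \text{sens} + \text{spec} - 1$, with ties broken
  toward higher specificity. Reported sensitivity/specificity are
  in-sample values at that cutoff — apparent accuracy, not cross-validated.
* **Clinical correlation.** Pearson *r* with the two-sided *p* from the *t*
  transform on $n-2$ df. Correlations with symptom duration, ALSFRS and
  finger-tapping are computed over patients only (duration is undefined
  for controls); per-region *p* values are reported unadjusted, mirroring
  the per-region presentation convention of this literature.

## The synthetic cohort generator

No MRI data ship with the package; the generator provides cohorts with
known ground truth so that every downstream stage can be validated
end-to-end:

* **Anatomy.** A deterministic pseudo-anatomical baseline (a fixed set of
  low-frequency 3D Gaussian blobs) inside an ellipsoidal brain mask with
  semi-axes 0.45 of the grid. Real anatomy is unnecessary for validating
  the statistics; what matters is a smooth, spatially varying background.
* **Noise and effects.** Stationary Gaussian noise (default SD 10 intensity
  units) is added to the baseline. Implanted effects modify the noise
  field only, inside spherical ROIs, for the affected group:
  `variance-scale` multiplies the local noise SD (raising local contrast,
  hence Sosv/Svar), `correlation-length` replaces local noise by a
  smoothed copy (lowering it), `mean-shift` adds an offset (moving
  Savg/Auto). Magnitude 0 disables an effect, giving exact null cohorts.
* **Intensity standardization.** The baseline is rescaled to a fixed window
  and volumes are clipped to [0, 255], so every subject attains the same
  in-mask extremes. This emulates the intensity standardization such
  pipelines assume of their input, and it matters: with unstandardized
  volumes, a variance effect inflates that subject's intensity range
  through noise extremes, widening that subject's quantization bins and
  shifting texture values *everywhere* — a global artifact of range-based
  binning, not a property of the local texture change. The clipped caps
  sit at the fixed baseline extremes; default ROIs are placed in
  mid-intensity regions away from them.
* **Clinical covariates.** Patient symptom duration is uniform over 9–72
  months; the per-patient effect magnitude is
  `magnitude + clinical_link × duration`, so a positive link implants a
  recoverable texture–duration correlation. ALSFRS and finger-tapping
  decline with duration with additive noise. Ages (uniform 25–80) are
  shared between groups and sexes alternate within group, so both
  covariates are balanced yet still exercise the GLM adjustment.
* **Determinism.** Every draw flows from the single config seed; identical
  config and seed give bit-identical cohorts, volumes included.

Effect magnitudes in shipped configurations (e.g. a 3× variance scale, or
base 1.2 with link 0.03/month) are chosen for statistical power in
compact volumes, not for biological realism — the literature offers no
usable effect-size calibration for these features. The generator also does
not simulate scanner artifacts, bias fields, registration error, or
anatomy-dependent noise; passing recovery tests therefore demonstrates the
correctness and calibration of the *pipeline*, not expected sensitivity on
clinical data.

## Numerical choices and degenerate inputs

* A constant in-mask volume quantizes to level 1 everywhere and yields the
  analytic point-mass maps (Auto 1, Savg 2, Sosv = Svar = 0).
* GLCMs with zero pairs return `pair_count = 0` and an all-zero matrix;
  `glcm_features()` refuses them, and the map code excludes those planes.
* `fdr_correct()` requires *p* ∈ (0, 1]; BH is implemented via
  `p.adjust(method = "BH")`.
* With perfect group separation the residual sum of squares underflows and
  *p* reaches the order of 1e-90; tests treat anything below 1e-12 as
  "zero".
* Map post-smoothing (`smoothing` > 0, FWHM in voxels) is NA-aware:
  the zero-filled map and the defined-voxel indicator are smoothed
  separately and their ratio taken, so undefined rim voxels do not bleed
  zeros into the brain.
* All cluster, peak and report orderings are fully deterministic
  (descending peak F; ties by linear index), and pipeline runs with the
  same config and seed produce byte-identical artifact hashes.

## Validation scale

The shipped tests validate the engine against a literal-loop brute-force
reference on volumes up to $9^3$ (every voxel, plane, direction and pair
enumerated naively), the GLM against `lm()`/`anova()` on toy designs, ROC
against exhaustive threshold enumeration and `pROC`, and correlations
against the definitional sums. Calibration and recovery properties use
compact cohorts — null FDR behaviour on 200 cohorts of 20 subjects with
roughly $20^3$ in-mask voxels; ROI recovery (Dice > 0.5) over 20 seeds at
$n = 15$/group; duration-link recovery over 50 seeds — sizes chosen so the
whole suite runs comfortably on a laptop while leaving Monte-Carlo margins
explicit in each test.

## Known limitations

* Only the four features above are implemented; the engine's accumulation
  step is feature-agnostic, so further Haralick statistics are a small
  extension, but entropy/energy/IMC are not currently exposed.
* The GLCM is strictly planar-then-averaged; no 26-neighbour volumetric
  co-occurrence.
* No preprocessing: volumes must arrive normalized to a common space and
  intensity-standardized; geometry is checked (`validate_geometry()`), but
  intensity comparability is the caller's responsibility.
* Diagnostic metrics are in-sample; no cross-validation or multivariable
  combination of regions is provided.
* Cluster anatomical labelling (atlas lookup) is out of scope; clusters are
  reported by world coordinates only.
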