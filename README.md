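# texmap3d

Whole-brain 3D texture analysis for structural MRI, as an R package.

Routine T1-weighted images of neurodegenerative disease — amyotrophic
lateral sclerosis (ALS) being the motivating application — often look
normal even where pathology is present (motor cortex, corticospinal
tract). Texture analysis quantifies the spatial organisation of voxel
intensities instead of their raw values. `texmap3d` turns each subject's
normalized T1 volume into per-voxel gray-level co-occurrence (GLCM)
texture maps, compares groups voxel-by-voxel, and evaluates the detected
regions as candidate biomarkers. It is aimed at neuroimaging researchers
who have spatially normalized, intensity-standardized volumes and a
subject table, and want a tested, reproducible texture-mapping pipeline
with ground-truth validation built in.

## Method

For every in-mask voxel, a `(2r+1) × (2r+1)` patch around it is examined
in each of the three orthogonal planes. Intensities are quantized into
`Ng` equal-width bins over the in-mask range; all voxel pairs at distance
`d` along the four in-plane directions (0°, 45°, 90°, 135°) are
accumulated symmetrically into a normalized co-occurrence matrix `p(i,j)`
per plane. Four Haralick-type features are computed per plane and averaged
over planes:

    Auto = Σᵢⱼ i·j·p(i,j)                 autocorrelation (regularity)
    Savg = Σₖ k·p_{x+y}(k)                sum average (texture intensity)
    Sosv = Σᵢⱼ (i−μ)²·p(i,j)              sum of squares variance (contrast)
    Svar = Σₖ (k−Savg)²·p_{x+y}(k)        sum variance (joint contrast)

with `p_{x+y}(k) = Σ_{i+j=k} p(i,j)` and `μ = Σᵢⱼ i·p(i,j)`. Defaults:
`Ng = 8`, `r = 1`, `d = 1`, no smoothing.

The per-subject maps are compared with a voxel-wise GLM (intercept +
group + age + sex), the group effect tested by a partial F-test with df
`(1, n−4)`, Benjamini–Hochberg FDR at `q ≤ 0.05` per feature, and
connected suprathreshold clusters strictly larger than 10 voxels reported
with peak MNI coordinates and effect direction. Each cluster's per-subject
mean feeds ROC analysis (pair-counting AUC, Youden-optimal cutoff) and
Pearson correlations with clinical measures (symptom duration, ALSFRS,
finger-tapping; patients only).

A synthetic cohort generator produces MNI-like two-group cohorts with
implanted spherical texture effects (variance scaling, correlation
length, mean shift) and duration-linked effect magnitudes, so the full
pipeline can be validated against known ground truth.

## Worked example

Analyze a synthetic cohort of 10 patients and 10 controls with a 3×
variance-scale effect implanted in a radius-4 sphere:

```r
library(texmap3d)

syn <- cohort_config(n_per_group = 10, volume_shape = c(24, 24, 24),
                     roi_specs = list(roi_spec(c(8, 12, 12), 4, magnitude = 3)),
                     seed = 7)
cfg <- pipeline_config(output_dir = "demo", synthetic = syn,
                       features = c("sosv", "svar"), seed = 7)
run_pipeline(cfg)
#> [info] stage simulate: writing synthetic fixtures
#> [info] stage inputs: 20 subjects validated
#> [info] stage texture: 2 features x 20 subjects
#> [info] stage analyze [sosv]: 5232 voxels tested, 123 significant at q<=0.05
#> [info] stage analyze [svar]: 5232 voxels tested, 20 significant at q<=0.05
#> [info] pipeline finished: 1 cluster(s), manifest at demo/manifest.json

read.csv("demo/tables/clusters.csv")
#>   feature cluster_id size_voxels peak_x_mm peak_y_mm peak_z_mm   peak_F  q_at_peak direction
#> 1    sosv          1         119      -6.5       1.5      -1.5 75.10737 0.00100668         1
```

The implanted sphere contains 121 voxels; the pipeline recovers a
119-voxel cluster at the right location, with direction `+1` — patients'
sum-of-squares variance is increased, as a noise-variance effect should
produce. (The 20 scattered svar voxels form no cluster larger than 10,
so svar reports nothing: the size threshold is strict.) The region report
adds biomarker metrics for the cluster:

```r
read.csv("demo/tables/region_report.csv")[, c("auc", "sensitivity_pct",
                                              "specificity_pct", "r_duration")]
#>   auc sensitivity_pct specificity_pct r_duration
#> 1   1             100             100 -0.1281648
```

AUC 1 with 100/100 in-sample sensitivity/specificity — the implanted
effect fully separates the groups at this cohort size — and no
texture–duration correlation, correctly, because this configuration set
`clinical_link = 0`.

Outputs under `output_dir`: per-subject feature maps
(`maps/<subject>_<feature>.nii.gz` + GLCM sidecar), `F`/`p`/`q` statistical
maps per feature, cluster and region-report CSVs, and a JSON manifest with
per-file MD5 hashes (byte-identical across re-runs with the same config
and seed).

A thin command-line front end with `simulate` / `texture` / `analyze` /
`run` subcommands is installed at `inst/cli/texmap3d.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/texmap3d.R", package="texmap3d"))')" \
    run --config analysis.yaml
```

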