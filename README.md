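# laminaprof

Layer-resolved cortical microstructure profiling from diffusion MRI and
histology.

## The problem

Alzheimer-type pathology attacks the six cytoarchitectonic layers of the
neocortex unevenly: amyloid-β plaques and hyperphosphorylated-tau tangles
accumulate in characteristic laminar patterns, and high-resolution ex vivo
diffusion MRI can, in principle, see the microstructural consequences layer
by layer. Testing that idea requires a chain of analyses that is easy to get
subtly wrong: segmenting the cortical ribbon into equidistant laminae,
reducing tensor-derived maps to per-layer/per-region profiles, quantifying
stained slides with color deconvolution and moment-preserving thresholding,
and running small-cohort statistics (covariate-adjusted group tests with FDR
control, pathology-stage mixed models, matched-pair difference profiles,
layer-wise rank correlations).

`laminaprof` implements that chain as tested, reusable R functions, together
with a synthetic-data module — cortical-ribbon DWI phantoms, cohorts with
injected group effects, layered histology slides — whose ground truth is
known exactly, so every stage can be verified end to end.

## The model in brief

**Equidistant laminae.** Each gray-matter voxel gets a relative depth
`d = D_pial / (D_pial + D_wm)`, where `D_pial` and `D_wm` are Euclidean
distances (mm) to the GM–CSF and GM–WM boundary voxel sets. Depth is binned
into `K = 8` equal-width laminae; the outermost and innermost are discarded
and the rest relabelled I–VI (pial → WM).

**Tensor metrics.** The diffusion tensor is fitted by log-linear least
squares per voxel; from its sorted eigenvalues `λ1 ≥ λ2 ≥ λ3`:

    MD = (λ1 + λ2 + λ3)/3,  AD = λ1,  RD = (λ2 + λ3)/2,
    FA = sqrt(3/2) · sqrt(Σ(λi − MD)²) / sqrt(Σλi²)

Maps are normalized by their mean over the retained cortex (mFA, mMD, …) and
averaged within each (ROI × layer) cell.

**Histology.** RGB slides are unmixed through the optical-density stain
matrix (Beer–Lambert), binarized with the moment-preserving (Tsai) threshold,
and summarized as per-layer positive-pixel fractions.

**Statistics.** Metrics are residualized on age, sex, cortical thickness,
PMI and fixation time, then compared between amyloid-positive and
amyloid-negative groups with pooled-variance t-tests (per layer pooled over
ROIs and per ROI-layer cell, 28 × 6 = 168 cells in the reference layout) with
Benjamini–Hochberg FDR per family. Pathology-stage effects are modelled with
`value ~ age + sex + Braak + Amyloid + (1 | subject)`. Case-minus-matched-
control ΔMD profiles are correlated with stain density across the six layers
by Spearman rank correlation with exact permutation p-values at small n.

## Worked example

```r
library(laminaprof)

# a cortical-ribbon phantom: 3 mm shell at 0.5 mm voxels, radial tensors,
# MD falling and FA rising from pial to WM surface
ph  <- make_phantom(phantom_spec())
dwi <- synthesize_dwi(ph$tensor_field, s0 = 100,
                      protocol = dwi_protocol(snr = 30), seed = 1)

# laminar segmentation and layer profiles
b      <- extract_boundaries(ph$gm_mask, ph$wm_mask)
depth  <- compute_depth(ph$gm_mask, b$pial, b$wm, ph$spacing)
layers <- retain_layers(assign_laminae(depth, 8), 8)
maps   <- tensor_metrics(fit_tensor(dwi, ph$gm_mask))
prof   <- layer_roi_profile(maps[c("FA", "MD")], layers, ph$roi_atlas, "demo")

subset(aggregate(value ~ layer + metric, prof, mean), metric == "MD")
#>    layer metric        value
#> 7      1     MD 0.0002394779
#> 8      2     MD 0.0002225931
#> 9      3     MD 0.0002005923
#> 10     4     MD 0.0001812410
#> 11     5     MD 0.0001557768
#> 12     6     MD 0.0001411120
```

The six per-layer MD means recover the generator's decreasing pial→WM
profile (2.4 → 1.4 × 10⁻⁴ mm²/s across layers I–VI) to within a few percent
under Rician noise at SNR 30; interior layers are nearly exact, the outer
ones show the expected bin-edge attenuation at this resolution.

A full synthetic study — cohort of 15 (4 HC / 3 PART / 8 amyloid-positive)
with +10% MD injected in layers II–III of the amyloid-positive group, a
stained slide, and the whole statistical battery — runs with:

```r
res <- run_pipeline(default_config())
subset(res$ttests, scope == "layer" & metric == "MD")   # per-layer group tests
tidy(res$lmm)                                           # stage mixed model
res$spearman                                            # layer-wise rank correlation
```

Outputs (profiles, density, test results, provenance log) are written as CSV
and JSON under the configured output directory; re-running the same
configuration reproduces them byte for byte.

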