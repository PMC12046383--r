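---
title: "Laminar microstructure profiling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar microstructure profiling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminaprof)
```

`laminaprof` analyses the cortical ribbon layer by layer: it segments gray
matter into equidistant laminae, reduces diffusion-tensor maps to
per-layer/per-region profiles, quantifies stained slides, and runs the
group and correlation statistics that relate laminar diffusivity to amyloid
and tau burden. This vignette is the package's own account of the models it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## Equidistant laminar segmentation

Every gray-matter voxel receives a relative cortical depth

$$d = \frac{D_\mathrm{pial}}{D_\mathrm{pial} + D_\mathrm{WM}},$$

where $D_\mathrm{pial}$ and $D_\mathrm{WM}$ are Euclidean distances in
millimetres to the pial and white-matter boundary voxel sets. Boundary sets
are defined by face adjacency (6-connected in 3D, 4-connected in 2D): the WM
boundary is the set of GM voxels touching WM, the pial boundary the set of GM
voxels touching anything that is neither GM nor WM. Distances are computed
with an exact separable squared-distance transform that honours anisotropic
voxel spacing.

Depth is binned into $K = 8$ equal-width laminae by
$\ell = \min(\lfloor dK \rfloor + 1, K)$, so bin-edge ties go to the deeper
lamina and $d = 1$ is clamped into lamina $K$. The outermost and innermost
laminae are discarded — they are the ones most contaminated by partial-volume
and segmentation error at the two surfaces — and the remaining six are
relabelled I–VI from the pial side. A voxel that belongs to both boundary
sets (a one-voxel-thick ribbon) is assigned $d = 0.5$.

Histology images run through exactly the same machinery in 2D after the
manually delineated CSF–GM and WM–GM polylines are rasterized onto the pixel
grid; intersecting polylines are rejected.

**Parcel thickness QC.** A parcel's thickness is estimated as the mean of
$D_\mathrm{pial} + D_\mathrm{WM}$ over its GM voxels; parcels whose estimate
differs from a reference thickness by 0.5 mm or more are dropped. The 0.5 mm
tolerance is one voxel of the targeted anatomical acquisition. The estimator
itself is one reasonable choice among several (no canonical "thickness
similarity" statistic exists); it is exact on slabs and within one voxel on
curved ribbons.

**Resolution caveat.** With a ~3 mm ribbon sampled at 0.5 mm, each of the
8 laminae is under a voxel thick; lamina labels near bin edges then depend on
sub-voxel discretization, which is a property of the data, not of the
algorithm. The consistency checks between the generator's analytic lamina
truth and the distance-based labels are therefore run on ribbons resolved at
about 15 voxels across (e.g. 6 mm at 0.4 mm), where agreement exceeds 95%
and every disagreement is an off-by-one at a bin edge.

## Diffusion tensor fitting and metrics

The tensor is fitted voxel-wise by ordinary least squares of $\ln S$ on the
standard 7-column design built from $b$-values and unit gradient directions.
All volumes, b0 and diffusion-weighted alike, enter one regression; OLS (not
WLS or nonlinear) is the simplest defensible default for noiseless synthetic
data and high-SNR ex vivo acquisitions. Non-positive signals are clipped to a
tiny epsilon before the log and the voxel is flagged rather than silently
altered; collinear direction sets abort with a rank message.

From sorted eigenvalues, MD/AD/RD/FA follow their closed forms; FA of the
zero tensor is defined as 0. Negative eigenvalues from noisy fits are kept in
the arithmetic (the voxel is flagged) — clipping would bias layer means.
Metric maps are normalized by their mean over the cortex mask, for which the
package uses the union of retained layers I–VI: the excluded laminae are the
least trustworthy voxels, and including them would couple the normalizing
constant to segmentation error. (Normalizing over all 8 laminae instead
changes every map by a single global factor and none of the test statistics.)

Profiles are arithmetic means per (ROI × layer) cell; empty cells are emitted
as missing rows with a zero voxel count, never silently dropped.

## Histology quantification

Brightfield RGB is converted to optical density
$OD_c = -\log_{10}(\max(I_c, 1)/I_0)$ and unmixed by inverting the stain
matrix (unit-norm OD row per stain; a missing third stain is completed with
the orthogonal unit vector). Presets for hematoxylin–DAB, H&E and a Luxol-
fast-blue-style myelin stain are included, but the matrix is always
overridable because practical deconvolution vectors are chosen per slide.

Binarization uses the moment-preserving threshold: the two-level image must
preserve the channel's first three gray-level moments. The channel is
quantized to 256 levels between its minimum and maximum. For every realizable
cut the two representative levels are solved to preserve the first and second
moments exactly, and the cut whose two-level image best matches the third
moment is selected. Whenever the closed-form below-fraction $p_0$ is exactly
attainable in the cumulative histogram this is precisely Tsai's percentile
rule; when $p_0$ falls between attainable cuts (discrete histograms), the
selection picks the better neighbour instead of always rounding up. The
threshold is applied globally per channel; the original method is described
as "local" but no window size is documented anywhere, and a global threshold
is the reproducible default for synthetic slides with stationary background.
Constant channels yield an empty positive mask with a warning.

Per-layer stain density is the positive-pixel fraction within each retained
layer band.

## Statistics

**Residualize-then-test.** Metrics are regressed on an intercept plus age,
sex (0/1), mean cortical thickness, postmortem interval and fixation time,
pooled over all subjects with no group term, and the residuals are compared
between amyloid-positive and amyloid-negative subjects by a pooled-variance
Student t-test (Welch available via a flag). Two families are produced: per
(ROI, layer) cell — 28 × 6 = 168 tests in the reference layout — and per
layer with each subject contributing its across-ROI mean. The t statistic is
signed as (amyloid-negative − amyloid-positive), so pathology-elevated MD
appears as negative t. BH-FDR is applied within each (metric, family).

This "regress out then test" scheme is conservative when a nuisance covariate
is itself separated between groups (as cortical thickness is in the cohort
design): part of the true group difference is absorbed by the pooled
regression. That is a property of the procedure, reproduced deliberately; the
power simulations below quantify it rather than hide it.

**Stage mixed model.** Per layer,
`value ~ age + sex + braak_stage + amyloid_stage + (1 | subject)` is fitted
by REML with Satterthwaite degrees of freedom, the random intercept absorbing
subject-level repetition across ROIs. Per-(ROI, layer) fits have one
observation per subject, so the random intercept is inestimable; those fits
degrade to OLS and are flagged `ols_fallback` in the output rather than
failing. Constant predictors (e.g. Braak stage all zero in a subset) are
dropped by name with a message.

**Delta profiles and rank correlation.** ΔMD is the cell-wise difference
between a case and its explicitly declared age/sex-matched control — matching
is configuration, not an automatic nearest-age algorithm, mirroring how such
pairs are chosen by hand in practice. Spearman correlation across the six
layers uses average ranks for ties and an exact two-sided permutation p-value
obtained by full enumeration for n ≤ 8 (720 permutations at n = 6), falling
back to the t approximation for larger n.

## The synthetic-data module

The generator exists so that every stage can be checked against known truth;
its defaults are the study conditions the pipeline targets.

- **Phantom.** A spherical-shell cortical ribbon (default inner radius 8 mm,
  outer 11 mm — a 3 mm cortex — at 0.5 mm isotropic voxels; a slab variant
  for analytic tests). Every GM tensor is axially symmetric with its
  principal axis along the local surface normal. Given per-layer (MD, FA)
  targets, the eigenvalues come from the closed form
  $\delta = \mathrm{FA}/\sqrt{3 - 2\,\mathrm{FA}^2}$,
  $\lambda_\parallel = \mathrm{MD}(1 + 2\delta)$,
  $\lambda_\perp = \mathrm{MD}(1 - \delta)$. Defaults make MD fall
  (2.4 → 1.4 × 10⁻⁴ mm²/s) and FA rise (0.10 → 0.35) from pial to WM across
  layers I–VI, the fixed-tissue pattern the pipeline is meant to detect. The
  excluded laminae 1 and 8 reuse the nearest retained layer's targets. The
  ground-truth depth uses the same distance-fraction convention as the
  segmentation, with the reference surfaces inset half a voxel (boundary
  voxel centres sit inside the geometric surfaces); ROIs are equal angular
  sectors, four by default.
- **Acquisition.** 20 b0 volumes plus 60 non-colinear directions at
  b = 6000 s/mm², the directions spread by seeded electrostatic repulsion.
  Noise is Rician by default (magnitude MRI) at SNR 30 defined as
  $S_0/\sigma$; the acquisition's true noise level is not documented
  anywhere, so the value is configurable and not claimed to match any
  scanner.
- **Cohort.** 4 HC / 3 PART / 8 amyloid-positive subjects. Ages centre on
  56 / 75 / 70 years per group (SD 8), sex is predominantly male (P(F) =
  1/15), PMI 150–1100 min, fixation 30–80 days, thickness 3.0 mm except
  2.7 mm in the amyloid-positive group (the thinning observed in such
  cohorts; the generator places it in the pathological group). Braak stage is
  drawn per group; Amyloid stage is 0 for HC/PART and ≥ 1 for the positive
  group. The default injected effect multiplies MD by 1.10 in layers II–III
  of amyloid-positive subjects. The fast mode perturbs the phantom's truth
  table with multiplicative log-normal noise (subject SD 0.02, cell SD 0.02
  on the log scale, about the per-layer variability tensor fitting shows at
  SNR 30); the full mode synthesizes a DWI dataset per subject.
- **Slides.** A horizontal GM band split into 8 laminae; stain-positive
  blobs (radius 1–3 px) are placed per lamina until the target count is met
  exactly, then rendered through the stain matrix by Beer–Lambert mixing.
  Default per-layer amyloid targets (0.02, 0.05, 0.10, 0.15, 0.15, 0.12)
  follow the nonlinear depth profile of plaque burden.

What the generator does **not** emulate: gyral folding, partial-volume
mixing at boundaries, spatially varying S0 or coil sensitivity, sequence-
specific signal physics (the forward model is plain monoexponential), stain
variability, tissue artefacts. Passing tests therefore demonstrate that the
algorithms are correct and the statistics calibrated under clean geometry —
not that any real acquisition meets those conditions.

## Numerical choices

- Distances in mm everywhere; anisotropic spacing supported in the distance
  transform; voxel indices are 1-based in R, world offsets derive from the
  NIfTI header.
- Depth ties at bin edges go to the deeper lamina; depth 1 is clamped.
- Signals ≤ 0 are clipped to `min(positive) × 1e-6` before the log and the
  voxel flagged.
- The moment threshold quantizes to 256 bins; the quantization bounds are the
  channel's min/max and are recorded in the result.
- The exchangeable null for size simulations uses homogeneous covariate
  means across groups; with the cohort's group-separated thickness and age
  kept in place the residualization absorbs between-group noise and the test
  becomes conservative (rejection well below nominal), which the power
  simulation reports as-is.
- Simulation problem sizes: statistical calibration runs use the 1 mm-voxel
  phantom (fast profile mode, 200 replicates); geometric and tensor checks
  use ribbons of 12–15 voxels' thickness. These sizes make the whole suite
  run in a few minutes while keeping Monte-Carlo error well inside the
  asserted tolerances.

## Known limitations

- Equidistant layering only; equipotential/equivolume schemes are outside
  scope, as are surface meshing and automatic GM/WM segmentation.
- The per-(ROI, layer) mixed model is inherently inestimable with one
  observation per subject; the OLS fallback changes the inferential model
  and is flagged, not hidden.
- dMRI-to-anatomy registration is assumed done (synthetic data guarantees a
  common grid); only a nearest-neighbour label resampler would be needed for
  real data and none is bundled.
- Sample sizes of 15 give the group tests limited power once covariates are
  regressed out; the package reports calibrated sizes and honest power, and
  no multiple-testing family can rescue n = 15.
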