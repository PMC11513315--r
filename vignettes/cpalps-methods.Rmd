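---
title: "Models and methods behind cpalps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cpalps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpalps)
```

cpalps validates, by parameter recovery on synthetic data, the two MRI
computations used to assess glymphatic function in case-control
neuroimaging studies: Gaussian-mixture segmentation of the choroid plexus
(CP) with TIV normalization, and the DTI-ALPS diffusivity ratio. This
vignette documents the models, every tunable that matters, the numerical
choices, and what the synthetic validation does and does not show.

## The intensity mixture model and its EM fit

Within a lateral-ventricle mask, T1 voxel intensities are modelled as a
K-component univariate Gaussian mixture. `segment_cp()` fixes K = 3
because exactly three tissue populations live there: CSF, CP, and the
partial-volume voxels of the ventricular wall. K is still exposed as an
option for sensitivity checks. After fitting, components are sorted by
mean and tissue identity is assigned by that order — CSF darkest, CP
intermediate, wall brightest. This ordering convention is the single most
consequential assumption in the package: it holds for T1-weighted
contrast, and sorting before assignment makes the labelling invariant to
the arbitrary component order EM converges in.

`fit_gmm_em()` implements the standard EM iteration with these specifics
(none of which are dictated by the published method, which leaves them
open):

* **Initialization**: the sorted sample is split into K contiguous
  equal-count chunks whose means/variances/proportions seed the fit
  (deterministic); k-means initialization is available and is the only
  consumer of the `seed` argument.
* **Convergence**: relative log-likelihood change below `tol = 1e-6`, cap
  `max_iter = 500`. The log-likelihood trace is recorded and is
  non-decreasing (a property the tests assert).
* **Variance floor**: `1e-6 * var(x)` applied at every M-step, preventing
  component collapse on near-duplicate intensities.
* **K = 1** returns the closed form, with the biased (divide-by-n)
  variance, matching the maximum-likelihood convention of the M-step.
* Responsibilities are computed in log-space (log-sum-exp), so widely
  separated components do not underflow.

Voxels get hard maximum-a-posteriori labels rather than soft partial
volumes because the downstream quantity is a binary mask volume, as in
expert-refined practice.

**Degenerate mixtures.** If the minimum pairwise separation
`|μ_i − μ_j| / sqrt((σ_i² + σ_j²)/2)` falls below `min_separation = 2`,
the histogram does not actually support distinct classes (e.g. a
ventricle containing only CSF). The CP class is then reported empty with
a warning and `qc$degenerate = TRUE`, rather than returning an arbitrary
third of the mask. The threshold 2 corresponds to adjacent classes
overlapping at roughly their 1-sigma points; it is configurable.

## Mask cleanup

Expert manual refinement is replaced by two explicit rules in
`refine_mask()`: 26-connected components smaller than 5 voxels are
removed (flow artifacts, specks), and CP voxels lying on the 1-voxel
inner boundary shell of the ventricle mask are removed
(wall-contamination rule; the shell is where partial-volume voxels live).
Both parameters are configurable; the operation is idempotent. Component
labelling builds the 26-neighbour adjacency graph of mask voxels and uses
igraph's component search.

## Bias fields: simulation and estimation

MR intensity inhomogeneity is modelled multiplicatively.
`simulate_bias_field()` sums a few broad Gaussian bumps with random
centres and signs, recentres to mean 0, rescales the peak to 1 and maps
to `1 + amplitude·g`: the field has grid mean exactly 1 and peak
deviation exactly `amplitude`.

`estimate_bias_field()` is a deliberately simple stand-in for the heavier
model-based correction used in clinical pipelines. Smoothing raw log
intensities would confound the bias with the spatial arrangement of the
tissue classes (the CP blob and wall shell are spatially structured), so
the estimator first removes a provisional class mean: in-mask voxels are
split into three intensity classes by quantile-initialized 1D k-means,
each voxel's class-mean log intensity is subtracted, and the residuals —
which contain the log bias plus noise — are smoothed by a separable
Gaussian kernel (SD `scale_mm = 12` mm, normalized convolution so only
in-mask voxels contribute). On bias-free phantoms this estimator stays
within ±2 % of unity, and on 0.2-amplitude corrupted phantoms dividing by
it strictly reduces within-class intensity spread; both behaviours are
asserted in the tests.

## The T1 phantom

`generate_phantom()` realizes the three-class model with known truth:

* **Geometry**: two ellipsoidal "lateral ventricles" (default semi-axes
  8 × 16 × 6 mm, centres ±11 mm from the grid centre, 48 × 44 × 24 grid at
  1 mm isotropic — large enough to hold both ellipsoids with margin while
  keeping a segmentation under 0.1 s). Anisotropic spacing is supported
  throughout.
* **Wall** is the 1-voxel inner boundary shell (face-neighbour
  definition), mirroring where partial-volume voxels occur.
* **CP** is one compact blob per ventricle — the k interior voxels
  nearest the posterior pole, with k split between ventricles
  proportionally to interior size — because real CP is contiguous tissue
  in the ventricle body/atrium, and salt-and-pepper CP would be destroyed
  by the small-component rule. The posterior direction is taken as +y on
  the grid. `cp_fraction` of all ventricle voxels is met to within one
  voxel of rounding.
* **Intensities**: class means 30 / 55 / 80 with SD 3 by default. The
  equal 25-unit gaps with SD 3 (12 % of the gap) represent a clearly
  resolvable, low-noise acquisition; the noise ladder in
  `analysis/02_segment_cp.R` raises the SD to 8 (32 % of the gap), where
  median Dice degrades monotonically to ≈ 0.92.
* **TIV** (default 64,000 mm³) is an input scalar, not derived from the
  grid: the phantom contains only the ventricles, and TIV only enters the
  percentage normalization. The default puts the default `cp_fraction`
  of 0.25 at a true CP volume of ≈ 2.5 % of TIV, the magnitude reported
  for patient groups.

`phantom_spec_for_cp_pct()` inverts the geometry: given a target CP
percentage it computes the `cp_fraction` that realizes it on the
rasterized ventricles, which is how per-subject phantoms are built in the
end-to-end pipeline.

## The tensor phantom and the ALPS computation

`generate_tensor_phantom()` fills an isotropic background (0.8 × 10⁻³
mm²/s) with two disjoint axis-aligned slabs: projection fibers with
diagonal tensor (1.2, 0.6, 1.8) × 10⁻³ mm²/s (principal axis z) and
association fibers (1.2, 1.8, 0.6) × 10⁻³ (principal axis y), sharing an
x-range as the ALPS selection rule requires. The noise-free truth index
is `mean(1.2, 1.2)/mean(0.6, 0.6) = 2.0`. Optional Gaussian noise is
added to the three diagonal components only — the phantom stays diagonal,
hence trivially symmetric positive-definite — and negative draws are
redrawn rather than clipped, preserving the distribution's symmetry about
the mean. DWI signal simulation and tensor fitting are deliberately out
of scope: the contribution being validated is the index, not the
reconstruction.

`compute_alps()` composes three steps:

1. **ROI**: a sphere (default diameter 5 mm, the conventional size)
   containing every voxel whose physical centre lies within the radius —
   anisotropic-aware; on a 1 mm grid the 5 mm sphere holds 81 voxels
   (verified against brute-force lattice enumeration). The hemisphere tag
   is annotation only.
2. **Fiber classification**: per ROI voxel, the principal eigenvector of
   the 3 × 3 tensor; dominant absolute component z → projection, y →
   association, x → subcortical, with exact ties broken in the fixed
   order z > y > x (so a perfectly isotropic voxel is "projection").
   Subcortical voxels are labelled but unused by the index formula.
3. **Representative selection**: restricted to x-indices where both
   classes occur ("on the same x-axis"), the voxel per class with maximum
   orientation — interpreted as the largest absolute principal-eigenvector
   component along the class axis; maximum fractional anisotropy is
   available as an alternative (`orientation = "fa"`). Diffusivities are
   read as raw tensor diagonal entries in scanner axes (Dxx literally "the
   diffusivity along x"), not eigenvalues.

The index inherits two exact properties asserted in the tests: scale
invariance (`ALPS(c·D) = ALPS(D)`) and unity on isotropic fields.
`tensor_spec_for_alps()` realizes any target index a exactly by setting
Dx of both fiber classes to `a × 0.6 × 10⁻³` while holding the
perpendicular diffusivities at 0.6 × 10⁻³; targets outside (0.1, 2.9)
would break the strict principal-axis ordering and are redrawn — at the
calibrated group models this is a < 10⁻⁸ event with no effect on means.

ROI placement on real data is a manual act; the package therefore always
takes an explicit centre coordinate (physical mm; voxel indices are
0-based in reports). The default pipeline centre sits midway between the
two fiber slabs on their shared x-range.

## The simulated cohort

`default_cohort_spec()` carries the study-calibrated group models: n = 40
patients / 42 controls; ALPS 1.470 ± 0.239 vs 1.641 ± 0.266; CP volume
2.514 vs 2.190 % of TIV; the nine neuropsychological subtest z-score
means/SDs of the patient group; and a −0.428 correlation between CP
percent and the word-list-recognition z-score, realized by a Cholesky
transform of two standard normal draws per subject. Choices the source
summaries do not pin down:

* **CP-percent SDs are not published** (only means, with p < 0.001). The
  shipped calibration uses 0.45 (patients) and 0.40 (controls) — plausible
  for CP volumetry and consistent with p < 0.001 at these group sizes
  (Welch SE ≈ 0.094, t ≈ 3.4). This is a package choice, made once.
* The published CP means appear in two presentations (2.514/2.190 in the
  results body, 1.392/1.138 in the abstract). The default preset uses the
  results-body values; `preset = "abstract"` switches. No attempt is made
  to reconcile them.
* **Controls' neuropsychological scores are not published**; controls draw
  z ~ N(0, 1) per subtest with zero CP correlation (normative behaviour).
  Impairment classification and correlations are computed within the
  patient group, matching the published analysis scope.

The generator draws measured quantities directly; the end-to-end pipeline
(`run_all()`) additionally *realizes* each subject as phantoms — a T1
phantom whose true CP fraction matches the subject's target percentage,
and a noise-free tensor phantom whose true index matches the target ALPS —
and measures them by running the actual segmentation and ALPS code, so
recovery checks exercise the pipeline, not just the RNG.

## The impairment rule and the statistics

A domain is *affected* iff any of its subtest z-scores is strictly below
−1.5 ("more than 1.5 SD below the mean": exactly −1.5 is not abnormal);
a subject is *impaired* iff ≥ 2 domains are affected ("more than one").
The subtest-to-domain mapping is fixed in `cerad_domains()`:
frontal/executive (verbal fluency, trail-making B, Stroop), language
(modified Boston Naming), verbal memory (word-list memory/recall/
recognition), visual memory (constructional recall), global (MMSE-KC).
The battery names the domains but not the mapping; this grouping follows
the natural reading of the test names, and whether MMSE-KC alone should
count as a domain is genuinely open — it does here.

Group comparisons default to the Welch unequal-variance t test (the safer
reading of "independent t-test"; the pooled-variance Student variant is a
flag), with a summary-statistic variant that is algebraically identical
to the sample variant. The chi-square test is Pearson's without Yates
correction by default (correction available). P-values are reported raw —
per-test α, as in the source analysis — with Benjamini-Hochberg
adjustment available as a clearly flagged extension. All three statistics
are cross-checked in the tests against brute-force formula/quadrature
oracles to 1e-8, and the zero-variance-equal-means comparison returns
t = 0, p = 1 by documented convention.

## Determinism and problem sizes

Identical specs and seeds produce bit-identical outputs everywhere: the
generators call `set.seed(spec$seed)` internally, and the pipeline
derives per-subject seeds as `(master + 104729·i) mod (2³¹ − 1)`, so a
subject can be regenerated in isolation and results are independent of
cohort size. Every pipeline run writes a manifest (seed, per-subject
seeds, configuration echo, package version).

The replication sizes used by the shipped validation — 50 replicates of
full 82-subject phantom cohorts for the ALPS and CP-volume recoveries,
200 cohorts for the correlation recovery, 20 phantoms per rung of the
noise ladder — keep the Monte-Carlo standard error of each grand mean an
order of magnitude below the effect sizes being recovered (e.g. SEM
≈ 0.005 for ALPS at 2,000 subject draws) while the whole validation runs
in minutes on a single core.

## Known limitations

* Phantoms are geometric idealizations: no anatomy, no multi-contrast
  physics, no k-space noise, no motion, no registration error. Passing
  recovery tests demonstrates the correctness of the computations under
  the stated intensity/tensor models, not robustness on clinical data.
* The T1 intensity model is piecewise-constant plus Gaussian noise; real
  CP shows internal texture and calcification, and real walls are not
  exactly one voxel thick.
* Tensors are generated, not fitted from diffusion-weighted images, so
  reconstruction-stage errors are outside the validation.
* The wall/CSF/CP mean ordering is assumed, not estimated; on sequences
  with different contrast the cluster-to-tissue assignment must be
  revisited.
* Ventricle masks and TIV are pipeline inputs, as in the source method
  (they come from a separate whole-brain segmentation there); the package
  neither detects ventricles nor estimates TIV.
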