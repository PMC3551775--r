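---
title: "Quantifying MR signal distribution in intervertebral discs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MR signal distribution in intervertebral discs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amrsid)
```

## The problem

On T2-weighted MRI, a healthy intervertebral disc shows a bright, hydrated
nucleus pulposus (NP) surrounded by a dark annulus fibrosus (AF). Early
disc degeneration -- as it occurs in adolescent idiopathic scoliosis and in
spondylolisthesis -- redistributes water and proteoglycans, and with them
the signal, before anything is visible to the naked eye. `amrsid`
quantifies the *distribution* of the signal inside segmented disc regions,
producing per-disc indices that can be compared across pathology and
severity groups.

Segmentation itself is out of scope: the package consumes a NIfTI intensity
volume plus an aligned integer label mask identifying up to five regions
(IVD, NP, AF, a CSF sample, and a cancellous-bone sample of the vertebra
above). Mask codes are exclusive per voxel with hierarchical semantics:
voxels coded NP or AF also count as IVD, so NP is a subset of IVD by
construction, and when no explicit AF code is present the annulus is
derived as disc-minus-NP.

## Normalization model

Raw MR intensities are arbitrary units that vary with acquisition gain,
patient morphology and sequence parameters. Two steps make them
comparable:

1. **Volume-fraction weighting.** Each voxel of a region carries weight
   $w_i = 1/n$ (uniform grid), so histogram indices are functionals of a
   probability distribution, independent of disc size and image
   resolution. On anisotropic grids the physical voxel volume is constant
   across the grid, so the uniform weights remain exact; slice gaps are
   not interpolated -- voxels are treated as samples of the underlying
   tissue.
2. **Reference division.** Intensities are divided by the volume-weighted
   mean of a reference tissue: **CSF**, whose composition is constant
   across subjects (so the division cancels the scanner gain), or
   **cancellous bone** of the vertebra above, which cancels the gain *and*
   folds in bone-remodelling signal, making it sensitive to severity
   differences. A `none` mode exists for phantom debugging only.

Gain invariance is exact by construction: multiplying the whole volume by
any $g > 0$ multiplies reference mean and voxel intensities alike. The
package's validation asserts that no CSF-normalized index moves by more
than $10^{-10}$ under $g \in \{0.5, 3, 10\}$; the observed deviation is at
the level of floating-point round-off ($\sim 10^{-14}$).

Negative intensities cannot occur in magnitude MR images but can arise in
synthetic data with additive noise; they are clipped to zero with a
warning before division.

## The eight histogram indices

For a region's normalized intensities $x_i$ with weights $w_i$
(`compute_index_set()`):

| index | definition | reads as |
|---|---|---|
| `std` | $\sigma = \sqrt{\sum w_i (x_i - \mu)^2}$ | width of the intensity peak; rises as NP/AF transition blurs |
| `sem` | $\sigma / \sqrt{n}$ | spread scaled by region size |
| `median` | weighted quantile at 0.5 | central tissue intensity |
| `sum_sq` | $\sum w_i x_i^2$ | bright (water-rich) signal mass |
| `p75` | weighted quantile at 0.75 | upper-intensity envelope |
| `max_bin_weight` | largest summed weight in one histogram bin | tissue homogeneity |
| `skewness` | $\sum w_i (x_i-\mu)^3 / \sigma^3$ | asymmetry of the distribution |
| `ks_distance` | $\sup_x |F_w(x) - \Phi(\tfrac{x-\mu}{\sigma})|$ | distance from a single-Gaussian (homogenised) disc |

Design choices that were genuinely open, and how they were settled:

* **Sum of squares is volume-weighted.** An unweighted sum would scale
  with voxel count, undoing step 1 of the normalization; the raw variant
  remains available via `sum_sq_weighted = FALSE`.
* **Standard error is $\sigma/\sqrt{n}$**, the standard meaning; it
  reproduces the expected co-movement with `std`.
* **The KS reference Gaussian is self-fitted** by the weighted mean and
  *population* standard deviation of the same region, and the statistic is
  computed on raw voxel values, not on a binned histogram (binning is used
  only by `max_bin_weight`; coarse bins would change the statistic). The
  supremum is evaluated on both sides of every ECDF step, so it is exact.
* **Weighted quantiles** interpolate the weighted CDF at plotting
  positions $p_i = (c_i - w_i)/(c_n - w_n)$ ($c_i$ = cumulative weight),
  chosen so that equal weights reproduce the standard linear-interpolated
  (type 7) sample quantile exactly. Quantile conventions differ between
  packages; this one was pinned by that reduction requirement.
* **Degenerate regions** (zero variance) return `NA` for skewness and KS
  distance -- undefined, not zero -- and propagate as missing values into
  cohort tables.
* **Histogram default**: bin width 0.01 normalized units over
  `(0, max)`, configurable via `histogram_spec()`.

## Centre geometry and volume ratio

The intensity-weighted centre $W = \sum I_i P_i / \sum I_i$ and the
geometric centre $G$ (plain centroid) of a region coincide for a
symmetric, uniformly bright disc. Their normalized distance

$$d = \frac{\lVert W - G \rVert}{N}$$

($N$ = voxel count of the region) measures the undirected displacement of
signal mass -- the imaging signature of nucleus migration in scoliotic
discs. Two conventions deserve note:

* The division by a *count* is implemented literally, so `d` carries
  resolution-dependent units (mm/voxel). Values are comparable only across
  matched grids; positions can alternatively be extracted in voxel-index
  units (`units = "voxel"`).
* $W$ uses the normalized intensities directly as weights (the sum runs
  over points); since the expression is scale-free, `d` is identical under
  CSF or bone normalization and invariant under gain. A volume-weighted
  variant exists for completeness (`use_weights = TRUE`).

The NP/IVD **volume ratio** is the voxel-count ratio of the segmented NP
to the whole disc -- integer-exact on one grid, around 0.25--0.27 for
healthy lumbar discs and lower in degenerated ones.

## Group statistics

Cohort tables (one value per subject x region x normalization x index) are
compared with the decision tree classical biostatistics software applies:

* **Gates:** Shapiro-Wilk on the group-mean-centred residuals and
  Levene's test across groups, both at $\alpha = 0.05$. Pooling the
  residuals for one normality test (rather than testing each group) is the
  convention of the classical packages this tree mirrors and gives a
  parametric selection rate near $(1-\alpha)^2 \approx 0.90$ for truly
  Gaussian groups.
* **One-way branch** (control / scoliosis / spondylolisthesis): ANOVA if
  the gates pass, otherwise Kruskal-Wallis with midrank tie correction.
  Post-hoc pairwise comparisons are attached only when the omnibus test
  rejects: Dunn's z-comparisons (Bonferroni-adjusted, tie-corrected) on
  the rank branch, pooled-SD t-tests with Holm adjustment on the
  parametric branch.
* **Two-way branch** (pathology x severity, control excluded): ordinary
  factorial ANOVA, or -- "ANOVA on ranks" -- the same linear model on the
  globally ranked values (the rank-transform method, the standard reading
  of that phrase). The group design is balanced, so sequential sums of
  squares are unambiguous.
* **Reporting:** `significance_report()` assembles the grid of
  comparisons x normalization x region x index with `*` (p < 0.05) and
  `**` (p < 0.01); the two-level notation is configurable. No
  multiple-testing correction is applied across the grid by default, for
  fidelity with the way such grids are conventionally reported; a
  Benjamini-Hochberg option exists (`adjust = "BH"`).

The type-I error of the *composed* procedure (gate, then branch) is a
property, not an assumption: over 2000 simulated null cohorts (3 groups of
8) the rejection rate at $\alpha = 0.05$ comes out near 4.8%.

## The synthetic phantom

No patient images ship with the package; the phantom generator is the test
bed. It emulates, at research resolution, the features of a sagittal
T2-weighted lumbar acquisition that the indices respond to -- and nothing
more:

* **Geometry:** an ellipsoidal IVD (default semi-axes 16 x 12 x 6 mm on a
  48 x 36 x 20 voxel, 1 mm grid) containing a nested NP ellipsoid whose
  semi-axis scale sets the analytic volume ratio (default
  $\approx 0.247$); two 8^3-voxel reference blocks (CSF, bone) of constant
  composition outside the disc; uniform soft-tissue background.
* **Intensities:** piecewise-constant tissue values (NP 200, AF 60, CSF
  240, bone 90, background 20, arbitrary units), multiplicative gain, and
  additive Gaussian noise (sd 5). Rician magnitude noise is deliberately
  not modelled: at these signal-to-noise levels the Gaussian
  approximation is standard, and additive symmetric noise keeps the
  analytic oracles exact.
* **Degeneration** $\delta \in [0,1]$: the NP intensity blends linearly
  toward the AF value and the tissue boundaries are blurred with a
  Gaussian of sd $3\delta$ mm. This minimal model reproduces the expected
  index signatures: annulus `std` and `sum_sq` rise (bright NP signal
  leaks into the AF), and the whole-disc KS distance falls (the bimodal
  NP/AF histogram homogenises toward a single Gaussian). Monotonicity is
  asserted over the ladder $\delta = 0, 0.1, \ldots, 0.4$; beyond
  $\delta \approx 0.5$ the annulus `std` saturates as the NP/AF contrast
  itself vanishes, which is why the ladder stops at 0.4. Note the KS trend
  is a whole-disc property: an undegenerated annulus alone is just
  constant tissue plus Gaussian noise, whose KS distance is already near
  zero.
* **Nucleus displacement:** `np_offset` shifts the NP ellipsoid (with a
  surface-sampled containment check against the IVD). With uniform
  tissues, displacement alone cannot separate the NP's *own* weighted and
  geometric centres; physically, a migrating nucleus dehydrates
  asymmetrically. The phantom therefore imposes a linear intensity
  gradient inside the NP along the displacement direction with relative
  magnitude `np_gradient * |offset|` (default 0.08 per mm, capped at
  0.9), giving $d(\mathrm{NP}) \propto |\mathrm{offset}|$ -- strictly
  monotone over the 0--4 mm ladder even in the presence of noise. Setting
  `np_gradient = 0` recovers the exact two-tissue phantom whose
  intensity-weighted centroid has a closed form (used as an analytic
  oracle in the tests).
* **Determinism:** every phantom is bit-reproducible from its seed, and
  the generator restores the caller's RNG state.

### Cohort simulation

`cohort_spec()` describes the five study groups (16 low/high scoliosis, 16
low/high spondylolisthesis, 15 controls -- 79 subjects) as distributions
over the parameters that carry the group differences: target volume ratio
(control mean 27.0% sd 6.3%, pathological groups 18--22%, the ranges
reported for such cohorts), NP displacement magnitude (about 2 mm in
scoliosis versus about 1 mm in control, direction uniform in the disc
plane), degeneration (higher at high severity), and a 5% disc-size jitter.
These defaults were fixed once, from the cohort literature and anatomical
plausibility, and define the simulation conditions; they are not tuning
knobs. Per-subject parameters and noise seeds all derive from one master
seed.

What the phantom does *not* emulate -- and therefore what passing tests do
not demonstrate about real data: anatomical shape variation beyond
ellipsoids, partial-volume structure of thick-slice sagittal acquisitions,
bias fields, Rician noise floors, segmentation error, and any correlation
structure between indices within a subject. The phantom validates the
*estimators and the statistical machinery*, not the clinical effect sizes.

## Numerical choices and degenerate inputs

* Positions are voxel centres mapped through the NIfTI affine (0-based
  indices); the sform is preferred over the qform on read.
* The KS supremum is evaluated exactly at ECDF steps (both sides), with
  tied values merged into single steps.
* Histogram bins are right-closed; a value exactly at the range minimum
  falls in the first bin; values outside a fixed range are excluded while
  the denominator remains total region volume.
* Empty regions, misaligned masks, non-positive reference means, all-zero
  intensities, sub-3-subject groups and empty design cells raise errors
  that name the offending stage; `cmd_indices()`/`cmd_cohort()` prefix
  the pipeline stage.
* All-identical design cells in the two-way model yield F = 0, p = 1
  (rather than 0/0).

## Problem sizes used in validation

The shipped validation runs at deliberately modest scale so the whole
suite executes in minutes: phantoms of 48 x 36 x 20 voxels, 20-phantom
gain-invariance sweeps, 2000 value-level null cohorts for the type-I
check, and 200 full image-level cohort replicates (79 subjects each) for
the power check of a 2-sigma volume-ratio deficit, which is detected in
essentially every replicate. Doubling the grid (96 x 72 x 40 at 0.5 mm)
is exercised once to confirm resolution robustness: volume-fraction
weighted indices are Riemann-sum approximations of tissue integrals and
move by only a few percent, while the voxelization error of the volume
ratio at least halves.

## Known limitations

* `d` is resolution-dependent by construction (distance divided by a
  count); cross-study comparisons require matched grids.
* The bone reference accepts any BONE-labelled region; whether a cuboid
  sample or a whole vertebral body is used is the mask author's choice.
* The rank-transform two-way ANOVA is an approximate non-parametric
  procedure; its interaction test in particular is known to be liberal
  under some alternatives.
* Multiple disconnected components under one label are accepted silently;
  cleaning segmentation artifacts is the caller's responsibility.
* DICOM input, registration, bias-field correction and segmentation are
  explicitly out of scope.
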