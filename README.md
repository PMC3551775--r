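# amrsid

Analysis of MR signal intensity distribution in intervertebral discs.

Early disc degeneration in spinal deformities (adolescent idiopathic
scoliosis, spondylolisthesis) changes the water and proteoglycan content of
the nucleus pulposus (NP) and annulus fibrosus (AF) — and with it the
distribution of T2-weighted MR signal inside the disc — before anything is
visible on the images themselves. `amrsid` turns a T2-weighted NIfTI volume
and an aligned region label mask into quantitative per-disc indices, and
compares them across patient groups. It is aimed at spine-imaging
researchers who already have segmentations (the package does not segment)
and want reproducible distribution biomarkers.

## What it computes

For each disc region (IVD, NP, AF), after normalizing intensities by the
mean signal of a constant-composition reference tissue (cerebrospinal
fluid, or cancellous bone of the vertebra above):

- **Eight first-order histogram indices** of the volume-fraction-weighted
  normalized intensities \(x_i\) (weights \(w_i = 1/n\)): standard
  deviation \(\sigma = \sqrt{\sum_i w_i (x_i - \mu)^2}\), standard error
  \(\sigma/\sqrt{n}\), median, sum of squared values
  \(\sum_i w_i x_i^2\), 75th percentile, modal histogram bin mass,
  skewness \(\sum_i w_i (x_i-\mu)^3/\sigma^3\), and the
  Kolmogorov–Smirnov distance
  \(\sup_x \lvert F_w(x) - \Phi((x-\mu)/\sigma)\rvert\) to the Gaussian
  fitted to the same region.
- **Centre geometry**: the intensity-weighted centre
  \(W = \sum_i I_i P_i / \sum_i I_i\), the geometric centre \(G\), and
  their normalized distance \(d = \lVert W - G\rVert / N\) — the
  undirected signature of nucleus migration.
- **NP/IVD volume ratio**: the voxel-count ratio of nucleus to whole disc.
- **Cohort statistics**: a parametric/rank decision tree (Shapiro–Wilk and
  Levene gates at 0.05; one-way ANOVA or Kruskal–Wallis with Dunn's
  post-hoc across pathology groups; two-way or rank-transform ANOVA for
  pathology × severity), summarised as a significance grid with `*`
  (p < 0.05) and `**` (p < 0.01).

A fully controlled synthetic phantom generator (ellipsoidal disc, nucleus
displacement, degeneration blend + blur, reference blocks, gain, noise)
provides an end-to-end test bed without patient data; see the methods
vignette (`vignettes/amrsid-methods.Rmd`) for the model and all design
decisions.

## Worked example

```r
library(amrsid)

# a degenerated disc with a 2 mm nucleus displacement
ph  <- generate_phantom(phantom_spec(seed = 42, degeneration = 0.2,
                                     np_offset = c(2, 0, 0)))
res <- disc_indices(ph$volume, ph$mask)
res
```

```
<amrsid_indices>
  reference means: csf = 213, bone = 81.38
  NP/IVD volume ratio: 0.2426 (1180/4864 voxels)
 region normalization     std       sem median  sum_sq    p75 max_bin_weight
    IVD           csf 0.21090 0.0030240 0.2929 0.20170 0.4620        0.07196
    IVD          bone 0.55200 0.0079150 0.7668 1.38200 1.2090        0.02961
     NP           csf 0.08616 0.0025080 0.7620 0.57160 0.8153        0.05678
     NP          bone 0.22550 0.0065650 1.9940 3.91600 2.1340        0.02797
     AF           csf 0.05645 0.0009301 0.2747 0.08328 0.3062        0.09501
     AF          bone 0.14780 0.0024350 0.7190 0.57060 0.8014        0.03909
 skewness ks_distance         d    N
   1.1600     0.26040 1.002e-04 4864
   1.1600     0.26040 1.002e-04 4864
  -0.3928     0.05459 2.335e-04 1180
  -0.3928     0.05459 2.335e-04 1180
   1.0600     0.09654 2.116e-05 3684
   1.0600     0.09654 2.116e-05 3684
```

Reading the output: CSF-normalized median AF intensity sits near 0.27 (the
annulus is dark relative to CSF) while the NP median is 0.76; the
whole-disc KS distance of 0.26 reflects the still-bimodal NP/AF histogram
(a healthy disc starts near 0.40, and it falls toward zero as degeneration
homogenises the disc); the displaced, asymmetrically bright nucleus yields
a non-zero centre distance `d` (2.3e-4 mm/voxel for the NP, versus ~1e-6
for a symmetric disc). The volume ratio 0.243 is the voxelized version of
the spec's analytic ellipsoid ratio 0.247.

File-level wrappers mirror the same pipeline for batch use
(`cmd_indices()` writes per-subject CSV rows; `cmd_cohort()` joins them
with a group table and writes the significance grid), and `exec/amrsid`
exposes `indices`, `cohort`, `phantom`, `simulate-cohort` and `full-run`
subcommands for shell use.

Cohort-level simulation:

```r
tab <- simulate_cohort_indices(cohort_spec(seed = 1))   # 79 subjects
significance_report(tab)
```

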