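---
title: "Topological inference on statistical maps: peak FDR, peak FWE and their evaluation"
author: "PeakFDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological inference on statistical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PeakFDR)
```

## The inferential problem

Statistical parametric maps (SPMs) arising in neuroimaging and other
image-based sciences are lattice samples of an underlying *continuous*
random field: reconstruction and smoothing guarantee that signal, where it
exists, has smooth and in principle unbounded spatial support. Voxel-wise
multiple-testing corrections are then conceptually awkward — every voxel
carries some signal, so the voxel-level false discovery rate of a non-null
map is, strictly, zero. The natural objects of inference are instead
*topological features* of the map: local maxima (peaks) and connected
suprathreshold components (clusters).

This package implements error control over those features:

* **peak FWE** — classical random-field-theory control of the family-wise
  error of peaks, via the expected Euler characteristic of the excursion
  set;
* **peak FDR** — Benjamini–Hochberg (BH) control of the false discovery
  rate over peaks, applied to conditional peak p-values derived from
  Euler characteristic densities;
* **cluster FDR** — BH over conditional cluster-extent p-values;
* **voxel FDR** — the conventional BH procedure over voxel-wise marginal
  p-values, retained as a comparator.

It also implements the Monte-Carlo harness used to compare these
procedures: a generator of smooth-noise t-maps with planted smooth
activations, the minimum-distance spatial-accuracy statistic, and
sensitivity ratios.

## The model

### Geometry: resels and EC densities

For a stationary field searched over a box of `shape` voxels with voxel
size and per-axis smoothness FWHM, the geometry enters through the resel
counts \(R_0,\dots,R_D\) (`SearchSpace`): \(R_0 = 1\) (the Euler
characteristic of a box), \(R_D\) the volume divided by the product of
FWHMs, intermediate counts the elementary symmetric sums of the side
lengths in FWHM units. The expected Euler characteristic of the excursion
set above \(u\) is

\[
E[\chi_u] \;=\; \sum_{d=0}^{D} R_d\, \rho_d(u),
\]

where \(\rho_d\) are the EC densities of the field family (`ecDensity`;
the standard closed forms for Gaussian and t fields, \(d \le 3\)). At
high thresholds almost every component of the excursion set is a simple
blob containing one peak, so \(E[\chi_u]\) approximates both the expected
number of peaks (`expectedPeaks`) and, when small, the probability of any
peak — the FWE-corrected peak p-value (`peakPFwe`, inverted by
`fweThreshold`).

### Conditional peak p-values

For a peak of height \(z\) harvested above a feature-defining threshold
\(u\), the uncorrected p-value is the conditional exceedance probability

\[
p_u(z) \;=\; P(Z > z \mid Z > u) \;\approx\; \frac{\rho_D(z)}{\rho_D(u)},
\]

the ratio of the rates at which the field emits peaks above the two
heights. Only the top-dimensional density is used: the resel counts
cancel in the ratio, which is also why the quantity is independent of the
search volume. For t fields this reduces to a ratio of
\((1+z^2/\nu)^{-(\nu-1)/2}\left(\frac{\nu-1}{\nu}z^2 - 1\right)\) terms.
These p-values (`peakPUncorrected`) feed the BH step-up rule
(`bhSelect`), and each peak receives the corresponding step-up adjusted
q-value (`qValues`) — the smallest FDR level at which it would be
declared.

Two validity guards reflect the approximation's domain. The polynomial
factor of \(\rho_D\) changes sign at a root (\(z = \sqrt{\nu/(\nu-1)}\)
for 3D t fields, \(z = 1\) Gaussian); thresholds at or below it are
refused. And because excursion components only remain simple blobs at
reasonably high thresholds, `u < 2.5` triggers a warning rather than an
error: the user may proceed knowingly.

The BH rule is applied under independence of the peak p-values, motivated
by Poisson clumping: for smooth fields searched over domains much larger
than their correlation length, the heights of distinct peaks are
effectively independent of each other and of the (random) number of
peaks. A Benjamini–Yekutieli variant (`method = "BY"`) is available for
sensitivity analysis. FDR control over peaks is only meaningful when many
peaks are harvested; `runProcedure` warns below 20.

### Cluster extents

The cluster-FDR comparator assigns each cluster the conditional
probability that a cluster's extent \(S\) (in resels) reaches its
observed size, \(P(S \ge s) = \exp(-\beta s^{2/D})\), with \(\beta\)
calibrated so that the implied mean extent equals the expected
suprathreshold volume divided by the expected cluster count — both
available in closed form (`clusterExtentP`). This is the classical
stationary-field extent approximation. Measuring extent in resels makes
the model smoothness-invariant. Whether a Gaussianised or native-t extent
law is preferable is genuinely open; we use the field's own EC densities
and marginal for the calibration and flag that the approximation is
coarse on discrete lattices (see below).

### The four decision procedures

`runProcedure` applies one procedure at level \(\alpha\):

| procedure | family tested | needs `u` | discovery set |
|---|---|---|---|
| `peak_fwe` | peaks above `u` | yes | peaks with FWE p \(\le \alpha\) |
| `peak_fdr` | peaks above `u` | yes | BH over conditional peak p |
| `cluster_fdr` | clusters above `u` | yes | peaks inside BH-significant clusters |
| `voxel_fdr` | all in-mask voxels | no | local maxima among BH-surviving voxels |

For comparability of the evaluation metric, cluster-FDR discoveries are
represented by *every* peak inside a significant cluster, and voxel-FDR
discoveries by the local maxima of the surviving voxel set — both choices
keep the accuracy statistic defined on peaks for every procedure.

## Topological feature extraction

Local maxima are voxels exceeding all neighbours under 26-connectivity
(strict inequality; ties have measure zero in continuous fields, and a
`plateau` flag reports the first voxel of a tied plateau for integer-like
toy inputs). Clusters use 18-connectivity, the SPM convention; both are
configurable. Missing neighbours — outside the lattice or masked
(`NA`) — count as \(-\infty\), so boundary voxels can be maxima, which
matches harvesting behaviour on masked data. Both kernels are small C++
routines; no pre-installed R package labels 3D lattices under these
connectivities.

When smoothness is not known, `estimateFwhm` recovers per-axis FWHM from
the variance of spatial derivatives of standardised residual fields via
the stationary identity \(\mathrm{FWHM} = \sqrt{4\log 2 /
\operatorname{Var}(\partial r/\partial x)}\); simulations use the known
kernel width instead.

## The simulation harness

`simulateSpm` reproduces the evaluation design: each replicate simulates
16 volumes, each the sum of a fixed activation pattern and independent
smooth Gaussian noise, then forms the voxel-wise one-sample t statistic
(15 degrees of freedom). Defaults, which are the study conditions:

* **lattice** 64×64×32, unit voxels. The simulation grid is not stated in
  the source design; this matches the real-data matrix size the design
  mirrors and keeps a full experiment tractable on one CPU. Configurable.
* **noise**: white Gaussian fields convolved with a Gaussian kernel of
  FWHM 4 voxels ("width" is read as FWHM, the unit used for smoothness
  throughout this literature), truncated at ±4 SD. Convolution is
  circular (FFT), making the field exactly stationary; the marginal
  variance is rescaled to 1 analytically via the kernel's \(\ell_2\)
  norm, not estimated.
* **signal**: `n` activations per map, centred uniformly at random
  (keeping a 4-voxel border margin so true peaks are interior — boundary
  peaks would distort the distance metric; disable with `margin = 0`).
  Each is a Gaussian bump with unit peak height scaled by an amplitude
  drawn from \(\chi^2_1\) and a kernel FWHM drawn from Gamma(shape 1,
  scale 4) — mean 4, variance 16 — truncated below at 4 by rejection
  sampling, so activation widths are bounded below by the noise
  smoothness (truncated mean 8, by memorylessness). Unit-peak rather
  than unit-mass kernels are used, so the sampled amplitude *is* the true
  peak height of the contribution; the alternative normalisation would
  make every activation undetectably small. Overlapping bumps sum.
  The signal is identical across volumes (a fixed effect), which is what
  the one-sample t is sensitive to.

Everything is reproducible bit-for-bit given a seed.

### Evaluation metrics

For each procedure's discoveries, `minDistances` computes the Euclidean
distance from each discovered peak to the nearest true activation centre;
`accuracyCurve` pools these over replicates into an empirical CDF
\(\Phi_{proc}(d)\) on a common grid (default 0–16 voxels in 0.25 steps),
and `accuracyContrast` forms \(\Phi_{FWE}(d) - \Phi_{proc}(d)\), the loss
of spatial accuracy relative to the peak-FWE reference, plus the paired
values for ROC-style plots. `sensitivityRatio` reports total discoveries
relative to peak-FWE. `runExperiment` loops replicates × activation
counts × thresholds and returns tidy tables; one FWHM (4 voxels) is the
conventional yardstick distance.

## Numerical choices

* `fweThreshold` brackets on the admissible range and bisects to within
  \(10^{-8}\) in probability.
* The expected-EC approximation to \(P(\text{any peak} \ge z)\) is used
  only where it is a probability: below the validity bound, or wherever
  the expected EC reaches 1, the FWE p-value is clipped to 1 (at low
  thresholds the EC is not even positive — the excursion set has
  handles).
* BH with zero harvested features returns an empty result, not an error
  (the number of tests is itself random; an empty family is a legitimate
  outcome).
* Probabilities are serialised to 6 decimals, statistic values to 4.

## What the simulations do and do not show

The generator emulates stationary smooth Gaussian noise with a fixed,
known smoothness and fixed-effect activations. It does not emulate
temporally correlated fMRI noise, non-stationary smoothness, physiological
artefacts, or signal height distributions other than \(\chi^2_1\) — so
green simulation results certify the procedures' calibration under the
stated model, not under arbitrary real data.

Two systematic effects of the lattice deserve explicit mention, because
they shape what calibration tests can honestly assert:

* **Discretisation.** Peaks live between voxels; sampling on a lattice
  biases observed peak heights and counts downward, the more so the
  coarser the lattice relative to the smoothness and the heavier the
  field's tails (t(15) spikes are spatially sharper than Gaussian peaks).
  At FWHM 8 voxels, Gaussian-field maxima counts match the expected-EC
  prediction closely (within Monte-Carlo error at \(u = 3\)); at FWHM 4,
  counts sit several percent below, and t(15) conditional peak p-values
  are visibly conservative (empirical exceedance below the EC-density
  ratio). The conservative direction is the safe one: empirical null
  error rates fall below nominal (measured null FWER ≈ 0.01 at nominal
  0.05; null peak-FDR "any discovery" rate ≈ 0.01 at nominal 0.05).
  Monte-Carlo oracle tests therefore validate the closed forms in the
  smooth regime (FWHM 8) where the continuum approximation is resolvable.
* **Wide activations scatter discoveries.** Under the width law above,
  a minority of activations are much wider than the noise smoothness
  (P(FWHM > 16 voxels) = 5%). A wide, strong activation elevates a broad
  dome of the t-field on which noise ripples create many genuine
  suprathreshold maxima, all of which count as discoveries but lie 5–15
  voxels from the single planted centre. Pooled over replicates this
  dominates the distance distribution: the fraction of peak-FWE
  discoveries within one noise FWHM of a true centre is ≈ 0.44 under
  these conditions, rising to ≈ 0.98 when all activation widths equal
  the noise FWHM. The within-one-FWHM accuracy headline is therefore a
  property of narrow-activation regimes; with heterogeneous widths the
  *relative* comparisons between procedures (orderings of accuracy
  contrasts and sensitivity ratios, which this package's tests verify)
  are the robust conclusions.

## Problem sizes used by the test suite

The packaged tests run the full design at reduced scale, chosen to keep a
complete run desk-sized while leaving Monte-Carlo error well inside each
assertion's margin: 200 replicates for the spatial-accuracy pooling, 1000
pure-noise replicates for null FDR calibration, 100 replicates (n = 16
activations, u ∈ {2.5, 3.5, 4.5, 5.5}) shared by the sensitivity- and
accuracy-ordering checks, 320 smooth fields for the expected-peak and
p-value-uniformity oracles, and 10⁴ random p-lists for exhaustive BH
equivalence.

## Limitations

* EC densities are implemented for Gaussian and t families, \(d \le 3\);
  F and \(\chi^2\) fields are an extension point.
* The search region is treated as a box (\(R_0 = 1\)); small-volume
  masks with nontrivial topology are out of scope, as are non-stationary
  (Lipschitz–Killing) geometry and surface meshes.
* Sub-voxel peak interpolation and watershed partitioning of clusters are
  not attempted.
* The minimum-distance statistic is pragmatic: with several discoveries
  per activation it double-counts accuracy, and no one-to-one matching
  is implemented.

## A worked miniature

```{r mini, eval = FALSE}
set.seed(1)
sim <- simulateSpm(nActivations = 8)          # 64x64x32, 16 volumes, t(15)
res <- runProcedure(sim$map, "peak_fdr", u = 2.5,
                    space = sim$space, field = sim$field)
res
summary(minDistances(res, sim$truth))
```
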