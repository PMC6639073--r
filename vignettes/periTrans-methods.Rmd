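---
title: "Quantifying peripheral RNA localization and local translation: models and methods"
author: "periTrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peripheral RNA localization and local translation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periTrans)
```

# The scientific problem

Many mRNAs are transported to the periphery of migrating cells — to
lamellipodia and the tips of protrusions — and the question this package's
tool chain addresses is whether they are *translated* there. Two kinds of
data answer it:

1. **Single-molecule two-channel imaging.** Individual reporter mRNAs are
   visible as diffraction-limited spots in an RNA channel (bacteriophage
   hairpin arrays bound by a coat protein fused to mCherry), while their
   nascent polypeptides are visible in a second channel (a repeated epitope
   array on the nascent chain bound by scFv-GFP). A spot that is bright in
   both channels is a translation site; an RNA spot with no GFP enrichment
   is translationally silent.
2. **Polysome gradient fractionation read by direct RNA counting.** A
   sucrose gradient is divided into four fractions — F1 free RNPs and
   ribosomal subunits, F2 80S monosomes, F3 light polysomes, F4 heavy
   polysomes — and each fraction receives an equal amount of an in vitro
   transcribed spike RNA before counting, so that per-fraction recovery
   losses can be corrected. The proportion of a transcript in F3+F4 is its
   *translated fraction*.

The package implements the full quantitative chain for both: sub-pixel
spot localization, per-particle translation efficiency, distance-to-edge
statistics, single-molecule versus RNA-cluster classification, and
spike-normalized fraction analysis — plus a seeded synthetic-data
generator that produces images and count tables with known ground truth,
so every estimator is validated by recovery rather than by eye.

# Spot localization by iterative Gaussian masking

Diffraction-limited spots are detected with a scale-normalized
Laplacian-of-Gaussian filter matched to the point spread function
(isotropic Gaussian, default $\sigma = 1.3$ px at 0.16 µm/px, typical for
a 63×/1.4 NA confocal). Candidates are local maxima whose response
exceeds `snrThreshold` (default 5) times a MAD-based robust estimate of
the filtered image's noise. When a cell mask is supplied, pixels outside
it are filled with the in-mask median intensity before filtering;
otherwise the intensity step at the membrane rings the filter and
produces spurious maxima along the cell outline.

Each candidate is then refined by **iterative Gaussian-mask fitting**:

* the local background is the median of an annulus of radii
  $3\sigma$–$5\sigma$ around the candidate, and is subtracted;
* the position estimate is the centroid of the background-subtracted
  window weighted by a unit-height Gaussian of width $\sigma$ centred at
  the current estimate, iterated until the update falls below `tol`
  (0.01 px) or `maxIter` (50) is reached;
* the integrated intensity uses the mask-photometry convention
  $\hat I = \frac{\sum S M}{\sum M^2}\, 2\pi\sigma^2$, under which a
  noiseless Gaussian of amplitude $A$ returns its volume
  $2\pi\sigma^2 A$.

$\sigma$ is a fixed, known input, not a fitted parameter — the standard
assumption of this estimator family. The window half-width defaults to
$\lceil 4\sigma \rceil$. In the test suite the mask fit is compared
against an independent nonlinear least-squares Gaussian fit on simulated
spots; at 2000 photons on a 50 photon/px background the localization RMSE
is about 0.05 px with bias below 0.01 px, and mask and least-squares
positions agree to better than 0.05 px.

`measureAt()` applies the same photometry *without* re-centring, which is
how nascent-chain (GFP) intensity is recorded at an RNA spot's position:
the analysis is RNA-anchored, so a silent RNA yields a GFP measurement of
the diffuse background rather than being missed entirely.

Tracking is deliberately minimal: greedy mutual-nearest-neighbour linking
under a displacement gate, followed by a persistence filter that keeps
tracks longer than six frames (default `minFrames = 7`) with RMS
positional deviation at most 1 px. The analysis targets *stationary*
particles; for these, greedy linking is equivalent to global assignment,
and no gap closing or motion model is needed. Transport kinetics are out
of scope.

# Translation efficiency per particle

Raw spot intensities depend on illumination, expression level of the free
fluorophore pools, and depth; the comparable quantity is the intensity
*relative to the nearby diffuse cytoplasm*. `normalizeToLocalCytoplasm()`
returns

$$\mathrm{norm} = \frac{\overline{I}_{\mathrm{disc}} - o}
                       {\overline{I}_{\mathrm{annulus}} - o},$$

where $o$ is the camera offset, the disc has radius $2\sigma$, and the
annulus spans $5\sigma$–$9\sigma$, intersected with the cell mask and
excluding pixels within $2\sigma$ of any other detected spot. A value of
1 means no local concentration. Restricting both disc and annulus to the
cell mask matters near the edge: pixels beyond the membrane carry no
diffuse fluorophore and would dilute the means, imprinting a spurious
distance dependence on every normalized quantity.

Per-particle translation efficiency is the ratio of normalized
intensities,
$\mathrm{eff} = \mathrm{gfp_{norm}} / \mathrm{mcherry_{norm}}$, which is
invariant to global illumination scaling (verified to $10^{-9}$ in the
noiseless tests). A raw-intensity ratio mode exists behind
`efficiencyMode = "raw"` for completeness. Whether per-spot ratios should
use integrated or peak intensities is genuinely open; integrated
intensities are used because they are what the mask estimator returns
unbiasedly.

Condition contrasts (for example before and after puromycin, which
releases nascent chains and collapses the GFP signal) use Welch's
two-sample t-test. A particle is flagged *translating* when its
normalized GFP exceeds a threshold derived from translation-free control
simulations ($1 + 3\,\mathrm{SD}$ of the null `gfp_norm`).

# Spatial statistics

Distances from the cell edge are read from the Euclidean distance
transform of the cell mask, bilinearly interpolated at sub-pixel
positions, with mask pixels adjacent to background placed half a pixel
from the boundary line. The transform agrees with a brute-force
point-to-polygon-segment oracle to within 1.5 px in the tests; the one
systematic exception is the exact centre of a circularly symmetric cell,
where bilinear interpolation at the ridge of the distance map can cost up
to about one extra pixel. The peripheral *band* mask uses
pixel-touches-band membership (a pixel belongs to a band of any positive
width if any part of it lies inside), so an infinitesimally thin band is
exactly the boundary-adjacent pixel ring and a 2 µm band on a 10 µm disc
matches the analytic annulus area to a few percent.

Efficiency-versus-distance association is summarized by the Pearson
correlation with a Fisher-z 95% confidence interval, and visualized with
a local-linear (loess, degree 1) trend plus a seeded bootstrap pointwise
95% band — chosen over parametric curves because no functional form is
assumed for the trend. Cumulative distance distributions report the
median and the fraction within a query band.

The **peripheral distribution index** (PDI) describes a whole cell's
signal distribution in one scalar. The definition adopted here is the
second moment of the signal about the nucleus centroid, normalized by the
same moment of a uniform distribution over the cell mask:

$$\mathrm{PDI} = \frac{\sum_i w_i d_i^2 / \sum_i w_i}
                      {\langle d^2 \rangle_{\text{cell mask}}}.$$

PDI is exactly 1 for uniform signal, 0 for signal at the nucleus
centroid, above 1 for peripherally biased signal; it is invariant to
intensity scaling and strictly increases when mass moves outward (all
verified, including against a direct double-sum oracle). Both
intensity-weighted and equal-weighted (particle-counting) modes are
available, with intensity weighting the default, since whether the
original index weighted particles by brightness is not recorded.

# Single RNAs versus RNA clusters

Endogenous transcripts at protrusion tips occur either as single
molecules or as multi-RNA clusters. Classification is intensity-based:

* the **unit intensity** of a single molecule is the mode of a Gaussian
  kernel density (Silverman bandwidth) over the population of integrated
  intensities — robust to a minority cluster tail — with a robust spread
  (MAD of intensities within ±50% of the mode). If less than 40% of the
  mass is near the mode the estimate is flagged as lacking a dominant
  single-molecule peak;
* three classification rules are provided: *absolute* (replicating
  instrument-specific cutoffs such as "above 400 a.u."), *relative*
  (above unit $+ 3\,\mathrm{SD}$, the default), and *copies*
  (rounded intensity ratio at least 2). Estimated copy numbers are
  rounded intensity ratios. On mixtures of singles (20% CV) and 4–12-copy
  clusters, the relative rule reaches sensitivity and specificity above
  0.95, and the median estimated copy number is exact for k = 2..8.

Contingency comparisons of single/cluster composition between regions or
RNA species use Fisher's exact test, two-sided as the sum of all tables
(with fixed margins) whose probability does not exceed that of the
observed table — stated explicitly because two-sided conventions differ.
The test suite verifies equality with an exhaustive hypergeometric
enumeration to $10^{-10}$ on a thousand random small tables. Tables with
a zero margin return p = 1 with a warning. Larger-than-2×2 tables fall
back to a seeded Monte-Carlo p-value above a total count of 200.

Cluster–cluster overlap (for example of a specific transcript's clusters
with polyadenylated-RNA granules) is the fraction of A-clusters with a
B-cluster within 0.5 µm. Protrusion ROIs are scored positive when they
contain at least one cluster call, or by a mean-intensity criterion
(background + 3 SD) when only an image is available; the two-channel
version emits the four-way presence/absence breakdown.

# Polysome fraction analysis

Spike normalization multiplies fraction $f$ by
$\bar s_g / s_f$, where $s_f$ are the spike counts and $\bar s_g$ their
geometric mean; the operation is idempotent and removes per-fraction
recovery distortions exactly in expectation. Distributions across
fractions are row-normalized proportions, averaged across replicates;
statistics are computed **on proportions**, not raw counts, because the
scientific claims concern distribution shape and spike normalization has
already absorbed recovery effects.

Condition contrasts fit, per gene, a two-way ANOVA of proportions on
condition × fraction and test the treated-minus-control difference within
each fraction, adjusting the four contrasts jointly by the single-step
multivariate-t method (Dunnett-style cell-mean contrasts, via
`multcomp::glht`). Because the four proportions of a replicate sum to 1,
their errors are negatively correlated, which the two-way ANOVA does not
model; empirically this leaves the per-gene familywise error near
0.05–0.06 at three replicates, within the package's stated control target
of 0.07.

Protrusion/cell-body (Ps/CB) enrichment ratios require the two sample
types to be made comparable; since the original co-normalization is not
recorded, the default equalizes the geometric mean of a declared set of
non-enriched control genes between the Ps and CB samples (total-count
normalization is available). Group-level treatment effects are tested by
two-way ANOVA on log ratios with Bonferroni-adjusted per-group contrasts.

# The synthetic-data generator

The generator defines the study conditions under which everything above
is validated. It emulates:

* **Cell geometry** — a star-shaped, simply connected cell built from a
  smoothly perturbed radial outline with optional narrow protrusions
  whose tips are recorded, and an elliptical nucleus; rasterized at
  0.16 µm/px by default.
* **Particle placement** — single molecules follow an exponentially
  tilted spatial density in edge distance whose tilt rate is *calibrated
  on the given geometry* so that the realized distance median equals the
  stated value: 5 µm for localized species, 15 µm for the control law.
  Calibration keeps per-pixel weights bounded (a naive inverse-area
  weighting stacks particles on the few deepest pixels of the distance
  map, which corrupts downstream photometry), at the cost that a small
  cell may truncate the achievable median below the target. Multi-copy
  clusters (discrete-uniform 4–12 copies) are confined to a 2 µm band
  around protrusion tips and carry zero ribosome load — the
  translationally silent state.
* **Ribosome load** — Poisson with mean 6 for translating singles, drawn
  independently of position. This is the null against which the
  efficiency-versus-distance statistics are calibrated.
* **Optics and camera** — pixel-integrated Gaussian PSFs
  ($\sigma = 1.3$ px), expected photons per RNA copy 2000 (mCherry) and
  per ribosome 1000 (GFP), diffuse background 50 photons/px in each
  channel inside the mask, then Poisson shot noise, gain, additive
  Gaussian read noise (SD 2), offset 100 counts, 16-bit clipping. The GFP
  per-ribosome budget is set so that an average translation site stands
  out five- to six-fold over the diffuse scFv-GFP pool — the regime in
  which translation sites are unmistakable bright spots; no quantitative
  intensity calibration exists to infer it from, so it is a stated study
  condition of the generator, not an estimate.
* **Motion** — stationary particles oscillate with small amplitude;
  a diffusing fraction performs free 2D Brownian motion; a minority runs
  directionally; frames are 0.5 s apart.
* **Count tables** — negative-binomial gene counts with mean
  `libraryScale × profile × recovery` (dispersion 0.05, per-gene
  log-normal abundance with 25% CV shared across conditions), and
  *Poisson* spike-in counts: a spike-in is a technical control carrying
  counting noise only, with recovery differences expressed through the
  recovery factors it exists to correct. Giving the spike the biological
  dispersion would inject heavy-tailed ratio noise that does not belong
  to it and measurably inflates the downstream ANOVA's false-positive
  rate. The default design mirrors the study: 20 APC-dependent genes, 6
  APC-independent, 8 controls, 3 replicates, and a puromycin condition
  that shifts profiles from (0.10, 0.15, 0.30, 0.45) to
  (0.35, 0.35, 0.20, 0.10).

What the generator does **not** emulate: 3D PSFs, spectral bleed-through,
photobleaching, cell motility and retraction dynamics, uneven
illumination, and autofluorescence structure. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimators
under the stated model, not robustness to every artifact of real
microscopy.

# Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col) with pixel centres at integers;
  distances convert to µm only at the API boundary (`*_um` columns).
* Constant or empty images yield empty candidate lists, not errors; a
  localization whose estimate escapes its window raises an error that
  batch callers count in a QC log.
* `compareRegions` with a zero margin returns p = 1 with a warning;
  zero-variance inputs to the correlation analysis raise errors.
* Fraction profiles must sum to 1 within $10^{-9}$; proportions are
  re-normalized after replicate averaging to absorb rounding drift.
* All random stages accept explicit seeds, restore the caller's RNG
  state, and reproduce bitwise.

# Problem sizes used by the test and acceptance runs

The shipped checks run at sizes chosen to make sampling error small
relative to the tolerances while completing comfortably on one CPU:
500 spots for localization accuracy, 100 seeded runs of 300 particles for
the null-correlation coverage, 1000-particle intensity mixtures for
cluster calling, 1000 random tables for the Fisher enumeration check,
100 seeded simulations for the polysome shift detection, and a
2000-gene null for the familywise-error estimate. A full synthetic
pipeline run on a 45 µm cell with 150 particles takes a few seconds.

# Known limitations

* The PDI definition is this package's own (second moment about the
  nucleus centroid); other implementations of a peripheral index may
  scale differently, so absolute PDI values should only be compared
  within one definition.
* Near the exact cell centre, bilinearly interpolated edge distances are
  biased low by up to ~1 px (ridge of the distance map).
* The two-way ANOVA on proportions ignores the compositional correlation
  between fractions; its familywise error is slightly above nominal
  (≈0.06 at n = 3) but within the package's stated 0.07 target.
* The persistence filter (tracks longer than six 0.5 s frames) means all
  single-molecule conclusions concern the stationary RNA population;
  fast-moving molecules are deliberately excluded, as in the analysis the
  package reproduces.
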