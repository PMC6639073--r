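# periTrans

Quantification of peripheral RNA localization and local translation from
single-molecule two-channel imaging and spike-in-normalized polysome
fractionation.

## What problem this solves

Migrating cells transport specific mRNAs to their periphery — to
lamellipodia and the tips of protrusions. Whether those mRNAs are
*translated* at the periphery is answered with two data types, and this
package implements the full quantitative chain for both:

- **Translation-site imaging.** Single reporter mRNAs appear as
  diffraction-limited spots in an RNA channel (PP7/MS2 hairpins bound by
  a coat protein fused to mCherry); their nascent chains appear in a GFP
  channel (SunTag epitopes bound by scFv-GFP). The package detects spots
  (Laplacian-of-Gaussian + robust threshold), localizes them to ~0.05 px
  by iterative Gaussian-mask fitting with local background subtraction,
  links and filters stationary tracks (persisting > 6 frames), and scores
  per-particle translation efficiency

  ```
  efficiency = gfp_norm / mcherry_norm,
  norm       = (mean disc − offset) / (mean spot-free annulus − offset)
  ```

  so that 1 means "no enrichment over nearby diffuse cytoplasm".

- **Spatial statistics.** Distances to the cell edge come from the
  Euclidean distance transform of the cell mask (bilinear sub-pixel
  sampling); the package computes efficiency-vs-distance Pearson
  correlations with Fisher-z CIs and bootstrap trend bands, cumulative
  distance distributions, peripheral band masks, and a peripheral
  distribution index

  ```
  PDI = [ Σ wᵢ dᵢ² / Σ wᵢ ] / ⟨ d² ⟩ over the cell mask
  ```

  (d measured from the nucleus centroid; 1 = uniform, < 1 perinuclear,
  > 1 peripheral).

- **RNA clusters.** Intensity populations are decomposed into single
  molecules vs multi-RNA clusters (KDE-mode unit intensity; absolute /
  relative / copy-number rules), compared across regions by Fisher's
  exact test, overlapped against polyA granules, and used to score
  protrusion ROIs.

- **Polysome fractionation.** Four-fraction count tables with a spike-in
  row are normalized (`counts × geomean(spike)/spike_f`), turned into
  per-gene fraction distributions and translated fractions (p3 + p4),
  compared across conditions by two-way ANOVA with single-step
  multivariate-t (Dunnett-style) per-fraction contrasts, and condensed
  into protrusion/cell-body enrichment ratios.

- **Synthetic data.** A seeded generator produces cell geometries,
  ground-truth particles (peripherally localized singles, silent
  multi-copy clusters at protrusion tips), rendered two-channel images
  with a realistic camera model, time-lapse stacks, and
  negative-binomial fraction count tables — so every estimator above is
  validated by recovery against known truth.

## Worked example

One seeded end-to-end run — simulate a cell, render both channels, detect
and quantify every RNA spot, and summarize its spatial translation
statistics:

```r
library(periTrans)

geom <- makeCellGeometry(45, 45, nProtrusions = 3, pixelSize = 0.16,
                         seed = 1)
geom
#> CellGeometry: 281 x 281 px grid, 0.16 um/px
#>   cell area 705.7 um^2, nucleus area 94.0 um^2, 3 protrusion tip(s)

summ <- runPipeline(seed = 1)   # same geometry + particles + analysis
str(summ[c("n_true_particles", "n_quantified", "pearson_r",
           "median_edge_distance_um", "pdi")])
#> $ n_true_particles       : int 150
#> $ n_quantified           : int 133
#> $ pearson_r              : num 0.12
#> $ median_edge_distance_um: num 4.62
#> $ pdi                    : num 1.76
```

133 of 150 simulated particles are detected and quantified. The median
distance from the cell edge is 4.6 µm (the generator's localized law has
median 5 µm), and the PDI of 1.76 confirms a peripherally biased
population. The efficiency-vs-distance correlation is small and positive
(r = 0.12): translating singles are placed with distance-independent
ribosome load, while the 10% silent clusters sit at the periphery — which
is exactly the structure the correlation picks up.

The polysome side, with the default study design (20 APC-dependent, 6
APC-independent, 8 control genes, 3 replicates):

```r
tabs <- simulateFractionCounts(defaultCountSimConfig(), seed = 1)
tabs[[1]]
#> FractionCountTable: 34 genes x 4 fractions (control, replicate 1)
#>   spike counts: 19880, 20140, 20060, 20180
#>   groups: APC_dependent=20, APC_independent=6, control=8

fd <- fractionDistribution(tabs[1:3])   # control replicates
fd
#> FractionDistribution: 34 genes (control, mean of 3 replicate(s))
#>   translated fraction (p3+p4): median 0.731, range [0.636, 0.796]
```

Under control conditions ~73% of each transcript sits in the polysomal
fractions; `compareFractionDistributions()` then flags the
puromycin-induced shift toward fractions 1–2 per gene and fraction.

A thin command-line wrapper over the same functions ships in
`inst/cli/peritrans.R` (subcommands `simulate-images`, `simulate-counts`,
`detect`, `polysome`, `pipeline`).

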