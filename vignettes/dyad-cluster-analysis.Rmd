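---
title: "Cluster and colocalization analysis of cardiac dyad proteins in SMLM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster and colocalization analysis of cardiac dyad proteins in SMLM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadSTORM)
```

## The analysis problem

Stochastic optical reconstruction microscopy (STORM) reconstructs
nanoscale structure from many sparse single-fluorophore "blink" events.
The raw product is not an image but a *localization table*: one row per
blink, with fitted coordinates (here always nanometres), a channel label,
a frame index and a fit-quality p-value. In cardiomyocytes, type-2
ryanodine receptors (RyR2) form clusters at dyads — the junctions between
transverse tubules and junctional sarcoplasmic reticulum — arranged in
rows along sarcomere z-lines at a period of roughly 1.8–2.0 µm.
Junctophilin-2 (Jph2) and the L-type calcium channel (CaV1.2) concentrate
at the same junctions, and the degree to which they colocalize with RyR2
clusters is a structural readout of excitation–contraction coupling.

`dyadSTORM` implements the quantitative pipeline used in such studies:

1. **Quality filter.** Localizations carry a p-value from the chi-square
   assessment of the Gaussian fit on the camera; the partner channel is
   filtered to p in [0.25, 1.0] (inclusive), the reference channel is
   left unfiltered by default (configurable), mirroring common practice.
2. **Regions of interest.** Two identical ROIs per cell, fixed measure:
   3.0×10⁸ nm² in 2-D and 3.0×10¹¹ nm³ in 3-D. Only the measure is
   fixed by the protocol; we use a square (side 17,320 nm) in 2-D and a
   14,142 × 14,142 × 1,500 nm box in 3-D, the thin axial extent matching
   the ~1.5 µm axial capture range of astigmatic 3-D STORM. Manual ROI
   placement is replaced by `propose_rois()`, a deterministic grid search
   that maximizes contained reference localizations; explicit ROIs can
   also be supplied.
3. **Clustering.** DBSCAN on the reference channel with search distance
   `eps = 100` nm and `min_pts = 10`, followed by morphology constraints:
   cluster *span* (the distance between the furthest two member
   localizations) must lie in [50, 800] nm, and 3-D clusters may hold at
   most 1,000 localizations. A separate small-cluster pass runs DBSCAN
   with `min_pts = 4` and keeps clusters of 4–9 localizations.
4. **Colocalization.** For every retained cluster, partner localizations
   within 210 nm (inclusive) of the cluster centroid are counted — a
   circle in 2-D, a sphere in 3-D. Derived statistics: mean partner count
   per cluster, the percentage of clusters with no partner localization
   ("empty" clusters), per-cluster partner/reference ratios, and the
   fraction of all partner localizations captured by the search regions.
5. **Spatial statistics.** Nearest-neighbor distances (NND) between
   cluster centroids within each ROI; cluster-size histograms in bins of
   25 localizations from 0 to 400 with a "400+" overflow bin; NND
   frequency distributions in 100 nm bins.
6. **Aggregation and inference.** Metrics are averaged over the two ROIs
   of each cell, then per animal; group contrasts use one-way ANOVA with
   Tukey HSD pairwise comparisons (cell level by default, animal level by
   flag), with Welch's t-test available as a secondary pairwise option.

## Conventions and numerical choices

Several details are deliberately pinned down because implementations
differ and exact regression tests require determinism:

* **DBSCAN semantics.** A point is core iff its *closed* eps-neighborhood
  — the point itself included — holds at least `min_pts` points (the
  original counting convention). Border points join the cluster of the
  lowest-index core point that reaches them, and cluster labels are
  numbered by first core-point index. The labeling is therefore a pure
  function of the input, and tests compare it *exactly* against a
  brute-force density-reachability oracle.
* **Intervals.** The quality filter is inclusive at both ends; span
  constraints are inclusive; the colocalization boundary is inclusive
  (distance ≤ 210 nm). ROI membership uses half-open intervals
  `[origin, origin + extent)` so tiled ROIs never double-count.
* **Hulls.** Cluster "volume" is the convex hull of the member
  localizations: polygon area (via the Andrew/Graham hull in `grDevices`)
  in 2-D, and an incremental convex hull written for this package in 3-D
  (no 3-D hull was available among the package's dependencies).
  Degenerate clusters — collinear in 2-D, coplanar in 3-D — report
  measure 0.
* **Overlapping search regions** double-count shared partner
  localizations, the literal reading of per-cluster counting; a
  nearest-centroid unique-assignment switch exists for sensitivity
  analysis. No edge correction is applied at ROI borders, matching the
  protocol; the synthetic generator keeps planted geometry at least a
  margin (900 nm laterally) away from ROI faces so border bias is
  negligible in validation.
* **Partner ratios.** Jph2/RyR2 ratios are computed per cluster and then
  averaged (`mean_ratio`); the ratio of summed counts (`ratio_of_means`)
  is reported alongside, since protocols are often ambiguous about the
  order of averaging.
* **NND scope.** NNDs are computed within one ROI only — clusters in
  different ROIs are never neighbors — because the ROI is the unit of
  measurement and export.
* **Undefined metrics.** A zero-cluster ROI yields `NA` downstream
  metrics; cell averages drop `NA`s with a warning rather than
  propagating them silently.
* **Small-cluster pass.** The 50 nm lower span bound is applied in the
  small-cluster pass too (a 4-point cluster can span less than 50 nm;
  such candidates are discarded). Discarded candidates of either pass do
  not count toward the clustered-localization fraction.

## The synthetic generator

Real acquisitions of this kind are rarely deposited, so validation rests
on a generator that emulates the data at the level the analysis sees.
`generate_roi()` plants, in order: rows of cluster anchors perpendicular
to the cell's long axis at `row_spacing` (default 1,850 nm) with
truncated-normal within-row gaps; lateral anchor jitter; optional uniform
relocation of a fraction of anchors (row disarray) and random anchor
deletion (cluster loss); per-anchor localization counts from a truncated
lognormal (or 4–9 uniformly for the planted small-cluster subpopulation);
uniform scatter of those localizations in a disk (2-D) or flattened
ellipsoid (3-D, axial semi-axis 0.6 of lateral) followed by Gaussian
localization noise (20 nm lateral, 50 nm axial); uniform reference
background; partner localizations Poisson-distributed per anchor and
scattered Normal(0, 90 nm) about it, with a planted fraction of
partner-free anchors; and uniform partner background. All fit-quality
p-values are drawn in the passing interval, so the filter is exercised as
a pass-through; a `qc_stress_fraction` option plants sub-threshold
partner p-values to test the filter path. Everything derives from one
seed through per-stage substreams, so equal seeds give bit-identical
scenes and ground truth.

Two generator choices deviate from the most naive model, and both matter:

* **Footprint scales with content.** The cluster radius is a drawn base
  radius scaled by `sqrt(n / n_ref)` (2-D) or `(n / n_ref)^(1/3)` (3-D) —
  constant packing density up to jitter. With a content-independent
  radius, a 10-localization cluster would span ~200 nm and be invisible
  to DBSCAN at `eps = 100, min_pts = 10`, contradicting the joint
  benchmark statistics (most clusters small *and* mean span ~220 nm).
  RyR2 cluster area is indeed observed to grow with channel content.
* **Partner-free clusters are locally depleted.** A planted-empty anchor
  excludes partner *background* within 240 nm. With unstructured
  background at realistic densities (70–90% of partner localizations
  outside clusters), the probability of zero background partners within
  210 nm would be essentially nil and single-digit empty-cluster
  percentages would be unreachable. Biologically, a partner-free RyR2
  cluster is one without a nearby dyad — a region deficient in partner
  protein, not an unlucky draw. The exclusion is a switch
  (`empty_exclusion`); with it off, the recovered empty fraction follows
  the thinning law `p · exp(−λ·V)`, which the test suite checks by Monte
  Carlo.

What the generator does **not** emulate: blink kinetics and fluorophore
re-activation (localization counts *are* blink counts here, so
overcounting is implicit in the size distributions), anisotropic
localization-precision maps, drift or channel-registration residuals,
nuclear exclusions and cell-boundary geometry, and any sub-cluster
arrangement of receptor tetramers. Passing validation on these scenes
therefore demonstrates the correctness and calibration of the *analysis*,
not instrument-level fidelity.

## Condition presets and calibration

Shipped presets emulate euthyroid control (`EU2D`, `EU3D`), hypothyroid
(`PTU2D`, `PTU3D`) and T3-restored (`T32D`, `T33D`) myocytes. The PTU
presets encode three independent disease axes — anchor deletion, row
disarray (jitter + off-row relocation), and partner loss (lower partner
means, more planted-empty clusters) — so each summary statistic has a
dominant controlling knob.

Free parameters were fixed once by `calibrate_preset()`: a secant search
per (metric, knob) pair against the full pipeline run on 20–60 fixed-seed
ROIs, cycling until all targets sit within 1–2% — cluster-size lognormal
(mean localizations per cluster; and in 2-D the share of clusters below
50 localizations, solved jointly with the mean since both hang off the
same distribution), base cluster radius (mean span), within-row gap mean
(mean or median NND), planted-empty probability (empty-cluster
percentage), and small-cluster fraction (small-cluster share of the
min-4 pass). The calibrated values are frozen in
`inst/extdata/presets/*.yaml`; benchmark runs and the test suite re-run
the frozen presets with *fresh* seeds, so the reproduction checks are
out-of-sample. One consequence of the joint 2-D size solution is a
heavy-tailed lognormal (large `sdlog`, small `meanlog`, truncated to
[10, 1500]): the only shape in this family that puts ~70% of clusters
below 50 localizations while keeping the mean near 69. The upper
truncation is effectively moot because the 800 nm span cap removes the
rare giant clusters at constant packing density.

Cluster density per ROI is *not* a calibration target: no printed
per-ROI cluster counts exist to constrain it directly, so it follows
from the row geometry (spacing × gap) and is validated only through the
NND statistics. Sample sizes for validation runs (10 cells × 2 ROIs per
preset, ~20 ROIs and 10³–10⁴ clusters per statistic) were chosen so
Monte-Carlo error is well below the acceptance tolerances while a full
validation cycle stays comfortable on a laptop.

## Known limitations

* The linear mixed-effects analysis sometimes applied to binned
  histograms (random effects for animals and cells) is out of scope; the
  histogram group contrast is reported descriptively.
* Three-channel analysis (RyR2 + Jph2 + CaV1.2 simultaneously) is not
  supported; the partner channel is one protein per acquisition.
* DBSCAN with a 100 nm search radius cannot resolve sub-cluster
  structure; nothing here models tetramer packing, cluster fragmentation
  dynamics, or DNA-PAINT/MINFLUX-resolution detail.
* The 3-D Euclidean metric is isotropic even though axial precision is
  poorer; no anisotropic re-weighting is applied.
* The within-row gap law is a truncated normal, so the preset NND
  *distributions* are roughly symmetric about their calibrated means.
  Real dyad spacings can be strongly right-skewed, with a modal NND well
  below the mean; reproducing such shapes would need a skewed spacing
  family. The presets are calibrated to means and medians, not to
  distribution shapes.

## A worked mini-example

```{r example, eval = FALSE}
library(dyadSTORM)

## simulate one euthyroid cell (2 ROIs) and analyze one ROI
cfg <- preset("EU2D")
sim <- generate_roi(cfg, seed = 1,
                    metadata = list(cell = "c1", animal = "a1",
                                    group = "EU"))
res <- analyze_roi(sim$table)
res$clusters
res$coloc
res$nnd

## full two-condition experiment with group comparison
out <- run_pipeline(list(
  mode = "simulate",
  simulate = list(presets = c(EU = "EU2D", PTU = "PTU2D"),
                  n_cells = 10, rois_per_cell = 2, seed = 42),
  out_dir = tempfile("dyadstorm_run")))
out$comparison
```
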