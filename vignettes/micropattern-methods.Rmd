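---
title: "Quantifying germ-layer patterning on micropatterned colonies"
author: "micropattern authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying germ-layer patterning on micropatterned colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and the analysis problem

Human iPSCs confined on 1000-µm circular micropatterned islands and
stimulated with BMP4 and NODAL differentiate into radially ordered
germ-layer domains: an ectoderm core (SOX2), a mesoderm mid-ring
(BRACHYURY/BRA) and an outer endoderm ring (SOX17), the last frequently
showing angular discontinuities. Because the geometry is imposed by the
substrate, the radial organization of marker expression is a reproducible,
quantifiable phenotype, and differences between donor-derived cell lines in
that phenotype can be related to their genetic variants.

`micropattern` turns multi-channel well images of such colonies into
line-level phenotypes in five stages, each usable on its own:

1. **Segmentation** (`detect_nuclei()`, `measure_intensities()`): nuclei are
   segmented in the DAPI channel by Gaussian smoothing (σ = 1 px), Otsu
   thresholding and a distance-transform watershed that splits touching
   blobs; objects below 25% of the nominal nucleus area are discarded. The
   per-nucleus statistic is the arithmetic mean intensity over the nucleus
   mask, in every channel. Nuclei whose DAPI mean is not positive are
   dropped, because the later DAPI normalization would be undefined.
2. **Colony identification and QC** (`identify_colonies()`, `qc_filter()`):
   the colony mask is the morphological closing of the union of nucleus
   masks (closing radius 50 µm — large enough to bridge the sparsest
   inter-nucleus gaps, far below the ≥200 µm inter-colony spacing);
   connected components are colonies. A colony is rejected if its mask
   comes within 10 µm of the image border ("edge"), if its area leaves
   [0.7, 1.3] × the nominal disc area ("area"), or if its isoperimetric
   roundness 4πA/P² falls below 0.8 ("roundness") — the first failing rule,
   in that order, is recorded. Area and perimeter are measured on the
   convex hull of the mask contour: the micropattern boundary is convex by
   construction, and the hull removes the scalloping the nucleus-union mask
   shows between peripheral nuclei (a rasterized disc then measures
   roundness ≈ 0.99; a half disc stays at its analytic ≈ 0.75).
3. **Radial binning** (`nucleus_distance()`, `assign_bin()`): each
   nucleus's distance from its colony centroid,
   D = √((xᵢ−x)² + (yᵢ−y)²), is assigned to one of 20 concentric rings of
   25 µm, half-open intervals [(B−1)·25, B·25), which exactly tile the
   nominal 500-µm colony radius. Distances at or beyond 500 µm
   (segmentation jitter) are clipped into ring 20 and counted, never
   silently discarded — discarding would bias the outer ring.
4. **Normalization cascade** (`nucleus_ratios()`, `estimate_background()`,
   `radial_profiles()`): marker intensity is divided by DAPI intensity per
   nucleus; the background level of non-expressing cells is estimated per
   well and marker and subtracted (floored at zero); ring values are the
   per-colony mean of subtracted ratios (empty rings are missing, not
   zero — zero would fabricate absence of expression); finally every value
   is divided by the maximum ring value across the colonies of its well,
   so the well maximum is exactly 1. The order — ratio, background
   subtraction, per-ring colony mean, well-max scaling — is fixed here
   because the assay description states the steps but not their order
   relative to background subtraction.
5. **Phenotype statistics** (`percent_positive_table()`, `kruskal_dunn()`,
   `outlier_mean_expression()`, `outlier_radial()`,
   `marker_correlations()`, `pca_lines()`): percent-positive per colony
   (which controls for cell-number variation), Kruskal–Wallis with Dunn's
   post hoc across lines (α = 0.05), pooled two-tailed Student's t outlier
   calling per line (α = 0.001), Kolmogorov–Smirnov comparison of the
   radial positions of marker-positive nuclei against a designated control
   line (α = 0.01), Spearman correlations between markers, and PCA of
   line-level percent-positive features.

`run_pipeline()` wires the stages together for a set of wells under a
plate layout and returns tidy tibbles throughout.

## Background and positivity model

The per-nucleus marker/DAPI ratios of one well are bimodal: a
non-expressing background population and an expressing one. A
two-component Gaussian mixture (G = 2, via `mclust`) is fitted per well and
marker; the background is the lower component's mean and the positivity
threshold is that mean plus twice the lower component's SD. A nucleus is
positive when its *background-subtracted* ratio exceeds the threshold.
That subtracted-scale comparison is deliberate: when a well contains no
expressing cells the mixture splits the unimodal background in two and the
threshold lands inside the background distribution; on the ratio scale
this would mislabel a third of the background as positive, while on the
subtracted scale an all-background well scores ≈ 0% positive. Degenerate
fits (near-constant samples, which can also stall the EM and are therefore
short-circuited) fall back to a quantile rule (5th percentile background,
median threshold) with a warning. At least 50 nuclei are required.

## What the synthetic-data generator emulates

No raw images accompany the assay, so the package ships a ground-truthed
simulator (`generate_well()`, `generate_plate()`) whose defaults are the
study conditions:

* 1000-µm circular colonies, 6 per well (the physical plates yield four to
  seven readable colonies per well), 30% truncatable at the image border
  when requested;
* nuclei of 8 µm radius placed uniformly at random with an 18-µm minimum
  spacing, 600 per colony by default — a density at which individual nuclei
  remain resolvable at the simulated 2 µm/px scale (20× objective class);
  placement that cannot satisfy the spacing errors out naming
  `nuclei_per_colony`;
* per-nucleus DAPI from a gamma distribution (mean 1000, CV 0.2), strictly
  positive;
* marker expression as a marker/DAPI *ratio*: non-expressing nuclei emit a
  baseline ratio of 0.1 (the background population the pipeline must
  subtract), expressing nuclei add a Gaussian radial term
  amplitude·exp(−(D−center)²/(2·width²)) with amplitude 0.9 — SOX2 as a
  central dome (width 150 µm), BRA as a ring at 300 µm (width 60), SOX17 as
  a ring at 425 µm (width 40) with a 20% angular discontinuity sector;
* positivity probability proportional to the same radial shape, so
  positive cells concentrate where expression is high;
* marker pixel intensity = DAPI × ratio (multiplicative in DAPI), so DAPI
  normalization is exactly invertible in the noiseless limit;
* nuclei rendered as discs with Gaussian-blurred edges (σ = 1 px), additive
  Gaussian pixel noise (SD 5 on a DAPI scale of 1000), floored at zero;
* donor effects as per-line shifts/scalings of ring centre, width,
  amplitude and positive fraction, shared by all wells of a line;
  replicate wells differ only by their deterministically derived RNG
  streams.

The generator reproduces the *statistical* structure the analysis assumes —
radially organized expression, replicate hierarchy, donor variation,
truncated colonies, imaging noise. It does not model cell-density
gradients within colonies (uniform density is assumed; the assay
description gives no gradient), nuclear texture, optical vignetting,
segmentation-hostile cell crowding, or the BMP4/NODAL reaction–diffusion
signalling that creates the rings in reality — the ring structure is
imposed phenomenologically. Passing tests therefore demonstrate that the
pipeline recovers known spatial statistics from images with realistic
noise and replicate structure, not that it is robust to every artefact of
real microscopy.

## Numerical choices and degenerate inputs

* Half-open bins with floor arithmetic make assignments unambiguous;
  equivalence with a brute-force interval search is asserted on 10⁴ random
  distances.
* Well-max normalization is idempotent; all-zero wells are left unscaled
  with a warning instead of dividing by zero.
* Aggregation is hierarchical — colonies → well (technical replicate),
  wells → experiment (biological replicate), experiments → line — with the
  SD taken over the units being averaged at each level; this differs from
  naive pooling whenever well sizes differ, and the tests pin the
  difference on a hand-computed toy.
* Dunn's post hoc z statistics use mean ranks with tie correction;
  multiplicity adjustment is Bonferroni by default (the convention of the
  graphing software commonly used for this test), switchable via
  `p_adjust`.
* The outlier t test is Student's pooled-variance test (matching the
  stated method), with Welch available by flag; it refuses pools smaller
  than 4 colonies, and `run_pipeline()` only calls it when the pool has at
  least 10.
* The KS comparison operates on the radial distances of marker-positive
  nuclei, not on binned profiles: 20 bin means are too few points for a
  distributional test, while nucleus distances measure spatial patterning
  directly.
* PCA features are column-standardized before decomposition; variance
  explained sums to 1 by construction.
* Variant filtering applies the strict inequalities exactly as stated
  (MAF < 0.005 in both databases, fewer than five carrier HipSci lines,
  Condel class "deleterious"); a missing MAF fails rarity conservatively
  and a missing Condel class is dropped with a warning, both counted.
  "Fewer than five" counts lines, not donors, switchable via `max_lines`.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script verify parameter recovery on
plates of 2 wells × 4–5 colonies with 500–800 nuclei per colony, nucleus
detection on a 500-nucleus well, KS calibration on 1000 null draws of 200
positive nuclei per group, power for a 100-µm ring shift on 200
repetitions, and the pooled-t outlier rule on 200 simulated 10-line
panels. These sizes give binomially tight rate estimates while keeping a
full run in the minutes range on a single core.

## Known limitations

* Segmentation assumes nuclei are resolvable discs; heavily overlapping
  nuclei (confluent cultures imaged at low magnification) will be merged
  or split imperfectly, as with any watershed approach.
* Colony QC assumes one colony per connected mask component; colonies
  that touch (< 2 × closing radius apart) would merge and then fail the
  area gate rather than being separated.
* The convex-hull roundness is blind to concavities; genuinely bitten
  colonies are caught by the area window instead.
* The KS radial-outlier test inherits the usual sensitivity of KS to
  sample size: with thousands of positive nuclei per line, tiny
  patterning differences become formally significant; the effect size (D
  statistic) is reported alongside p.
* Condel and DUET scores are consumed as annotations; the package neither
  recomputes nor audits them.
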