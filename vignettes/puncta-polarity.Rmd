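---
title: "Quantifying planar polarity from fluorescent puncta: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar polarity from fluorescent puncta: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctapolar)
```

## The measurement problem

Planar cell polarity (PCP) proteins and mechanosensitive junctional
components often appear as discrete puncta within epithelial cells. Under a
directional cue — tension toward a dorsal midline, apically constricting
neighbors, a nearby wound — the puncta shift toward one side of each cell.
The quantification implemented here reduces a fluorescence image plus a cell
segmentation to one angle per cell (where, relative to the cue, the protein
is enriched) and one tissue-level test (is the angular distribution
non-random?).

The pipeline assumes: (i) a single-channel, already Z-projected 2-D image;
(ii) a label mask in the Cellpose convention (0 = background, cells
labeled with positive integers; gaps in the id sequence are tolerated and
reported, never rewritten); (iii) puncta bright enough relative to local
background that a global threshold on the log-normalized image separates
them. Segmentation itself is out of scope — masks are consumed, not
produced.

## Conventions

All coordinates are 1-based pixel indices with the origin at the top-left:
x runs along columns (rightward), y along rows (downward). Angles are in
degrees on (−180, 180], computed as `atan2(dy, dx)`, so 0° points along +x
and +90° points down the image. Rose plots negate the angle for display
only, so positive angles appear counterclockwise on the page with 0° (the
reference direction) at the right.

## Pipeline stages and their parameters

**Normalization** (`log_normalize`): `log(1 + I)`, then a linear rescale
mapping the 1st/99.9th percentiles of the log image to 0/1, clipped to
[0, 1]. The percentile clip makes the scale robust to hot pixels; `log1p`
compresses the dynamic range so a single threshold can serve both dim and
bright puncta. A constant image normalizes to all zeros rather than
erroring. Rank order of pixels is weakly preserved.

**Thresholding** (`threshold_image`): Otsu's criterion over a 256-level
histogram is the default — it is parameter free and exactly checkable
against exhaustive search; a quantile threshold (default 0.95) is available
for images whose foreground fraction is known to be stable. Foreground
means strictly above the threshold, so constant images give empty masks.
Ties in the Otsu criterion break toward the lowest level. Thresholding is
global per image; per-cell thresholding would change puncta counts in dim
cells and is deliberately not done.

**Cluster labeling** (`find_clusters`): connected components of the binary
mask, 8-connectivity by default (puncta are blobs; diagonal contact should
not split them), built as an igraph pixel-adjacency graph. Each cluster
records pixel area, the unweighted mean of member pixel coordinates as a
subpixel centroid, and integrated intensity summed over the *normalized*
image (the same domain the threshold sees); per-cell mean intensity for
group comparisons is instead measured on the raw image, so it stays on the
acquisition scale.

**Size filter** (`filter_clusters_by_size`): inclusive bounds, defaults
4–400 px — the lower bound removes single-pixel noise, the upper removes
junction-scale smears. Both are configuration knobs.

**Cell assignment** (`assign_clusters_to_cells`): plurality of member
pixels; ties break toward the smaller label (a deterministic, geometry-free
rule); clusters whose plurality is background are dropped and counted.

**Polarity** (`cell_polarity_vector`): the weighted mean of *unit* vectors
from the cell centroid to cluster centroids, weights either cluster area
(default) or integrated intensity. Unit vectors mean a punctum's distance
from the centroid carries no weight — only its direction and its
size/intensity do — and they bound the resultant magnitude by 1. Both
weighting modes are implemented because either size or fluorescence
intensity is a defensible mass proxy; when all clusters in a cell have
equal area and equal intensity the two modes coincide exactly. A cluster
centroid coinciding with the cell centroid is skipped (its direction is
undefined); a cell with no clusters, zero total weight, or a resultant
below 10⁻⁶ is flagged undefined rather than contributing a noise angle.

**Reference field** (`reference_field`): `fixed_angle` applies one global
direction to every cell and is the default for midline-type geometries
(the midline is far relative to the field of view, so a single direction
per image is the simpler model and the one used unless there is evidence
of curvature); `target_point` aims each cell at a fixed pixel and serves
wound geometries, where 0° of relative angle then means "toward the
wound". A cell whose centroid coincides with the target has no defined
reference and is excluded, with the reason recorded.

**Border cells** are included by default: wound-margin cells are precisely
the border-adjacent ones in cropped views, and nothing in the polarity
definition degrades at the border. Exclusion is available
(`include_border_cells = FALSE`) for tiled acquisitions where cut cells
would bias centroids.

**Pooling** (`pool_fields`): defined cells from several images (e.g.
several embryos) are concatenated with their field of origin; pooling
refuses to mix fields analyzed under different configurations. Each cell
contributes weight 1 to the histogram by default, so an image with larger
or brighter puncta does not dominate the pooled distribution; weighting
cells by their total cluster mass is available
(`cell_weight = "weight_total"`) and affects only the rose-plot rendering.

**Histogram and test** (`bin_angles`, `chi_square_uniformity`): bins of
360/`n_bins` degrees, first bin centered on 0° (the reference), left-closed
right-open with the wrap seam closing the circle. The default of 8 bins
keeps expected counts ≥ 5 for pooled n of about 60–300 cells, the realistic
scale for a few embryos. The chi-square statistic is computed on
*unweighted* per-cell counts — one cell, one observation — because weighted
counts would invalidate the test's sampling distribution; weights only ever
shape the rendered rose. Degrees of freedom are `n_bins − 1`; a flag warns
when the expected count per bin drops below 5. Zero pooled cells yield an
undefined test, reported as such, not an error.

## The synthetic generator

`generate_label_field` tessellates the image by nearest-seed (Voronoi)
assignment of jittered-grid seed points (jitter ≤ 40% of the grid pitch),
giving convex, confluent, singly connected regions resembling an epithelial
apical surface, with labels exactly 1..n and no background.
`generate_puncta_image` then draws a Poisson(`mean_puncta_per_cell`) number
of puncta per cell; each punctum's angle about the cell centroid is von
Mises with mean equal to the local reference direction and concentration
`bias_kappa` (0 = uniform, i.e. unpolarized tissue), and its radial
position is uniform within `radial_fraction_range` of the centroid-to-
boundary distance along that angle, so every ground-truth punctum lies
inside its cell by construction. Puncta render as additive isotropic
Gaussian spots clipped to the owning cell (keeping ground-truth ownership
unambiguous), over a constant background with additive Gaussian noise.

Defaults — 6 puncta/cell, spot sigma 1.5 px, amplitude 800 over background
100 with noise sd 20 on a 16-bit scale — were chosen once as a plausible,
clearly super-threshold regime for testing; puncta-per-cell counts and spot
sizes are not reported for real acquisitions, so these are test-convenience
values, not biological calibration. The von Mises sampler is the
Best–Fisher rejection algorithm, validated in the tests against the
I₁(κ)/I₀(κ) mean-resultant identity.

What the generator does *not* emulate: Poisson shot noise (additive
Gaussian only — the detection contract being exercised does not depend on
the noise family), anisotropic or junction-hugging puncta, intensity
gradients, segmentation errors, or any mechanical origin of the bias (the
bias is imposed statistically, not emergently). Passing tests on synthetic
fields therefore demonstrate the correctness of the measurement chain, not
robustness to every pathology of real microscopy.

Seeds: a field is fully reproducible from `field_spec(seed = s)`; datasets
derive per-field seeds arithmetically (s, s+1, ...) so any single field can
be regenerated in isolation. The mask generator and the puncta renderer use
separated seed streams so each stage is individually reproducible.

## Numerical choices and degenerate inputs

* Angle wrapping maps −180° to +180°, making (−180, 180] exact; the
  histogram's seam bin therefore collects both +180 and just-below −180.
* Binning uses a half-bin shift and floor, with a 10⁻⁹-bin guard against
  floating-point edge jitter; an angle exactly on an interior edge goes to
  the higher bin.
* The polarity degeneracy tolerance (|v| < 10⁻⁶) marks symmetric cancellation
  as undefined instead of emitting an arbitrary angle.
* Constant images: normalization returns zeros, both thresholds return
  empty masks, the pipeline reports zero clusters everywhere.
* Empty masks (no cells) flow through to an undefined uniformity test.
* 90° raster rotations and background padding leave relative angles
  unchanged (to 10⁻⁶ degrees and 10⁻⁹ on vector components respectively in
  the test suite), because every stage is a permutation-equivariant
  pixel operation followed by coordinate arithmetic.

## Calibration and verification strategy

The test suite checks the statistical machinery at the level where the
statistics live: type-I error of the uniformity test is measured over 500
replicates of 200 cells drawn from the generator's angular ground-truth
model (`simulate_polarity_angles`, the same Poisson/von Mises layer the
image renderer consumes) rather than 500 full image renders — the test's
calibration depends only on the per-cell angles, and this keeps the run in
seconds. Power against κ = 1.5 is measured the same way. Full-raster
end-to-end behavior is covered separately: pooled simulations of 3 × 150
cells (κ = 1.5, fixed reference) and 2 × 30 cells (κ = 1.0, target-point
reference) at 256×256 px — the problem sizes used throughout — must reject
uniformity at 0.001 and 0.05 respectively, and a κ = 2 field of 100 cells
must recover the imposed direction within ±10°.

Oracle tests pin the numerics: Otsu against exhaustive 256-level search,
connected components against a flood-fill labeler, the chi-square tail
against direct numerical integration of the density, and the von Mises
sampler against its Bessel-function moments.

## Known limitations

* Global thresholding under-detects puncta in cells much dimmer than the
  field average; whether the original workflow thresholded globally or
  per cell is not documented, and the global choice is the conservative,
  reproducible one.
* Heavily overlapping puncta merge into single clusters; the polarity
  vector degrades gracefully (merged mass still sits on the biased side)
  but per-cell cluster counts are not punctum counts.
* The polarity is vectorial; nematic (180°-periodic) order is out of scope.
* The chi-square test treats cells as independent; cells within one embryo
  are not, so pooled p-values are anti-conservative to an unquantified
  degree — the per-field counts are always reported so sensitivity analyses
  per embryo remain possible.
* No multiple-testing correction is applied across conditions; every
  p-value is recorded and correction is left to the study design.
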