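# punctapolar

Quantification of planar cell polarity (PCP) from punctate fluorescent
protein signal in epithelial sheets.

Many PCP and mechanosensitive proteins concentrate in discrete bright
puncta at or near the apical cortex. When a tissue experiences a
directional cue — pulling forces toward a dorsal midline, apical
constriction at a neural plate border, the free edge of a wound — those
puncta redistribute toward one side of each cell. `punctapolar` turns a
single-channel fluorescence image plus a cell segmentation (a
Cellpose-convention label mask) into a per-cell quantification of that
asymmetry, and tests whether the tissue-level angular distribution is
non-random.

## The quantification

For each segmented cell with centroid **g** and detected puncta clusters
with centroids **c**ᵢ and weights *w*ᵢ (pixel area or integrated
intensity), the polarity vector is the weighted mean of unit vectors

> **v** = Σᵢ wᵢ (**c**ᵢ − **g**)/|**c**ᵢ − **g**| / Σᵢ wᵢ,  |**v**| ∈ [0, 1]

Its orientation θ = atan2(v_y, v_x) is expressed relative to a reference
force direction — a fixed tissue axis (midline geometry) or the direction
from the cell toward a target point (wound geometry) — so that 0° always
means "polarized toward the cue". Relative angles pooled over cells and
images are binned into a rose-plot histogram (8 × 45° sectors by default,
first bin centered on the reference) and tested against the uniform
circular distribution with Pearson's chi-square test on the per-cell
counts.

Puncta are detected the same way throughout: `log(1 + I)`, percentile
min–max normalization, Otsu (or quantile) thresholding, 8-connected
component labeling, an inclusive size filter (4–400 px by default), and
assignment of each cluster to the cell holding the plurality of its
pixels.

A synthetic-epithelium generator (jittered-grid Voronoi cells, von
Mises-biased Gaussian puncta, full ground truth) makes every stage
testable without microscopy data; see the methods vignette
(`vignettes/puncta-polarity.Rmd`) for the model, its parameters and its
limits.

## Worked example

Simulate three midline-polarized fields (150 cells each, von Mises bias
κ = 1.5 toward 0°) and run the full pipeline with defaults:

```r
library(punctapolar)

spec <- field_spec(n_cells = 150, bias_mu = 0, bias_kappa = 1.5, seed = 1)
fields <- generate_dataset(spec, n_fields = 3)
res <- run_pipeline(lapply(fields, `[[`, "image"),
                    lapply(fields, `[[`, "mask"),
                    analysis_config(reference_angle_deg = 0))
res$test
res$histogram
```

```
Chi-square uniformity test: X2 = 877.1, df = 7, p = 4.226e-185 (n = 436)
Angular histogram: 8 bins of 45 deg, n = 436 cells
  center_deg count weight
1          0   238    238
2         45    81     81
3         90     8      8
4        135     1      1
5        180     0      0
6       -135     5      5
7        -90    13     13
8        -45    90     90
```

Of 450 simulated cells, 436 had a defined polarity vector; 238 of them
fall in the 45° sector centered on the reference direction against 54.5
expected under uniformity, so the chi-square test rejects uniformity
decisively. `mean_resultant(res$pooled$relative_angle_deg)` summarizes the
same pool as R = 0.836 at −2.6°, i.e. a strong mean orientation along the
imposed bias. `run_pipeline(..., output_prefix = "out/run")` additionally
writes the per-cell CSV, a JSON summary and the rose plot.

A thin command-line front-end with `analyze`, `simulate` and `calibrate`
subcommands is installed at `exec/punctapolar`.

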