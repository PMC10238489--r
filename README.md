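# divquant

Quantification of asymmetric cell division from single-plane fluorescence
time-lapse movies, built around the cytokinesis of *Drosophila* larval
neuroblasts: a large self-renewing neuroblast and a small ganglion mother
cell (GMC) are separated by an acto-myosin contractile ring whose position
and dynamics determine daughter-cell size.

The package implements, as tested reusable code, the standard manual
quantification schemes for this system together with a ground-truthed
synthetic movie generator:

* **Cortical linescans and enrichment** — pole-to-pole cortical intensity
  profiles (2-px wide line along the cortex, cytoplasm-subtracted,
  max-normalised, neighbour-averaged), the polar enrichment index
  `(Myo_cortex − Myo_cyto) / Myo_cyto` read at the moment of maximal polar
  signal (~80% furrow ingression), and the cortex-to-furrow intensity
  ratio.
* **Furrow kinetics** — the furrow as the point of maximal inward membrane
  curvature, ingression onset as the first frame with inward curvature on
  both sides, and percent ring constriction
  `100 (d0 − d) / (d0 − d_mb)` anchored at the anaphase-onset width (0%)
  and the midbody diameter (100%, 4 px by convention).
* **Morphometrics** — GMC cross-section area (pixel count × pixel area)
  and roundness `4A / (π L²)`.
* **Cohort statistics** — exact two-tailed Mann–Whitney (full enumeration
  up to combined n = 20), Pearson r/R² with t-transform p values,
  median ± IQR (type-7 quantiles), and an in-silico furrow-position
  correction experiment: without correction the final GMC area tracks the
  initial furrow basal distance (strong positive correlation); with
  correction the correlation collapses.
* **Isoform usage** — relative splice-isoform frequencies from
  exon-junction read counts by non-negative least squares on the junction
  membership matrix, plus codon-substitution classification (e.g. CAG →
  TAG, glutamine to stop: nonsense).
* **Synthetic movies** — `simulate_division()` renders a dividing-cell
  phantom (mother circle pinched at the furrow plane, cortical band,
  ring-focused bump, transient polar pulse peaking near 80% ingression,
  PSF blur, camera offset, shot and read noise) with full per-frame ground
  truth, written/read as multi-page 16-bit TIFF plus a JSON sidecar.

## Worked example

```r
library(divquant)

p   <- sim_params(initial_furrow_basal_distance = 3.2, seed = 7)
sim <- simulate_division(p)
sim$movie
#> time_lapse_movie: 30 frames of 82 x 82 px, 0.160 um/px, 20 s/frame
#>   anaphase onset at frame 2; background not subtracted

m <- measure_division(sim$movie, camera_offset = p$camera_offset,
                      enrichment = TRUE)
round(as.data.frame(m), 3)
#>   onset_frame initial_basal_distance_um gmc_area_um2 gmc_roundness
#> 1           6                     3.088       12.902         0.279
#>   enrichment_index constriction_complete
#> 1            2.496                     1
```

The pipeline traced every frame, timed ingression onset at frame 6,
measured the initial furrow 3.09 µm from the basal pole (ground truth:
3.2 µm), followed the ring to full closure, and measured the nascent GMC
at 12.9 µm² (model ground truth 11.1 µm²; the polygon split at the furrow
carries a small positive bias) with roundness 0.28 — the flat-cap shape of
a freshly pinched-off GMC. The constriction curve behind these numbers
rises linearly, e.g. sampled every three frames:

```r
cc <- attr(m, "curve")
round(cc$percent[seq(7, 28, by = 3)], 1)
#> [1]  5.8 20.0 33.7 47.0 60.2 73.6 86.9 97.3
```

Comparing GMC areas between two small cohorts:

```r
mann_whitney_two_tailed(c(12.1, 14.9, 13.7, 15.2), c(18.4, 17.9, 19.5))
#> Mann-Whitney two-tailed: statistic = 0, p = 0.05714 (n = 4/3, exact)
```

The headline experiment — does correcting the furrow position abolish the
correlation between initial furrow position and GMC size? — runs as
`correlation_experiment(n_cells = 30, seed = 1)`, which simulates both
cohorts, quantifies every movie and reports r, R² and p per cohort plus
the Mann–Whitney comparison of areas.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch — the seeded furrow-position-correction cohort experiment through
the full simulate → trace → detect → measure pipeline, and the
exon-junction isoform estimation on the packaged synthetic locus — and
writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette
(`vignettes/quantifying-asymmetric-division.Rmd`) documents the phantom's
model and assumptions, every numerical choice in the measurement pipeline
(thresholds, subpixel refinement, smoothing semantics, axis conventions),
and known limitations. Function-level documentation is in the roxygen
comments under `R/`.
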