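---
title: "Quantifying asymmetric cell division: models, measurements and phantoms"
author: "divquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying asymmetric cell division}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divquant)
```

## The measurement problem

During asymmetric division of *Drosophila* larval neuroblasts, an
acto-myosin contractile ring constricts the cleavage furrow and splits the
cell into a large self-renewing neuroblast and a small ganglion mother cell
(GMC). Three families of readouts characterise this process on single-plane
fluorescence time-lapse movies of a cortical myosin marker:

* **cortical intensity**: pole-to-pole linescans along the cortex, the
  polar enrichment index `(cortex - cyto) / cyto`, and the cortex-to-furrow
  intensity ratio;
* **furrow kinetics**: the position of the furrow (the point of maximal
  inward membrane curvature), the time of ingression onset, and ring
  constriction expressed as a percentage between the anaphase-onset
  diameter (0%) and the midbody diameter (100%, by convention a ring 3–5 px
  across; the package default is the 4 px midpoint);
* **daughter-cell morphometrics**: the GMC cross-section area (pixel count
  times pixel area) and its roundness `4A / (pi L^2)` with `L` the maximal
  chord.

A central biological question these readouts address is furrow-position
robustness: the initial furrow can form at variable distances from the
basal pole, and in the wild type a severely basal position is corrected
during constriction so that the final GMC size is preserved, whereas
without the correction the final GMC area simply tracks the initial furrow
position. The package recasts this contrast as a parameter-recovery
experiment on synthetic data (`correlation_experiment()`).

Because the quantification schemes originate in manual image analysis,
every operation here is paired with a synthetic movie generator that knows
the ground truth, so each step of the pipeline is testable.

## The phantom

`simulate_division()` renders an asymmetrically dividing cell on a single
sagittal plane. The outline is a half-width profile of the axial
(apico-basal) coordinate `z`:

    w(z) = W(z) - (W(zf) - d(t)/2) * phi(z - zf)

where `W(z)` is the half chord of a mother circle of radius `R` (default
5.5 µm: a cell just above the 11 µm observation cut-off), `zf` is the
furrow plane, `d(t)` the ring-diameter schedule and `phi` a smooth
compact-support pinch with a parallel-walled throat whose half-length grows
with pinch depth (deep furrows are tubes, not V-grooves; the throat length
fraction `neck_throat` is the "tube furrow" knob). This explicit profile
was chosen over an implicit two-lobe scalar field because it gives exact,
closed-form control of the two quantities every downstream test measures —
the furrow axial position and the neck diameter — plus an analytic
ground-truth GMC area by 1-D quadrature, at O(rows) rendering cost. The
analysis side still runs marching squares (`grDevices::contourLines`), so
the measurement path is independent of the generator path.

Key schedule conventions:

* `d(t)` is flat at the initial chord `d0 = 2 sqrt(2 R delta0 - delta0^2)`
  through the ingression-onset frame, then linear down to the midbody
  diameter. `d0` is derived from the geometry rather than free: a free
  value inconsistent with the furrow position could not be rendered.
* The first frame showing a pinch is `ingression_onset_frame + 1`; the
  curvature detector therefore reports onset within one frame of the
  schedule.
* The polar myosin pulse is
  `E(t) = E exp(-(c(t) - 0.8)^2 / (2 * 0.15^2))` in constriction fraction
  `c(t)`, peaking at ~80% ingression; its width (0.15) is a package
  assumption, as only the peak position is established.
* With `correction_on = TRUE` the furrow plane drifts in proportion to
  `c(t)` toward the position whose model GMC area equals
  `target_gmc_area`; with `FALSE` it stays at `delta0`, making the final
  GMC area strictly increasing in `delta0`.

Intensities are arbitrary camera units: cytoplasm 100, cortical base band
250 (raised uniformly by the factor `1 + E(t)`), a ring-focused Gaussian
bump of amplitude 400 in arclength around the furrow plane, camera offset
100. Optics and detection are a Gaussian point-spread function
(`psf_sigma`, default 0.11 µm — without it the rendered edges are aliased
and none of the subpixel measurements are meaningful), 2x2 subpixel
box-averaged rasterisation, Poisson shot noise, and Gaussian read noise
(sd 5). The effective pixel size of the emulated 100x EMCCD setup is not
established; 0.16 µm/px is the configurable default.

What the phantom deliberately does **not** emulate: 3-D structure (the
quantified data are single-plane), photobleaching, cortical flows or any
force-based mechanics, neighbouring cells, and uneven illumination. A
green test therefore establishes that the measurement code recovers the
stated model, not that it is robust to every failure mode of live imaging.

## Numerical choices in the measurement pipeline

* **Tracing.** The cell outline is the largest closed iso-contour at the
  midpoint between the extracellular background (median of the frame
  border) and the intracellular level; nested contours are treated as
  holes of one region. Each vertex is then refined to the subpixel
  crossing of the local half-maximum edge level along its normal. On
  noise-free phantoms the traced outline is within 1 px (Hausdorff) of the
  truth on convex outlines; at the furrow fold the iso-contour rounds the
  throat corners by up to ~2 px — a resolution limit of contour tracing
  that the quantitative readouts below avoid by construction.
* **Curvature.** Signed discrete curvature by an algebraic circle fit over
  an 11-sample window on a lightly pre-smoothed contour; concave
  (inward) is negative, and the furrow qualifies below the concavity
  threshold 0.05 px^-1 (the manual "onset of inward membrane curvature"
  call has no published number). A tube-like neck traces as two concave
  corners bridged by a straight throat, so the furrow point is the median
  of the concave run, which sits at the throat centre.
* **Ring diameter.** Measured on the image, not the contour: an intensity
  linescan along the furrow chord, taking the separation of the two
  outermost half-maximum edges (the outer faces of the cortical band on
  each wall), minimised over a +/-1.5 px axial window. This stays accurate
  when the two walls are closer than twice the band width and the
  cytoplasmic dip between them disappears (late constriction). Typical
  accuracy on phantoms is ~1 px throughout the curve.
* **The 0% anchor.** The ring does not exist as a geometric feature at
  anaphase onset, so `d0` is the cell width at the eventual furrow plane,
  located through the nascent ring's cortical intensity maxima on each
  pre-ingression frame (median across frames). If the ring has no
  intensity contrast the onset furrow points are used instead.
* **Linescans.** Profiles follow one lateral side of the contour from the
  apical to the basal pole, sampling a `width_px`-wide line centred 1.5 px
  inside the boundary along inward normals (bilinear interpolation);
  hugging the boundary any closer puts half the line on the blurred edge
  ramp. Negative values after cytoplasm subtraction are retained; only
  camera-background subtraction clips at zero.
* **Smoothing semantics.** The "6 neighbours average" of linescan plots is
  implemented as a centred moving average with 3 neighbours per side
  (7-point window), the "4 neighbours average" of constriction curves as 2
  per side; both are exposed as `smooth_k`. Max-normalisation happens
  before smoothing, so the pre-smoothing maximum is exactly 1.
* **Polar cortex.** For the enrichment index the cortex mean excludes the
  tangent-rule furrow segment plus an arc neighbourhood (12% of the
  perimeter) around each furrow point, because the ring-focused signal has
  Gaussian tails well beyond the geometric furrow. The index is read at
  the frame of maximal polar signal among frames with a detected furrow.
  Whether the published index covers one or both nascent cells is not
  stated; both-cells is the default and `cells = "neuroblast"` restricts
  to the apical side.
* **Axes.** The principal axis of a nearly round cell — and of the nearly
  isotropic two-lobe dumbbell — is numerically ill-conditioned. Every
  orientation-sensitive step therefore derives the division axis from the
  furrow chord (perpendicular of the line joining the two furrow points)
  rather than from image moments; the moment-based poles are kept for
  elongated contours and for the pole-to-pole paths.
* **Furrow segment.** The tangent-angle rule (< 30 degrees from the long
  axis) is evaluated with tangents over a +/-2-sample baseline; the
  furrow "length" readout is the arclength extent of that segment.
* **GMC split.** At the last frame with a two-sided furrow the contour is
  split along the furrow chord; the GMC is the sub-polygon with the larger
  mean row (the basal lobe, with apical rendered toward row 1). Area is a
  rasterised pixel count to match the ROI-based convention; roundness uses
  the maximal pairwise chord.

## Statistics

`mann_whitney_two_tailed()` follows the convention of exact enumeration of
all label arrangements for combined samples up to 20 without ties (`U`
with half credit for ties; two-sided p = min(1, 2x the smaller tail
including the observed point)), and a tie-corrected normal approximation
with continuity correction otherwise. Note that `stats::wilcox.test` is
silently exact up to n < 50, so reference comparisons in the large-sample
regime must set `exact = FALSE`. `pearson_r2()` is the product-moment
coefficient with the t-transform p value; `median_iqr()` uses
linear-interpolation (type 7) quantiles, which the interquartile bars
depend on. No multiple-comparison adjustment is applied, matching
per-comparison reporting.

## Isoform usage

`estimate_isoform_frequencies()` solves `counts ~ scale * (M f)` over
non-negative scaled frequencies, where `M` is the junction-membership
matrix of the isoform model, then normalises `f` to sum to one. The least
squares is Poisson-weighted (rows scaled by `1/sqrt(count + 1)`) — a
one-line refinement over raw-count least squares that accounts for the
variance of count data. The solver is a self-contained Lawson–Hanson
active-set NNLS (no NNLS package ships with the target environment).
Junctions observed but absent from the model are reported, never silently
dropped, and isoforms with identical junction signatures are flagged
non-identifiable.

Estimator accuracy depends on the conditioning of `M`. On a cassette-exon
pair the recovery error at 10^4 multinomial reads is well below 0.05. The
packaged six-isoform locus (`six_isoform_model()`, a synthetic stand-in
with a cassette exon carried by two of six isoforms and ~91% of mass on
the two major isoforms) has nearly collinear columns for the rare
skip-isoforms, and recovery at the same depth is within ~0.10. Noise-free
proportional counts are recovered exactly (residual 0) whenever columns
are distinct.

`classify_codon_substitution()` translates reference and substituted
codons under the standard genetic code and labels the change synonymous,
missense or nonsense — e.g. a first-position C-to-T in CAG (glutamine)
yields TAG, a nonsense substitution that truncates any isoform whose
reading frame contains it.

## The correction experiment

```{r corr, eval = FALSE}
report <- correlation_experiment(n_cells = 12, seed = 1)
report
```

Per cohort the experiment draws `delta0 ~ U(1.5, 3.5)` µm, simulates a
movie per cell (16 frames, 0.2 µm/px — a coarser, faster variant of the
stated world that leaves every contrast intact), measures the initial
furrow basal distance at onset and the GMC area at the end of ingression
with the full pipeline, and reports Pearson r/R² per cohort plus the
Mann–Whitney comparison of areas. With the correction off the measured
correlation is strong and positive (r > 0.8 at n = 30); with it on, R²
collapses (<= 0.2), reproducing the corrected-vs-uncorrected contrast as a
property of the pipeline rather than a number read off a figure.

## Known limitations

* Contour tracing rounds sharp furrow-fold corners (~2 px); use the
  linescan-based ring diameter and polygon-split areas, which do not
  inherit this error.
* The `d0` anchor relies on the nascent ring having intensity contrast at
  anaphase; for ringless markers it falls back to the (later, slightly
  less accurate) onset furrow points.
* The enrichment index is only defined relative to a furrow that can be
  excluded; pre-ingression frames are used only when no frame shows a
  furrow.
* The exact/approximate Mann–Whitney switch at combined n = 20 is a
  convention; p values in the 20–50 range differ slightly from fully exact
  enumeration.
* The six-isoform frequency estimates for rare skip-isoforms are
  ill-conditioned by construction; treat sub-5% frequencies from junction
  counts as order-of-magnitude estimates.
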