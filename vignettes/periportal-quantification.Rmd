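---
title: "Periportal collagen quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periportal collagen quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfib)
```

## The measurement problem

Staging early NASH fibrosis hinges on a subtle histological distinction:
stage F1 disease shows perisinusoidal collagen only, while stage F2 adds
collagen around the portal tracts. On dual-channel nonlinear microscopy
the collagen is imaged label-free — fibrillar collagen emits
second-harmonic (SHG) signal at half the 780 nm excitation wavelength,
while two-photon excited fluorescence (TPEF) shows the surrounding tissue
architecture. `qfib` turns such image pairs into a fixed 56-parameter
morphometric vector per biopsy and screens cohorts of vectors for
parameters that discriminate F1 from F2.

The geometric heart of the method is the **periportal region**: every
tissue pixel within a 100 µm Euclidean radial margin of a portal tract,
excluding the tract itself. Collagen inside this margin is periportal
collagen; the perisinusoidal compartment that remains after the carve-out
is the **reduced perisinusoidal (RPS)** region. Portal tracts, the
periportal margin and RPS partition the tissue exactly: the three masks
are pairwise disjoint and their union is the tissue mask.

## Pipeline and its assumptions

For one sample the pipeline is:

1. **Tissue mask** — Otsu's threshold on the Gaussian-smoothed TPEF
   channel (σ = 2 px), with interior background holes up to 500 µm²
   filled. Assumes tissue autofluorescence is brighter than the slide
   background; no attempt is made to classify tissue type.
2. **Collagen mask** — Otsu's threshold on the SHG channel restricted to
   tissue pixels, then removal of components below 0.5 µm². The automatic
   threshold is accepted only when its effectiveness
   (between-class/total variance ratio, η) reaches 0.8: a detector-noise
   SHG channel is a clipped Gaussian with η ≈ 0.75 independent of the
   noise level, while any genuine collagen signal is strongly bimodal
   (η ≥ 0.9), so the guard declares noise-only channels collagen-free
   instead of thresholding mid-noise. Fixed and percentile thresholds are
   available as config overrides.
3. **Portal tracts** — user-supplied annotation masks are the supported
   input; a heuristic detector (bright TPEF blobs ≥ 2000 µm²) exists for
   triage only and is flagged experimental, because automated portal
   delineation is an open problem we do not claim to solve.
4. **Region partition** — exact Euclidean distance transform of the
   portal mask on the pixel grid, converted to µm through the
   calibration; periportal = distance in (0, 100] µm, intersected with
   tissue. The boundary is inclusive, margins of nearby tracts merge by
   set union, and the margin is measured from the tract boundary, not its
   centroid, which is what "radial margin around the tract" means
   geometrically.
5. **Fiber strings** — one fiber per 8-connected collagen component
   (8-connectivity preserves diagonal fiber continuity). Each fiber gets:
   area (pixel count × pixel area), skeleton length (Zhang–Suen thinning;
   arc length sums 1-px orthogonal and √2-px diagonal steps between
   adjacent skeleton pixels, with a one-pixel floor), and mean width =
   area / length. Branched components are one fiber; we do not split at
   branch points.
6. **Classes** — long if length ≥ 20 µm, thick if width ≥ 3 µm,
   aggregated if area ≥ 200 µm²; complements are short / thin /
   distributed. All three dichotomies are exhaustive and
   boundary-inclusive. These cut-offs are *declared defaults*, not
   community standards — the original algorithm's values are unpublished
   — so they live in `morphometry_config()` and are recorded in every
   output.
7. **Intersections** — skeleton pixels with ≥ 3 skeleton neighbours;
   a junction produces a small clump of such pixels, so branch points
   closer than 1 µm are merged by single linkage and each cluster counts
   once.
8. **The 56 parameters** — for each region (periportal, RPS) and stratum
   (all / aggregated / distributed): collagen area percentage of the
   region, fiber counts overall and by class, summed area, length and
   width, plus the per-region intersection count. Percentages follow the
   collagen-proportionate-area convention (collagen area ÷ region area);
   the alternative reading (share of whole-slide collagen) would make the
   periportal and RPS parameters mutually redundant. Portal-tract
   collagen contributes to no parameter. Region assignment is by majority
   pixel overlap with ties broken periportal > portal > RPS, keeping the
   region of interest when a fiber straddles the boundary.

### Calibration

The default calibration is 512 × 512 px tiles covering 200 × 200 µm,
i.e. 0.390625 µm/px, matching 20× acquisition on the imaging system the
method targets; it is overridable everywhere. Mosaics are stitched from
abutting, pre-aligned tiles in row-major order — no registration or
blending, because tile overlap is not part of the acquisition model.

## The statistical screen

Cohorts of parameter vectors are compared with the two-sample Wilcoxon
rank-sum test, two-sided, one test per parameter, significance at
**p < 0.05 strictly** (a p-value of exactly 0.05 is not significant).
No multiplicity correction is applied by default — the screen
reproduces a per-parameter error-rate analysis — but Benjamini–Hochberg
adjustment is available behind a flag. Exact enumeration of the null is
used for tie-free samples with combined n ≤ 16; otherwise the normal
approximation with midranks, tie correction and continuity correction.
A pooled sample with all values identical carries no evidence and
reports p = 1.

The two-stage design (`screen_and_validate()`): stage 1 screens all 56
parameters on a discovery contrast; stage 2 re-tests only the stage-1
hits on the validation contrast (true F1 vs true F2); the discriminant
panel retains the stage-2 parameters with p < α, in schema order.
Applying the retention rule to the reference validation table shipped
with the package (`reference_validation_pvalues()`) keeps 26 of 28
candidates, dropping the two `#ThinStr` periportal rows at p = 0.054.

Sidedness was not specified in the original analysis; we use two-sided
tests as the conservative default. Likewise whether the original
validation used exact or approximate p-values is unknown; at the
original group sizes (17 and 30) both converge to the approximation.

## The synthetic-data generator

No clinical images are distributed with the method, so every claim the
package makes is validated on synthetic slides with exact ground truth.
A `stage_profile()` fixes the study conditions:

* geometry: one portal tract of radius 30–50 µm inside an irregular
  elliptical tissue silhouette;
* fiber placement: Poisson counts at a rate per 10⁴ µm² of target-region
  area — F0-like: no collagen (and no portal collagen rim, so the SHG
  channel is pure detector noise); F1-like: RPS rate 6, periportal rate
  0.2 (perisinusoidal fibrosis with at most stray periportal fibers);
  F2-like: adds periportal rate 8 with perisinusoidal settings identical
  to F1-like, so the F1/F2 contrast is localised to the periportal
  compartment by construction;
* fiber morphology: log-normal lengths (median 15 µm) and widths
  (median 1.5 µm); a 15% fraction is drawn as aggregated bundles
  (median 40 × 6 µm) whose area exceeds the aggregation cut-off;
* noise: additive Gaussian (σ = 0.02 of full scale) on both channels.

Rendered fibers are smoothed random-walk polylines stamped with a
constant-width disk, placed so that fibers touch neither each other nor
the portal tracts; every fiber therefore survives as its own connected
component, and the pipeline should recover fiber counts exactly on
noise-free renders. Ground-truth bookkeeping records realized pixel
areas, polyline lengths and the same majority-vote region assignment the
pipeline uses.

The default slide is 1024 × 1024 px (400 × 400 µm): a single 200 µm tile
cannot hold a portal tract, its 100 µm margin *and* a meaningful RPS
remainder.

What the generator does **not** emulate: point-spread functions,
polarization effects, intensity attenuation with depth, touching or
overlapping fiber networks, septa, vessels and bile ducts, staining or
sectioning artifacts. Passing the recovery tests therefore demonstrates
that the measurement chain is internally consistent — not that
segmentation is robust on clinical material, where threshold choice and
portal annotation quality will dominate.

### Two generation paths

`generate_slide(render = TRUE)` produces images plus pixel-exact truth
and feeds the image-pipeline validation. `render = FALSE` skips
rendering: fiber lengths and widths are drawn from the profile, areas
taken as length × width, and only the region geometry is resolved — on a
grid up to 8× coarser (~3.1 µm effective pixels), since only region
*areas* enter the bookkeeping and their discretisation error (< 1%) is
far below the Poisson sampling noise of the counts. This fast path makes
cohort-level simulation practical; per-sample intersection counts on
this path are a stylized Poisson proxy (rate 0.15 per fiber in the
region), sufficient to carry count-correlated signal through the screen.

## Simulation studies the tests run

All simulations fix their seeds and use n = 15 samples per group,
matching the scale of the clinical cohorts the method targets.

* **Null calibration**: 1000 replicate cohorts with both groups F1-like;
  each cohort contributes one parameter test, rotating through the 28
  RPS parameters (one test per cohort keeps the 1000 replicates
  independent; under this profile the periportal family is structurally
  zero and carries no information about test calibration). The flagged
  fraction at α = 0.05 is required to lie in [0.03, 0.07]. Structurally
  sparse parameters (e.g. thin-aggregated counts) are heavily tied and
  make the screen mildly conservative; the pooled rate in practice sits
  near 0.045.
* **Power**: 100 replicate F1-like vs F2-like cohorts; the seven
  periportal count parameters the contrast drives must be significant in
  ≥ 80% of cohorts (observed: essentially always, as the simulated
  periportal effect is large).
* **Specificity**: under the same contrast, RPS parameters stay at their
  false-positive rate.
* **Geometry**: for a circular tract of radius 50 µm the periportal mask's
  area is within 2% of the analytic annulus π((r+100)² − r²) and its
  maximal distance-transform value is 100 µm to within one pixel.

## Numerical and degenerate-input choices

* Distances: exact Euclidean distance transform; when a bound is known
  the computation is windowed to the portal bounding box plus margin,
  which changes nothing within the bound.
* Empty portal mask → empty periportal region; empty tissue is an error.
* A region with fibers but zero area reports 0 for its percentages with
  a warning (keeping cohort tables rectangular) rather than NaN.
* An all-zero channel is valid input: no tissue, no collagen, all 56
  parameters zero.
* Connected components: 8-connectivity for foreground, 4-connectivity
  for background hole-filling (the standard duality).
* Single-pixel fibers have length one pixel by declaration, so width =
  area/length never divides by zero.
* All randomness flows through per-call seeds; generation restores the
  caller's RNG state.

## Known limitations

* Thresholds for long/thick/aggregated are declared, not estimated; on
  real data they should be calibrated against expert annotation before
  any clinical use.
* The heuristic portal detector is not validated and annotation masks
  remain the supported input.
* Fiber extraction treats a collagen component as one fiber; dense
  fibrosis with merging fibers will undercount strings and overestimate
  widths. The non-touching placement in the generator deliberately
  avoids this regime, so the recovery tests do not probe it.
* The screen controls per-comparison error only; the 56 tests are not
  corrected by default, by design, to mirror the original analysis.
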