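---
title: "Quantifying amyloid plaques and their proximity bands: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid plaques and their proximity bands: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqband)
```

## The measurement problem

In amyloid neuropathology the interesting biology concentrates around
plaques: dystrophic neurites accumulate near the plaque surface, microglia
cluster against it, and lysosomal activity rises in the clustered cells.
`plaqband` implements the corresponding measurement chain for
multi-channel fluorescence sections: segment each channel with the
classical automatic-threshold operators, detect plaques as connected
components with an equivalent-diameter floor, build a fixed-width
proximity band around every plaque outline, and quantify each marker
inside the plaque and in its band. A seeded synthetic-section generator
with complete ground truth makes every stage testable without any imaging
data, and a statistics layer covers the group comparisons such studies
report.

## Segmentation model

Each channel is max-projected over z, background-subtracted with a
rolling-ball estimate (grayscale opening with a flat disk; radius
`ball_radius_px`, default 25 px), smoothed with a truncated Gaussian
(`sigma_px`, default 2 px, mirror-reflected boundaries), and thresholded.
The four classical histogram algorithms are implemented from their
original definitions on 256-bin histograms with 8-bit semantics (integer
images in [0, 255] are binned at the integer levels):

* **Otsu** — maximize between-class variance; ties break toward the
  smaller threshold.
* **Li** — minimum cross-entropy fixed point
  `t = (mu_f - mu_b) / (log mu_f - log mu_b)`; intensities are shifted to
  be strictly positive when the histogram includes zero (the shift is
  reported and removed from the returned threshold), and the iteration
  stops on a stable class split so the returned value is an exact fixed
  point.
* **Intermodes** — iterated 3-bin mean smoothing of the histogram until
  exactly two modes remain; the threshold is the midpoint level. The
  iteration errors out, with a diagnostic, on histograms that become
  unimodal — sparse punctate channels can genuinely do this.
* **Moments** — Tsai's moment-preserving split: the unique two-level image
  matching the first three raw moments, thresholded at the p-tile of the
  background fraction.

The foreground rule is strictly greater-than everywhere. Default method
per channel role: Otsu for the plaque dye, Intermodes for the neurite
marker, Moments for the microglial and lysosomal markers; Li is the
morphometry path's threshold. On a clearly bimodal mixture all four
operators land between the modes, but none is guaranteed to stay within a
fixed window between the class means: on a 30/180 mixture with SD 10 the
canonical Otsu and Moments occasionally sit just outside [60, 150]
(scikit-image's Otsu behaves identically), so the package's tests assert
separation at means ± 2.5 SD rather than a tighter window.

## Plaques, bands and counting rules

Plaques are 8-connected components of the plaque mask; the equivalent
diameter is `2 * sqrt(A / pi)` and components at or below 9.9 µm diameter
are discarded — the conventional counting floor. The proximity band is the
set of pixels whose Euclidean distance to the plaque is in (0, w] with
w = 30 µm by default, computed with an exact distance transform; the
plaque interior is excluded and interior quantities are always reported
separately. Bands of different plaques are independent: a pixel may lie in
two bands. Border-clipped plaques are flagged and excluded from
per-plaque statistics by default.

Marker quantification in a region reports positive area (marker mask ∩
region), mean intensity over *all* region pixels, and the number of
8-connected marker components touching the region. Microglial somata are
detected as the blobs that survive a disk opening (radius 3 px) of the
microglia mask, split by a watershed of the distance map where cells
touch, and filtered by area (≥ 20 µm²) and compactness (blob area at
least 0.4 of the circle through its farthest pixel) — the compactness gate
rejects the elongated or fan-shaped remnants that overlapping processes
leave in the opened mask, an operational proxy for "clearly visible
soma". A soma centroid inside the plaque mask counts as within; in a band,
as around, assigned to the nearest outline when bands overlap (ties to the
lower plaque id).

## Skeleton morphometry

Microglial masks are thinned with two-subiteration Zhang–Suen thinning
iterated to a fixed point, with two safeguards: components the classic
scheme would erase entirely (isolated 2×2 blobs) are retained as their
most central pixel, and any residual filled 2×2 block is reduced by
removing a simple pixel, so downstream metrics always see a 1-px-wide
skeleton while the component count is preserved.

All topology is read from the *reduced curve graph*: pixels are nodes;
edges are orthogonal adjacencies plus those diagonal adjacencies whose two
pixels do not share an orthogonal skeleton neighbour. The excluded
diagonals are corner shortcuts — on a digital staircase they would
otherwise create spurious triangles, inflating lengths by up to a third
and turning ordinary curve pixels into fake junctions. With the reduced
graph an interior staircase pixel has degree 2, endpoints are degree ≤ 1
nodes, branch pixels are degree ≥ 3 nodes (adjacent branch pixels merge
into one junction), and length sums the edges at 1 px (orthogonal) and
√2 px (diagonal). Spur pruning removes endpoint-to-junction paths shorter
than a threshold (default 3 µm) and re-thins. Per-cell selection keeps
skeleton components overlapping exactly one soma with total length in a
configurable window; components touching two somata are rejected and
counted as merged — the automated stand-in for the visual single-cell
selection such analyses perform, validated only on synthetic ground truth.

Digital curve length systematically overestimates smooth arc length by up
to ~8–20% depending on orientation; the tests therefore require exact
endpoint recovery but only distributional agreement for lengths (90% of
cells within 15%, all within 25%).

## The synthetic section generator

`section_config()` defines the study conditions; `generate_section()`
renders a 4-channel 8-bit-scale section and returns ground truth recorded
before noise. Modelling choices, stated once:

* **Plaques**: Poisson count at `plaque_density` (default 40/mm²),
  log-normal diameters (meanlog log 20, sdlog 0.3, truncated to
  [10.5, 50] µm), centers placed by rejection so outlines stay
  `plaque_margin_um` apart (default 10 µm — plaques are discrete objects
  and merged rendering would conflate components). The radial profile is a
  plateau with a sharp logistic shoulder (scale 0.4 px) at the planted
  radius, calibrated so Otsu segmentation of a noise-free section recovers
  the diameter to about one pixel.
* **Dystrophic neurites**: per-plaque Poisson counts with mean
  `alpha + beta * diameter` (defaults 2 + 0.4/µm, so counts grow with
  plaque size), placed area-uniformly in the 30 µm band with a 1.5 µm
  inner/outer safety margin (rasterised distances stay inside the band)
  and a 9 µm minimum punctum separation, so that each punctum remains one
  connected component after the default smoothing — the generator plants
  objects the measurement definitions can resolve.
* **Microglia**: per-plaque Poisson counts scaled by `condition_factor`
  (the Western-diet/diabetes suppression of clustering; 0.6 in the
  condition arm of the bundled experiments), somata of radius 4–6 µm in
  the band (a quarter inside the plaque when it is large enough),
  background cells kept clear of every band; 2–6 processes per cell as
  persistent random walks from the soma centre (step 1 px, angular noise
  0.04 rad/step, evenly spread base angles with ±0.15 rad jitter), walk
  length clearing the soma by 8–16 µm, rendered as the walk's own 1-px
  pixel chain (~1 µm wide). A cell whose processes run within 3 px of each
  other outside the soma is redrawn, and cells are placed far enough from
  the field border that every walk fits — planted process topology is
  exactly recoverable, which is what the morphometry tests require.
  `microglia_min_gap_um` separates soma edges: 4 µm by default (realistic
  clustering, somata still resolvable by the watershed), raised to ~42 µm
  in per-cell morphometry fixtures so whole cells never touch.
* **Lysosomal puncta**: Poisson per soma (rate 3 × condition factor),
  uniform inside the soma.
* **Noise**: additive Gaussian (σ = 5 by default) plus a smooth tilted
  background gradient (peak-to-peak 10), added last; intensities clip to
  [0, 255]. Optional z-stacks replicate the plane with per-slice
  multiplicative jitter; ground truth lives on the projection, which is
  also the analysis surface.

Cohorts derive one counter-based sub-seed per section from a master seed,
so any member regenerates in isolation.

What the generator does **not** emulate: optical point-spread functions
and z-blur, autofluorescence texture, section-to-section staining
variability, plaque morphology classes (dense-core vs diffuse), microglial
process branching, and cells truncated by the field border. Passing
recovery tests therefore show the measurement chain is correct under the
generator's assumptions, not that it is robust to everything real tissue
does.

## Statistics layer

Two-way between-subject ANOVA uses Type II sums of squares (identical to
Type I/III on balanced designs; the balanced from-scratch decomposition is
the test oracle). Mann–Whitney U uses mid-ranks, exact enumeration
p-values when n₁+n₂ ≤ 14 without ties and the tie-corrected normal
approximation (no continuity correction) otherwise. Kruskal–Wallis H is
tie-corrected with χ² p-values, and reduces to the squared Mann–Whitney
normal deviate for two tie-free groups. Pearson r uses the
product-moment formula with the t approximation; Spearman rho is Pearson
on mid-ranks, also with the t approximation (both coefficient names are
reported explicitly). Fisher's exact test reports the conditional
hypergeometric p (two-sided: tables at most as probable as observed) with
the *sample* odds ratio ad/bc, infinite when a zero cell makes it so.
Printed percentages round half-up (5/22 → 23%). The response-concordance
classifier on paired Z statistics uses the |Z| > 2.5 cutoff: concordant
(both exceed, same sign), discordant (first only), enhanced (second only),
neither — an exhaustive, exclusive partition — plus the genome-wide
Pearson correlation. Relative qPCR expression is 2^−ΔΔCt. A
Benjamini–Hochberg helper serves the transcriptomic path; no correction is
applied by default elsewhere.

The human-cohort module computes BMI as weight/height² (half-up at one
decimal; base R's round-half-even would reproduce several printed values
wrongly, e.g. 31.25 must print 31.3), HOMA-IR in two explicit unit
variants with no silent default (glucose mmol/L ÷ 22.5, or mg/dL ÷ 405),
and the metabolic grouping BMI < 25 / BMI > 30 / BMI > 30 + T2D, warning
on subjects that fit no group. The packaged table's obese non-T2D average
row is internally inconsistent (its printed means are not recomputable
from its three members — e.g. mean BMI recomputes to 33.4 against a
printed 32.6); the package reproduces the per-subject values and the two
recomputable average rows, and deliberately leaves that row out of
exact-match checks rather than "correcting" it.

## Replicated experiment design

`run_cohort_experiment()` mirrors the animal-study design: each animal
contributes three sections, section means are averaged per animal, and the
animal is the statistical unit (Mann–Whitney, two-sided). The bundled
power analysis uses 200 × 200 µm fields at 75 plaques/mm², 8 microglia
per plaque, condition factor 0.6 versus 1.0, 6 animals per group —
compact sections keep 100 replicates affordable while each replicate still
carries ~75 plaques per group. Planted-count measurement
(`measure = "ground_truth"`) is the fast path for the 100-replicate power
and type-I calibration; the full segmentation chain
(`measure = "pipeline"`) is run at a reduced replicate count to show the
measured effect carries through. The type-I calibration at factor 1.0 is
judged against the binomial 95% band around 0.05; the exact Mann–Whitney
at n = 6 + 6 is slightly conservative, which the band accommodates.

## Numerical conventions and degenerate inputs

Pixel (i, j) has its centre at ((i−1)·s, (j−1)·s) µm for pixel size s;
all areas and lengths are reported in µm²/µm. Constant images raise a
degenerate-histogram error rather than returning an arbitrary threshold.
An empty ROI is an error; an empty plaque mask is an empty result. A
zero-variance correlation returns NaN with a warning. Interaction ANOVA
with an empty cell, or one observation per cell, raises an error.
Thresholding ties, soma assignment ties and component ordering are all
resolved by documented deterministic rules, and identical configuration
plus seed reproduces output bit-for-bit.

## Problem sizes used by the bundled analyses

The recovery analyses use three 500 × 500 µm noise-free sections (sparse
fixture) and six 300 × 300 µm microglia fields; the correlation property
uses 100 seeds of a 1 mm² field carrying ≥ 200 plaques each
(ground-truth fast path); power and calibration use 100 replicates of the
6 + 6 animal design with three sections per animal, and 15 full-pipeline
replicates. These sizes give stable Monte-Carlo estimates (binomial SE
≤ 5 percentage points on fractions) at desktop runtimes.

## Known limitations

* The rolling-ball background is the grayscale opening approximation, not
  the original sliding-paraboloid variant.
* Thresholds are computed per image; a shared-threshold mode across a
  group is provided as an option but the bundled analyses do not use it.
* Manual plaque outlining workflows are supported only by accepting an
  externally supplied plaque mask.
* Skeleton lengths inherit the digital-curve overestimate; endpoint and
  junction counts are exact on resolvable cells, but cells whose processes
  genuinely overlap (merged components) are rejected rather than
  disentangled.
* The 2D analysis surface means true 3D morphology (and any z-dependent
  intensity structure) is outside the model.
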