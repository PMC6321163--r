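---
title: "Measuring amyloid fibril morphometry from AFM height maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring amyloid fibril morphometry from AFM height maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibriltrace)
```

## The measurement problem

AFM topography of amyloid-beta on mica yields height maps in which the
biology lives in objects a few nanometres tall: compact oligomers and
curvilinear fibrils. The raw images additionally contain sample tilt,
scanner bow (a quadratic bend along each scan line), and line-to-line
offsets, all of comparable or larger magnitude than the features
themselves. The quantities of interest per experimental condition — a DHA
concentration crossed with an incubation time — are the mean fibril
length, the mean fibril height, and the fraction of the surface covered
by aggregate. Every choice below exists to make those three numbers
comparable across conditions.

## Background removal

Flattening proceeds in stages, each absorbing the model error of the
previous one:

1. a global least-squares plane (sample tilt);
2. per-line median subtraction (line offsets);
3. per-line second-order polynomial subtraction (scanner bow), fitted
   only to pixels *not* masked as features.

The feature mask is the critical step. Fitting the bow through fibril
pixels biases the background upward under every feature and carves
shadow artefacts beside them; excluding the tallest pixels first avoids
that. Interactive AFM analysis traditionally does this with a cutoff the
operator chooses by eye. We parameterise it reproducibly as
`median + k_mask * 1.4826 * MAD` of the pixel heights, with
`k_mask = 3` by default; MAD-based spread keeps the threshold insensitive
to the features it is meant to exclude. Because the threshold sits above
the median, the mask can never exceed half the image, and a guard refuses
any mask that leaves less than 10% background for fitting. Two
mask-flatten passes are run by default: the first mask is computed on a
still-bowed image, the second on the much flatter result, which
stabilises it; more passes change nothing measurable on our scenes.
Lines left with fewer than `order + 2` unmasked pixels (a line crossed
along its length by a fibril) reuse the element-wise median of the other
lines' coefficients rather than having their background invented from
two points.

The polynomial basis is `1, x, x^2` with `x` the centred column index in
pixels. On any background that is exactly plane + per-row quadratic the
whole chain is exact to numerical precision, which the test suite
asserts at `1e-9` nm.

## The background height reference

After flattening, the background pixel heights are histogrammed (256
bins across the 0.1–99.9 percentile range; the percentile clip keeps
stray feature pixels from stretching the bins) and a Gaussian
`A exp(-(h - mu)^2 / 2 sigma^2)` is fitted by Levenberg–Marquardt from
moment-based starting values. The fitted peak `mu` becomes the zero of
all subsequent height measurements — far more stable than referencing
local neighbourhoods, whose value fluctuates with the noise. `sigma`
calibrates the detection threshold. If the optimiser fails (it does not
on any tested input, but robustness costs nothing) the sample
median/MAD are used with a warning; if the background has numerically
zero spread — possible only for noise-free synthetic input — the model
degenerates explicitly (`sigma = 0`) rather than fitting femtometre-scale
rounding residue, and detection falls back to a tiny positive height
floor.

On 1024² pure-noise images the fit recovers `mu` within ±0.05 standard
deviations and `sigma` within 5% in at least 95% of seeds (asserted over
20 seeds in the acceptance suite).

## Detection and measurement

Detection thresholds the flattened image at `k_detect * sigma`
(default 5, i.e. a ~3-in-10-million false-pixel rate on Gaussian
background), labels 8-connected components, and discards components
below `min_area_px = 4` pixels. 4-connectivity would split fibrils
running diagonally; 8-connectivity matches visual continuity at this
sampling. Objects that touch or overlap form a single feature by
design: separating them reliably is not possible in a height map, and
applying the same merging rule to every condition preserves the
between-condition comparison even if absolute values drift. This is a
known, accepted bias of the method.

Per-feature measurement:

* **Length** is the geodesic length of the skeleton (Zhang–Suen
  thinning). The skeleton is traced into its branch paths; each path is
  measured as a polyline sampled every third pixel, which suppresses the
  staircase overestimate of naive step counting (up to ~12% on curved
  paths) while chords this short undershoot real curvature by well under
  1%. Branch lengths are summed, so a branched or overlaid fibril counts
  once, with the combined length of its branches. Thinning erodes object
  ends, so each skeleton endpoint adds `max(EDT - 0.5, 0)` pixels, the
  local distance-to-boundary. For unbranched features the maximum Feret
  extent of the footprint (minus the blur-to-threshold overhang, about
  half a pixel per end) is used when larger: for short, nearly straight
  fibrils the end-to-end extent is the more faithful estimate, while for
  curved ones the skeleton is. Features whose skeleton collapses to two
  pixels or fewer are compact blobs; their length is the Feret diameter
  outright. Whether a fibril's "long axis" should be geodesic or
  end-to-end is genuinely ambiguous for curved objects; we measure
  geodesically, which is the only reading under which branch lengths add.
* **Width** is `2 * mean(EDT) - 1` pixels sampled on skeleton pixels
  (exact for odd-width rods). Collapsed-skeleton blobs take the larger of
  the EDT half-thickness and the area-per-length width, both lower
  bounds that degrade on different shapes.
* **Height** is the maximum in-cluster height above `mu`. Averaging over
  the footprint would systematically underestimate the crest height of a
  ridge-shaped object, so the maximum is used even though it rides ~1-2
  noise standard deviations high.
* **Class**: a feature is a fibril when `length >= 2 * width`. One guard
  supplements the ratio at the resolution floor: a footprint contained in
  a 3 × 3 pixel box cannot support a credible 2:1 aspect judgement and is
  classed as an oligomer.
* Features touching the image border are measured but flagged and
  excluded from length/height statistics — their true extent is
  unknowable.

Surface coverage is the percentage of detected pixels after min-area
filtering, oligomers and fibrils together.

## Aggregation

Within a condition, fibril lengths and heights are pooled across images
(features are the measurement unit; thousands of measurements accumulate
per condition) with `SEM = sd / sqrt(n_fibrils)`. Coverage is defined
per image, so its mean and SEM use images as the replication unit. A
condition with no usable fibrils reports an explicit marker, never a
zero. Length distributions are summarised by a Gaussian-kernel KDE with
Silverman's rule-of-thumb bandwidth — the closest documented equivalent
of common violin-plot defaults — evaluated on a 128-point grid extended
three bandwidths past the data range, so the trapezoid integral is 1
within 1%. Error bars in all outputs are labelled SEM explicitly.
Condition contrasts are ratio-based (`ratio`, `percent change`, and
`percent reduction of the smaller mean`), which is how statements like a
"50% reduction in fibril length" or "well over triple the length" are
computed from per-condition means. No hypothesis testing is performed:
the readout of this analysis is means with errors and distribution
shapes, and inventing inferential machinery around them would misstate
what the data support.

## The synthetic scene generator

Because the measurement chain cannot be validated on images without
ground truth, the package generates AFM-like scenes with every object's
true geometry recorded:

* **Fibrils** are discrete worm-like chains: fixed 0.5-px steps with
  i.i.d. Gaussian turning angles of variance `2 * step / P`, giving
  tangent correlation `exp(-s/P)` and hence the standard closed form
  `<R²> = 2PL - 2P²(1 - exp(-L/P))`, which the test suite checks against
  1000 sampled chains. The default persistence length is 4 µm — amyloid
  fibrils are stiff, with literature values from one to tens of
  micrometres — so rendered fibrils are gently curved, like the imaged
  ones. Chains are painted as flat-topped ridges of the stated apparent
  (tip-broadened) width with a 0.8-px radius floor that keeps sub-pixel
  ridges gap-free, then blurred by a small Gaussian (`tip_blur_px = 0.5`)
  representing residual instrument smoothing.
* **Oligomers** are hemispherical caps, radius 15 ± 2 nm (floored at
  10 nm) and height 1.8 ± 0.25 nm: large enough to be firmly detectable
  at the default sampling, as the study's 1:10 dilution was chosen to
  make them.
* **Background and noise**: plane tilt (4 and 3 nm across the image),
  per-scan-line quadratic bow of 3 nm with ±20% per-line amplitude
  variation, per-line offsets of 0.15 nm RMS, and 0.08 nm RMS Gaussian
  pixel noise — a typical noise floor for tapping-mode imaging on mica.
  Fibril heights default to 3 ± 0.4 nm, in the range reported for
  Aβ1–42 fibrils on mica. Overlapping objects add, capped at 1.5× the
  tallest object.

The default condition grid renders 8 images per condition at 512 px over
5 × 5 µm — the same 9.77 nm/px sampling as a 1024-px scan of 10 × 10 µm,
at a quarter of the area, which keeps the full 72-image dataset
tractable on one CPU. Median true lengths follow the reported 30 µM
series (64, 88, 126 nm at 1, 6, 24 h) with the control reaching 250 nm
and the 100 µM arm 421 nm at 24 h; geometric SDs grow with time and are
largest in the 100 µM arm, whose distributions are visibly
heavier-tailed. Object counts grow with time and keep both length and
coverage ordered 30 < 0 < 100 µM at every time point. Counts in the
100 µM arm rise only mildly: its growth is expressed in length and
coverage, keeping long fibrils mostly separable so that ground truth
remains meaningful.

## What passing tests do and do not show

The generator emulates the *geometry* of these images faithfully enough
to exercise every pipeline stage: realistic background structure, tip
broadening, sub-pixel ridge widths, merging of touching objects, noise at
realistic SNR. It does not emulate tip-shape convolution (a Gaussian
blur is not a dilation by a real tip), height-dependent imaging
artefacts, surface contamination, salt crystals, or the judgement calls
a microscopist makes on marginal images. Recovery results on synthetic
grids therefore validate the measurement chain, not the instrument
model: on the default grid the per-condition mean fibril length is
recovered within 10% and coverage within 0.3 percentage points, with the
densest, longest-fibril condition (100 µM, 24 h) biased low by several
percent — over-merging joins fibrils (raising individual lengths but
removing features) and skeleton smoothing absorbs sub-width wiggles of
very long chains. Per-feature skeleton lengths can shift by ~10% under
90° rotation for unluckily oriented curved objects (thinning is not
isotropic); counts are rotation-invariant and aggregate lengths move by
under 2%, which is the level at which the analysis operates.

## Numerical choices and degenerate inputs

* Histogram fit: 256 bins, moment initialisation, 200 LM iterations;
  spreads under `1e-9` nm are declared degenerate rather than fitted.
* Flattening exactness: plane + per-row quadratic backgrounds reduce to
  `< 1e-9` nm residual; the pipeline is idempotent on noise-free input to
  within 10 machine epsilons of the dynamic range.
* Detection with `sigma = 0` (noise-free input) uses a `1e-9 ×
  max|height|` floor so ideal synthetic scenes remain analyzable.
* Ties and ordering: component labels are renumbered by first pixel in
  column-major order, making label ids, feature tables, and CSV output
  byte-deterministic for a fixed seed and configuration.
* Seeds: every generator takes an explicit seed; the condition grid
  derives per-image seeds from the master seed via the seeded RNG.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `mask_k` | 3 | robust sigmas | feature mask for background fitting |
| `k_detect` | 5 | fitted sigmas | detection threshold |
| `min_area_px` | 4 | px | component noise rejection |
| `poly_order` | 2 | — | per-line background polynomial |
| `n_passes` | 2 | — | mask -> flatten iterations |
| `n_bins` | 256 | — | background histogram |
| `kde_grid` | 128 | — | KDE evaluation points |

`mask_k` and `k_detect` are deliberately separate: masking errs toward
excluding too much (only the background fit suffers, mildly), detection
errs toward excluding too little (every statistic depends on it).

## Known limitations

Merged objects stay merged, so absolute feature counts and lengths are
condition-comparable rather than absolute; edge-touching features are
excluded from length statistics, which slightly under-samples the
longest fibrils in dense scenes; heights ride the noise maximum by
design; and the classification boundary at exactly `length = 2 * width`
is sharp, so features near it flip class under resampling. All are
properties of the measurement definition itself rather than artefacts
of this implementation, and all are exercised explicitly in the test
suite.
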