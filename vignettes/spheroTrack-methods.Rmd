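---
title: "Rigid motion correction and cell-cycle-resolved tracking in free-floating assembloids"
author: "spheroTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid motion correction and cell-cycle-resolved tracking in free-floating assembloids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroTrack)
```

## The problem

Free-floating spheroid and assembloid cultures — for instance a glioblastoma
(GB) spheroid fused with a cerebral organoid — drift and spin between frames
of a time-lapse acquisition. The whole-structure motion is, to a very good
approximation, rigid over one frame interval: a translation $(\Delta x,
\Delta y)$ plus a rotation $\theta$ about the structure's center. This global
motion swamps the micron-scale movements of individual cells, so single-cell
migration cannot be measured until it is removed. spheroTrack estimates and
removes that rigid motion, then extracts per-cell trajectories from FUCCI
(Fluorescent Ubiquitination-based Cell Cycle Indicator) reporter channels,
calls cell-cycle phase from the red/green hue, and summarises migration with
path length, net displacement, and convex hull area (CHA).

## The registration model

Each frame pair $(n, n+1)$ is related by a rigid transform
$p' = R(\theta)\,(p - c) + c + t$ with pivot $c$ at the image center.
The estimate is built in three stages, iterated to convergence:

1. **Translation.** At least six square templates are drawn from the
   highest-local-variance positions inside the (eroded) convex hull of the
   structure in frame $n$ and matched against frame $n+1$ by zero-normalised
   cross-correlation, $\mathrm{ZNCC} = \sum \tilde I \tilde T /
   \sqrt{\sum \tilde I^2 \sum \tilde T^2}$, over a bounded search window.
   Each peak is refined to subpixel precision by a quadratic fit;
   $(\Delta x, \Delta y)$ is the componentwise median over templates scoring
   at least 0.5. Perfect lattice matches skip the quadratic refinement, so
   integer shifts of identical imagery are recovered exactly.
2. **Rotation.** Both frames are polar-unwrapped about the center (rows =
   radius, columns = angle), where a rotation becomes a circular horizontal
   shift. Up to 40 rectangular regions tiled over the informative radius
   band (25–95% of the hull radius; the center is angularly degenerate and
   the outside is background) are matched by normalised squared difference,
   $\sum (T - I)^2 / \sqrt{\sum T^2 \sum I^2}$, with wraparound; regions
   scoring at most 0.3 vote, and $\theta$ is the median of their subpixel
   offsets times the angular bin width.
3. **Refinement.** Updates are damped ($\lambda = 0.5$) and the
   translation–rotation–translation cycle repeats until the per-iteration
   updates fall below 0.5 px and 0.1°, or 15 iterations are reached. The
   damping suppresses the translation/rotation cross-talk oscillation that
   an undamped alternation exhibits; an optional 3-point running median over
   the per-pair $\theta$ series (off by default) is available when the
   oscillation is temporal rather than within-pair.

Registration of a stack anchors on frame 0: its segmentation centroid
(Gaussian smoothing at $\sigma = 2$ px, Otsu threshold, largest connected
component, convex hull) is moved to the image center, and each subsequent
frame is registered against its *motion-corrected* predecessor with the
previous cumulative transform as the starting estimate. This keeps the
reference centered — so the frame-0 hull mask and the fixed polar center
stay valid — while still estimating genuinely per-pair motion.

### Conventions

Pixel coordinates are 0-based, origin top-left, x rightward, y downward;
positions may be subpixel. Positive $\theta$ is counterclockwise on the
displayed (y-down) image. `registerPair()` reports the *motion* of the
moving frame; the correction applied to images is its inverse. Cumulative
motion composes as `pair[k] ∘ cumulative[k-1]`; the inverses (the applied
corrections) therefore compose in the opposite order.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `nTemplates` | 6 | – | translation votes; 6 is the floor for a robust median |
| `templateSizePx` | 64 | px | patch side; must fit inside the eroded hull |
| `searchPx` | 48 | px | first-iteration search radius |
| `nRegions` | 40 | – | rotation votes on the polar image |
| `dthetaBin` | 0.25 | deg | angular bin; with quadratic refinement gives well-sub-0.5° resolution |
| `convTolPx`, `convTolDeg` | 0.5, 0.1 | px, deg | convergence thresholds on damped updates |
| `maxIterations` | 15 | – | refinement cap |
| `damping` | 0.5 | – | update fraction per iteration |

Growth of the structure is deliberately not modelled: the transform is
rigid-only, and slow volumetric expansion appears as a benign, slowly
varying mismatch that the median-over-votes estimators absorb.

## Detection, phase calling, linking

Cells are detected on the red + green sum image as local maxima of a
scale-normalised Laplacian-of-Gaussian response at several scales
($\sigma \in \{2, 3, 4\}$ px by default). Maxima are found per scale and
deduplicated across scales (strongest response wins within 2 px), which
keeps spots separable down to roughly 2 spot widths. Hue is computed from
the mean red/green intensities over the detection footprint on the
half-angle scale, where the occupied red-to-green range is $[0, 60]$:
pure red (G1) $\to 0$, yellow (S) $\to 30$, pure green (G2/M) $\to 60$.
Phase cuts default to G1 $< 25 \le$ S $< 45 \le$ G2/M; detections with both
channels under 5% of the dynamic range are UNKNOWN. The cuts are
config-exposed because FUCCI spectra vary between reporter lines; the
defaults place the canonical G1 hue (~20) and G2/M-entry hues (~50–60) in
the correct bins with S as the yellow band around 30.

Linking is greedy globally-nearest-pair per frame: candidate
(track, detection) pairs within 30 px (≈ 39 µm at 1.3 µm/px, per 60-min
frame) are matched in order of distance; a track may bridge up to 2 missing
frames with the distance budget scaled by the gap. The linker is
deliberately simple — detections are sparse and frame-to-frame motion is
small relative to cell spacing after registration — and identity swaps at
genuine trajectory crossings are accepted (track count is conserved).

## Migration analytics

Per cell: cumulative path length (the default reading of "migration
distance", appropriate for hourly sampling of wandering cells), net
displacement (also exported, for the straight-line reading), and CHA — the
area of the convex hull of all trajectory points, reported in µm². Cohorts
are ranked by CHA; the top-N and bottom-N sets (N = 50 by default) are
summarised by the counts of each dominant phase and the G2/M:G1 ratio. A
cell's phase for these summaries is its modal phase over the trajectory,
ties broken toward the later-occurring phase; UNKNOWN cells stay in the
ranking but are excluded from ratios, and S-phase cells are excluded from
both bins by default (a config flag pools S with G2/M instead). Group
means are compared with the classical equal-variance two-sample t-test.
Infiltration percentage is thresholded fluorescence area inside the host
mask over total mask area.

## The synthetic test bed

`generateScene()`/`renderStack()` emulate what the acceptance of the method
actually requires: a bright, textured, roughly circular structure whose
texture is stable over one frame interval, undergoing per-pair rigid motion,
with compact fluorescent nuclei inside. The defaults are the study
conditions used throughout the tests: 512×512 px frames, 30 frames, disc
radius 150 px, 40 cells of spot width $\sigma = 2.5$ px, per-pair motion
uniform within ±6 px and ±4°, additive Gaussian noise at 2% of the dynamic
range. The texture is band-pass filtered white noise with feature scales of
roughly 8–32 px, so template and region matching see structure at their
working scales. Cell cycle schedules loop G1 (10 frames) → S (5) → G2/M (8)
from a random starting offset; a phase-coupled mode instead fixes each
cell's phase and doubles G2/M step lengths, providing a ground-truthed
"go-and-grow" contrast. Scenes are seed-deterministic, including rendering
noise.

What the generator does **not** emulate: optics (no PSF beyond the Gaussian
spot, no depth attenuation), photobleaching, structure growth or
deformation, cell division, detection-confounding debris, and
intensity-graded FUCCI transitions (phase colors switch discretely).
Passing tests therefore demonstrate correctness of the estimation machinery
under realistic geometry and noise, not robustness to every imaging
artifact of a real acquisition.

## Numerical choices and degenerate inputs

* Matching scores are implemented as explicit formulas (see above) so any
  backend can be validated against them.
* Subpixel refinement is a 3-point parabola; at perfect matches (ZNCC = 1,
  SSD = 0) refinement is skipped to keep integer recovery exact.
* Equal match scores resolve to the smallest offset magnitude.
* Rotation votes use the linear median of angular offsets: offsets are
  bounded by the ±20° search window, far inside a half-turn, where the
  linear and circular medians coincide.
* A frame pair in which no template or region matches is recorded as
  identity motion with a warning; downstream frames keep registering.
* Constant images, empty thresholds, and undersized components raise
  classed segmentation errors; zero-variance texture warns but proceeds.
* `hueOf(0, 0)` is an error surfaced to callers; `detectStack()` never
  produces it because detections require summed intensity above a floor.
* Degenerate t-tests (both groups constant) follow the documented
  convention p = 1 (equal means) / p = 0 (unequal).
* The butterfly Y coordinate uses the signed form
  $\mathrm{sign}(D)\log_2(|D|+1)$: the unsigned $\log_2(D+1)$ is undefined
  for $D \le -1$, and the signed form is the unique odd extension that
  agrees with it for $D \ge 0$.

## Design decisions that were genuinely open

* **z-handling.** Acquisitions are z-stacks but analysis is planar;
  per-channel maximum-intensity projection is applied before all analysis,
  since it preserves bright FUCCI nuclei regardless of focal plane.
* **Filtering and thresholding.** The segmentation filter is Gaussian and
  the threshold Otsu (fixed-threshold override available) — standard
  choices where only "filtering, thresholding" is specified.
* **Centroid.** Geometric (mean pixel position of the filled hull), not
  intensity-weighted: the center of mass of an *outline* is geometric.
* **Where smoothing lives.** Damped within-pair updates by default;
  optional temporal median filtering of the θ series as the alternative
  reading.
* **Problem sizes.** The validation suites run the full default scene
  (30 frames, 512² px), thirty independent frame pairs for the rotation
  precision figure, and a 60-cell phase-coupled scene for the cohort
  contrast — sizes chosen so the whole suite completes in minutes on a
  single core while leaving every estimator operating at its intended
  scale.

## Known limitations

Rigid-only correction (no growth/deformation model); single structure per
field; no mitosis-aware lineage splitting; greedy rather than globally
optimal linking; hue cuts are hard thresholds rather than fitted mixtures.
These match the intended scope: quantifying whole-structure-corrected
single-cell migration by cycle phase, not general-purpose cell tracking.

## A worked example

```{r example, eval = FALSE}
res <- runPipeline(list(seed = 11, output_dir = "demo_out"))
ev <- evaluateRegistration(res$registration, res$scene)
ev$median_abs_dtheta       # median per-pair rotation error, degrees
tk <- evaluateTracking(res$trajectories, res$scene,
                       offset = res$registration@refShift)
tk$recall
res$summary
```
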