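# spheroTrack

Single-cell migration inside free-floating spheroid and assembloid
time-lapse videos is unmeasurable until the global motion of the structure
itself is removed: between consecutive frames the whole assembloid
translates and rotates, swamping the micron-scale steps of individual
cells. spheroTrack is an R package for exactly this setting — tumor
spheroid / organoid co-cultures imaged hourly with FUCCI cell-cycle
reporters — and provides the full chain from raw frames to
phase-stratified migration statistics.

## What it computes

**Rigid registration.** Each frame pair is related by
`p' = R(θ)(p − c) + c + (Δx, Δy)` about the structure center `c`.
Translation is estimated by zero-normalised cross-correlation template
matching (≥ 6 templates from the textured interior of the structure, median
vote, subpixel peak fit); rotation by normalised squared-difference matching
of up to 40 regions on polar-unwrapped frames, where a rotation is a
circular column shift. The translation–rotation–translation cycle is
iterated with damped updates (λ = 0.5) until updates drop below 0.5 px /
0.1°, capped at 15 iterations. All matching is restricted to the convex
hull of the structure, segmented on frame 0 (Gaussian smoothing, Otsu
threshold, largest component).

**Tracking and phase calling.** FUCCI-labelled nuclei are detected in the
registered frames as scale-normalised Laplacian-of-Gaussian maxima on the
red + green image, linked greedily (nearest pair, gap closure), and phase
is called from the half-angle hue `H/2` of `(R, G, 0)`: pure red (G1) → 0,
yellow (S) → 30, pure green (G2/M) → 60, with cuts at 25 and 45.

**Migration analytics.** Per cell: path length, net displacement, and
convex hull area (CHA, µm²) of the trajectory. Per cohort: CHA-ranked
top-N/bottom-N sets, their G2/M:G1 ratios, infiltration percentage, and
two-group Student's t comparisons.

**Synthetic ground truth.** A scene generator renders textured discs under
scripted rigid motion with scripted, phase-coded cells, so every stage can
be validated against known truth. A butterfly projection
(`D = max(OPC, NPC) − max(AC, MES)`, with log2 coordinates and cell-cycle
score `CCS = G1/S + G2/M`) maps per-cell signature scores to lineage-state
coordinates.

## Worked example

```r
library(spheroTrack)

## simulate the default scene (512x512 px, 30 frames, 40 FUCCI cells,
## per-pair motion within +-6 px / +-4 deg, 2% noise) and run everything
res <- runPipeline(list(seed = 11, output_dir = "demo_out"))

ev <- evaluateRegistration(res$registration, res$scene)
ev$median_abs_dtheta
#> [1] 0.06676683
tail(ev$cum_theta_err, 1)
#> [1] 0.6435312

tk <- evaluateTracking(res$trajectories, res$scene,
                       offset = res$registration@refShift)
unlist(tk[1:4])
#>         recall      precision  link_accuracy phase_accuracy
#>      0.9633333      0.9829932      0.9753650      0.9757785
```

The median per-pair rotation error on this scene is 0.067°, the cumulative
rotation error after 29 composed pairs is 0.64°, and 96% of scripted cell
positions are recovered, linked to the correct identity, and called in the
correct cycle phase. `demo_out/` holds `transforms.csv`, `detections.csv`,
`trajectories.csv`, `metrics.csv`, `summary.csv`, and the effective
`config.yaml`; `plots = TRUE` adds trajectory-map, vector-map and
hue-vs-time figures.

A thin command-line front end with `simulate`, `register`, `track`,
`metrics`, `butterfly` and `run` subcommands is installed at
`inst/scripts/spherotrack`.

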