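Package: spheroTrack
Title: Rigid Motion Correction and Cell-Cycle-Resolved Tracking for
    Free-Floating Spheroid Time-Lapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying single-cell migration inside free-floating
    spheroid and assembloid time-lapse videos. The package corrects the global
    rigid motion (translation and rotation) of the structure by template
    matching on raw and polar-unwrapped frames with iterative refinement,
    detects FUCCI-labelled cells in the registered frames, calls cell-cycle
    phase from the red/green hue, links detections into trajectories, and
    derives migration analytics: path length, net displacement, convex hull
    area (CHA), CHA-ranked cohort summaries with G2/M:G1 ratios, infiltration
    percentage, and two-group comparisons. A synthetic-scene generator renders
    ground-truthed textured discs with scripted rigid motion and scripted cell
    tracks for validation, and a butterfly-plot projection maps per-cell
    signature scores to lineage-state coordinates with a cell-cycle score.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
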