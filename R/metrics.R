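## Per-cell and cohort migration analytics.

trajPoints <- function(traj) {
    if (is.data.frame(traj)) cbind(traj$x, traj$y) else as.matrix(traj)
}

#' Cumulative path length of a trajectory
#'
#' Sum of Euclidean inter-detection distances, converted to microns.
#'
#' @param traj data.frame with x, y (px, temporal order) or a 2-column
#'   matrix.
#' @param pixelSizeUm microns per pixel.
#' @return path length in microns.
#' @export
pathLength <- function(traj, pixelSizeUm = 1) {
    p <- trajPoints(traj)
    if (nrow(p) < 2) metricError("path length needs >= 2 detections")
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)) * pixelSizeUm
}

#' Net displacement of a trajectory
#'
#' Euclidean distance from the first to the last detection, in microns.
#'
#' @inheritParams pathLength
#' @return net displacement in microns.
#' @export
netDisplacement <- function(traj, pixelSizeUm = 1) {
    p <- trajPoints(traj)
    if (nrow(p) < 2) metricError("net displacement needs >= 2 detections")
    n <- nrow(p)
    sqrt((p[n, 1] - p[1, 1])^2 + (p[n, 2] - p[1, 2])^2) * pixelSizeUm
}

#' Convex hull area (CHA) of a trajectory
#'
#' Area of the 2D convex hull of all trajectory points (shoelace formula on
#' the hull vertices), in square microns: the two-dimensional territory
#' spanned by the entire trajectory, a surrogate measure of migration.
#' Fewer than 3 points, or collinear points, give 0.
#'
#' @inheritParams pathLength
#' @return hull area in um^2.
#' @export
convexHullArea <- function(traj, pixelSizeUm = 1) {
    p <- unique(trajPoints(traj))
    if (nrow(p) < 3) return(0)
    hull <- grDevices::chull(p[, 1], p[, 2])
    polygonArea(p[hull, , drop = FALSE]) * pixelSizeUm^2
}

#' Dominant cell-cycle phase of a trajectory
#'
#' Modal phase over the trajectory's detections, ignoring UNKNOWN; ties are
#' broken toward the phase occurring later in the trajectory.
#'
#' @param phases character vector of per-detection phase calls in temporal
#'   order.
#' @return one of "G1", "S", "G2M", "UNKNOWN".
#' @export
dominantPhase <- function(phases) {
    known <- phases[phases != "UNKNOWN"]
    if (!length(known)) return("UNKNOWN")
    counts <- table(known)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) return(top)
    ## tie: the phase whose last occurrence is latest wins
    lastOcc <- vapply(top, function(ph) max(which(phases == ph)), 0)
    top[which.max(lastOcc)]
}

#' Per-cell migration metrics table
#'
#' @param trajectories data.frame from [linkTracks()] (cell_id, t, x, y,
#'   phase).
#' @param pixelSizeUm microns per pixel.
#' @return data.frame: cell_id, n_points, path_length_um,
#'   net_displacement_um, cha_um2, dominant_phase.
#' @export
migrationMetrics <- function(trajectories, pixelSizeUm = 1) {
    ids <- unique(trajectories$cell_id)
    out <- do.call(rbind, lapply(ids, function(id) {
        tr <- trajectories[trajectories$cell_id == id, , drop = FALSE]
        tr <- tr[order(tr$t), , drop = FALSE]
        data.frame(cell_id = id, n_points = nrow(tr),
                   path_length_um = pathLength(tr, pixelSizeUm),
                   net_displacement_um = netDisplacement(tr, pixelSizeUm),
                   cha_um2 = convexHullArea(tr, pixelSizeUm),
                   dominant_phase = dominantPhase(tr$phase))
    }))
    if (is.null(out)) out <- data.frame(
        cell_id = integer(0), n_points = integer(0), path_length_um = numeric(0),
        net_displacement_um = numeric(0), cha_um2 = numeric(0),
        dominant_phase = character(0))
    out
}

phaseCounts <- function(phases) {
    c(G1 = sum(phases == "G1"), S = sum(phases == "S"),
      G2M = sum(phases == "G2M"), UNKNOWN = sum(phases == "UNKNOWN"))
}

#' CHA ranking and G2/M:G1 ratios for a cohort
#'
#' Ranks cells by CHA (descending; ties broken by cell_id for determinism),
#' takes the top-N and bottom-N sets, and reports per-set phase
#' compositions and the G2/M-to-G1 ratio (NA when the set has no G1 cell).
#' UNKNOWN-phase cells stay in the ranking but are excluded from ratios.
#'
#' @param metrics data.frame from [migrationMetrics()].
#' @param N set size (default 50, the T-50/B-50 convention).
#' @return list: `N`, `overlapping` (TRUE when the cohort has fewer than 2N
#'   cells), `top_ids`, `bottom_ids`, `top_counts`, `bottom_counts`,
#'   `top_ratio`, `bottom_ratio`.
#' @export
rankAndRatio <- function(metrics, N = 50) {
    if (!nrow(metrics)) metricError("cohort is empty")
    ord <- order(-metrics$cha_um2, metrics$cell_id)
    n <- min(N, nrow(metrics))
    topIdx <- ord[seq_len(n)]
    botIdx <- rev(ord)[seq_len(n)]
    ratio <- function(counts)
        if (counts[["G1"]] == 0) NA_real_ else counts[["G2M"]] / counts[["G1"]]
    topCounts <- phaseCounts(metrics$dominant_phase[topIdx])
    botCounts <- phaseCounts(metrics$dominant_phase[botIdx])
    list(N = n, overlapping = nrow(metrics) < 2 * N,
         top_ids = metrics$cell_id[topIdx], bottom_ids = metrics$cell_id[botIdx],
         top_counts = topCounts, bottom_counts = botCounts,
         top_ratio = ratio(topCounts), bottom_ratio = ratio(botCounts))
}

#' Infiltration percentage
#'
#' Percentage of the organoid area covered by thresholded tumor
#' fluorescence: `100 * (fluorescent pixels inside the mask) / (mask
#' pixels)`.
#'
#' @param organoidMask an [AssembloidMask-class] or logical matrix.
#' @param tumorChannel fluorescence matrix, same shape.
#' @param threshold intensity threshold gating the tumor signal.
#' @return percentage in `[0, 100]`.
#' @export
infiltrationPercentage <- function(organoidMask, tumorChannel, threshold) {
    m <- if (is(organoidMask, "AssembloidMask")) organoidMask@mask else organoidMask
    if (!identical(dim(m), dim(tumorChannel)))
        inputError("mask and tumor channel differ in shape")
    total <- sum(m)
    if (total == 0) metricError("empty organoid mask")
    100 * sum(tumorChannel > threshold & m) / total
}

#' Two-group comparison (Student's t-test)
#'
#' Classical equal-variance two-sample t-test, two-tailed. Degenerate
#' zero-variance input is handled by convention: equal means give p = 1
#' (t = 0), unequal means p = 0 (infinite t).
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return list: mean_a, mean_b, t_statistic, p_value.
#' @export
compareGroups <- function(a, b) {
    if (length(a) < 2 || length(b) < 2)
        inputError("each group needs n >= 2")
    if (sd(a) == 0 && sd(b) == 0) {
        if (mean(a) == mean(b))
            return(list(mean_a = mean(a), mean_b = mean(b),
                        t_statistic = 0, p_value = 1))
        return(list(mean_a = mean(a), mean_b = mean(b),
                    t_statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0))
    }
    tt <- t.test(a, b, var.equal = TRUE)
    list(mean_a = mean(a), mean_b = mean(b),
         t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
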