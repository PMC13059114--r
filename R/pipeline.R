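## End-to-end orchestration: config handling, the full
## register -> detect/link -> metrics pipeline, CSV/plot output.

#' Default run configuration
#'
#' Every pipeline parameter with its default; a run's effective (merged)
#' config is written next to its outputs as YAML.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() list(
    input = NULL,                      # TIFF path / frame dir; NULL = simulate
    output_dir = "spherotrack_out",
    seed = 1L,
    simulate = list(),                 # scene parameter overrides
    calibration = list(pixel_size_um = 1.3, frame_interval_min = 60),
    channels = list(brightfield = 1L, red = 2L, green = 3L),
    registration = list(),             # overrides of registrationDefaults()
    detection = list(min_intensity = 0.1, sigma_range = c(2, 3, 4),
                     min_area_px = 4),
    phase = list(t_g1s = 25, t_sg2m = 45, intensity_floor = 0.05),
    linking = list(max_link_dist_px = 30, max_gap = 2),
    metrics = list(rank_n = 50, pool_s_with_g2m = FALSE),
    plots = FALSE,
    verbosity = 1L
)

mergeConfig <- function(config) {
    def <- defaultConfig()
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    unknown <- setdiff(names(config), names(def))
    if (length(unknown)) configError("unknown config key '%s'", unknown[1])
    for (nm in names(config)) {
        if (is.list(def[[nm]]) && is.list(config[[nm]])) {
            sub <- config[[nm]]
            if (!(nm %in% c("simulate", "registration"))) {
                bad <- setdiff(names(sub), names(def[[nm]]))
                if (length(bad)) configError("unknown config key '%s.%s'", nm, bad[1])
            }
            def[[nm]][names(sub)] <- sub
        } else def[[nm]] <- config[[nm]]
    }
    def
}

logMsg <- function(cfg, fmt, ...) {
    if (cfg$verbosity > 0)
        message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                        sprintf(fmt, ...)))
}

#' Run the full tracking pipeline
#'
#' Loads (or simulates) a stack, registers it, detects and links
#' FUCCI-labelled cells, computes migration metrics and cohort summaries,
#' and writes all CSV tables, the effective config, and optional plots to
#' the output directory.
#'
#' @param config a nested list (see [defaultConfig()]) or a YAML file path.
#' @return list with stack, registration, trajectories, metrics, summary,
#'   and (for simulated input) the scene; invisibly.
#' @export
runPipeline <- function(config = list()) {
    cfg <- mergeConfig(config)
    ph <- cfg$phase
    if (!(ph$t_g1s > 0 && ph$t_g1s < ph$t_sg2m && ph$t_sg2m < 60))
        configError("phase thresholds must satisfy 0 < t_g1s < t_sg2m < 60")
    mergeParams(cfg$registration)   # validate before any computation

    scene <- NULL
    if (is.null(cfg$input)) {
        logMsg(cfg, "simulating scene (seed %d)", cfg$seed)
        scene <- generateScene(cfg$simulate, seed = cfg$seed)
        stack <- renderStack(scene, cfg$calibration$pixel_size_um,
                             cfg$calibration$frame_interval_min)
    } else {
        logMsg(cfg, "loading %s", cfg$input)
        stack <- loadStack(cfg$input, unlist(cfg$channels),
                           cfg$calibration$pixel_size_um,
                           cfg$calibration$frame_interval_min)
    }

    logMsg(cfg, "registering %d frames", nFrames(stack))
    reg <- registerStack(stack, cfg$registration)
    registered <- applyRegistration(stack, reg)

    logMsg(cfg, "detecting and linking cells")
    det <- detectStack(registered,
                       tG1S = ph$t_g1s, tSG2M = ph$t_sg2m,
                       intensityFloor = ph$intensity_floor,
                       minIntensity = cfg$detection$min_intensity,
                       sigmaRange = cfg$detection$sigma_range,
                       minAreaPx = cfg$detection$min_area_px)
    traj <- linkTracks(det, cfg$linking$max_link_dist_px, cfg$linking$max_gap)
    if (nrow(traj)) {
        raw <- do.call(rbind, lapply(split(seq_len(nrow(traj)), traj$t),
            function(ii) {
                t1 <- traj$t[ii[1]] + 1L
                cbind(ii, registeredToRaw(cbind(traj$x[ii], traj$y[ii]), reg, t1))
            }))
        traj$raw_x <- NA_real_; traj$raw_y <- NA_real_
        traj$raw_x[raw[, 1]] <- raw[, 2]
        traj$raw_y[raw[, 1]] <- raw[, 3]
    }

    logMsg(cfg, "computing metrics over %d trajectories",
           length(unique(traj$cell_id)))
    px <- cfg$calibration$pixel_size_um
    met <- migrationMetrics(traj, px)
    metRanked <- met
    if (isTRUE(cfg$metrics$pool_s_with_g2m))
        metRanked$dominant_phase[metRanked$dominant_phase == "S"] <- "G2M"
    summary <- data.frame(n_cells = nrow(met))
    rk <- NULL
    if (nrow(met)) {
        rk <- rankAndRatio(metRanked, cfg$metrics$rank_n)
        g1 <- met$path_length_um[metRanked$dominant_phase == "G1"]
        g2 <- met$path_length_um[metRanked$dominant_phase == "G2M"]
        cmp <- if (length(g1) >= 2 && length(g2) >= 2) compareGroups(g2, g1)
               else list(mean_a = NA, mean_b = NA, t_statistic = NA, p_value = NA)
        summary <- data.frame(
            n_cells = nrow(met), rank_n = rk$N, overlapping = rk$overlapping,
            top_g1 = rk$top_counts[["G1"]], top_s = rk$top_counts[["S"]],
            top_g2m = rk$top_counts[["G2M"]],
            bottom_g1 = rk$bottom_counts[["G1"]],
            bottom_s = rk$bottom_counts[["S"]],
            bottom_g2m = rk$bottom_counts[["G2M"]],
            top_g2m_to_g1 = rk$top_ratio, bottom_g2m_to_g1 = rk$bottom_ratio,
            mean_path_g2m_um = cmp$mean_a, mean_path_g1_um = cmp$mean_b,
            t_statistic = cmp$t_statistic, p_value = cmp$p_value)
    }

    out <- cfg$output_dir
    writeTables(list(transforms = transformTable(reg), detections = det,
                     trajectories = traj, metrics = met, summary = summary),
                out)
    yaml::write_yaml(cfg, file.path(out, "config.yaml"))
    if (isTRUE(cfg$plots)) {
        plotTrajectoryMap(traj, file.path(out, "trajectory_map.png"),
                          dim = frameDim(stack))
        plotVectorMap(traj, met, file.path(out, "vector_map.png"),
                      dim = frameDim(stack))
        plotHueTime(traj, file.path(out, "hue_time.png"))
    }
    logMsg(cfg, "wrote results to %s", out)
    invisible(list(stack = stack, scene = scene, registration = reg,
                   registered = registered, detections = det,
                   trajectories = traj, metrics = met, summary = summary,
                   ranking = rk, config = cfg))
}

phaseColor <- function(phase)
    c(G1 = "#d62728", S = "#e6c700", G2M = "#2ca02c", UNKNOWN = "grey60")[phase]

#' Trajectory map colored by cell-cycle phase
#'
#' @param trajectories data.frame from [linkTracks()].
#' @param path output PNG path.
#' @param dim image (height, width) for axis limits.
#' @return `path`, invisibly.
#' @export
plotTrajectoryMap <- function(trajectories, path, dim = c(512, 512)) {
    grDevices::png(path, 800, 800)
    on.exit(grDevices::dev.off())
    plot(NA, xlim = c(0, dim[2]), ylim = c(dim[1], 0), asp = 1,
         xlab = "x (px)", ylab = "y (px)", main = "Cell trajectories by phase")
    for (id in unique(trajectories$cell_id)) {
        tr <- trajectories[trajectories$cell_id == id, ]
        tr <- tr[order(tr$t), ]
        graphics::segments(head(tr$x, -1), head(tr$y, -1), tail(tr$x, -1),
                           tail(tr$y, -1), col = phaseColor(head(tr$phase, -1)),
                           lwd = 2)
    }
    graphics::legend("topright", legend = c("G1", "S", "G2/M"), lwd = 2,
                     col = phaseColor(c("G1", "S", "G2M")))
    invisible(path)
}

#' Displacement-vector map
#'
#' One arrow per cell from first to last registered position, colored by
#' dominant phase.
#'
#' @param trajectories data.frame from [linkTracks()].
#' @param metrics data.frame from [migrationMetrics()].
#' @param path output PNG path.
#' @param dim image (height, width).
#' @return `path`, invisibly.
#' @export
plotVectorMap <- function(trajectories, metrics, path, dim = c(512, 512)) {
    grDevices::png(path, 800, 800)
    on.exit(grDevices::dev.off())
    plot(NA, xlim = c(0, dim[2]), ylim = c(dim[1], 0), asp = 1,
         xlab = "x (px)", ylab = "y (px)", main = "Displacement vectors")
    for (i in seq_len(nrow(metrics))) {
        id <- metrics$cell_id[i]
        tr <- trajectories[trajectories$cell_id == id, ]
        tr <- tr[order(tr$t), ]
        n <- nrow(tr)
        graphics::arrows(tr$x[1], tr$y[1], tr$x[n], tr$y[n], length = 0.08,
                         col = phaseColor(metrics$dominant_phase[i]), lwd = 2)
    }
    invisible(path)
}

#' Hue-versus-time curves
#'
#' @param trajectories data.frame from [linkTracks()].
#' @param path output PNG path.
#' @param nCells number of longest trajectories to draw.
#' @return `path`, invisibly.
#' @export
plotHueTime <- function(trajectories, path, nCells = 3) {
    grDevices::png(path, 900, 500)
    on.exit(grDevices::dev.off())
    lens <- sort(table(trajectories$cell_id), decreasing = TRUE)
    ids <- as.integer(names(head(lens, nCells)))
    plot(NA, xlim = range(trajectories$t), ylim = c(0, 65),
         xlab = "frame", ylab = "hue (half-angle deg)",
         main = "Per-cell hue over time")
    graphics::abline(h = c(25, 45), lty = 3, col = "grey50")
    for (k in seq_along(ids)) {
        tr <- trajectories[trajectories$cell_id == ids[k], ]
        tr <- tr[order(tr$t), ]
        graphics::lines(tr$t, tr$hue, col = k + 1, lwd = 2)
        graphics::points(tr$t, tr$hue, col = k + 1, pch = 16, cex = 0.6)
    }
    invisible(path)
}
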