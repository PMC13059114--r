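## Ground-truthed synthetic FUCCI assembloid videos: a textured disc under
## scripted rigid motion with embedded fluorescent cells whose positions and
## cycle phases are scripted. The renderer is the test bed for the whole
## pipeline.

sceneDefaults <- function() list(
    width = 512L, height = 512L, n_frames = 30L,
    disc_radius_px = 150, growth_rate = 0,
    t_max = 6, r_max = 4, max_drift = 30,
    n_cells = 40L, cell_sigma = 2.5, cell_peak = 1,
    cell_mode = "brownian",          # "brownian", "directed", "phase_coupled"
    cell_speed = 2.5,                # mean step length, px/frame
    speed_g2m_factor = 2,            # phase_coupled: G2M speed multiplier
    phase_durations = c(G1 = 10, S = 5, G2M = 8),
    noise_sigma = 0.02
)

## phase of a cell at frame f (0-based) given its cycle offset
phaseAt <- function(offset, f, durations) {
    cyc <- sum(durations)
    pos <- (offset + f) %% cyc
    if (pos < durations[["G1"]]) "G1"
    else if (pos < durations[["G1"]] + durations[["S"]]) "S"
    else "G2M"
}

#' Generate a ground-truthed synthetic scene
#'
#' Draws a reproducible motion script (per-pair translation and rotation as
#' a bounded random walk), cell trajectories inside the disc (Brownian,
#' directed-outward, or phase-coupled-speed modes), and per-cell cycle-phase
#' schedules. The same `(params, seed)` always yields an identical scene.
#'
#' @param params named list overriding `sceneDefaults()`: frame size, disc
#'   radius, per-pair motion bounds `t_max` (px) and `r_max` (deg), cell
#'   count/behaviour, noise level.
#' @param seed integer seed.
#' @return A [SyntheticScene-class].
#' @export
generateScene <- function(params = list(), seed = 1) {
    def <- sceneDefaults()
    unknown <- setdiff(names(params), names(def))
    if (length(unknown)) configError("unknown scene parameter '%s'", unknown[1])
    def[names(params)] <- params
    p <- def
    if (p$disc_radius_px + p$max_drift + p$t_max >= min(p$width, p$height) / 2)
        configError("infeasible geometry: disc radius %g + drift %g exceeds half frame",
                    p$disc_radius_px, p$max_drift)
    set.seed(seed)

    ## motion script: bounded random walk, reflecting at the drift bound
    nP <- p$n_frames - 1L
    dx <- runif(nP, -p$t_max, p$t_max)
    dy <- runif(nP, -p$t_max, p$t_max)
    dth <- runif(nP, -p$r_max, p$r_max)
    cum <- c(0, 0)
    for (k in seq_len(nP)) {
        if (abs(cum[1] + dx[k]) > p$max_drift) dx[k] <- -dx[k]
        if (abs(cum[2] + dy[k]) > p$max_drift) dy[k] <- -dy[k]
        cum <- cum + c(dx[k], dy[k])
    }
    script <- data.frame(pair = seq_len(nP), dx = dx, dy = dy, dtheta = dth)
    if (nP > 0) {
        cumul <- data.frame(t = 0:(p$n_frames - 1L),
                            dx = c(0, cumsum(0 * dx)), dy = 0, theta = 0)
        center <- c(p$width / 2, p$height / 2)
        M <- RigidTransform(center = center)
        for (k in seq_len(nP)) {
            M <- composeTransforms(RigidTransform(dx[k], dy[k], dth[k], center), M)
            cumul$dx[k + 1] <- M@dx; cumul$dy[k + 1] <- M@dy
            cumul$theta[k + 1] <- M@theta
        }
    } else {
        cumul <- data.frame(t = 0L, dx = 0, dy = 0, theta = 0)
    }

    ## texture: band-pass filtered white noise (feature scale ~8-32 px)
    wn <- matrix(rnorm(p$width * p$height), p$height, p$width)
    bp <- as.matrix(EBImage::gblur(EBImage::Image(wn), sigma = 4)) -
          as.matrix(EBImage::gblur(EBImage::Image(wn), sigma = 16))
    bp <- (bp - mean(bp)) / sd(bp)
    texture <- matrix(pmin(pmax(0.55 + 0.18 * as.numeric(bp), 0.15), 0.95),
                      p$height, p$width)

    ## cells: start positions inside the disc, scripted random walks
    mode <- match.arg(p$cell_mode, c("brownian", "directed", "phase_coupled"))
    Rin <- 0.85 * p$disc_radius_px
    offsets <- sample.int(sum(p$phase_durations), p$n_cells, replace = TRUE) - 1L
    cells <- vector("list", p$n_cells)
    for (i in seq_len(p$n_cells)) {
        rr <- Rin * sqrt(runif(1)); aa <- runif(1, 0, 2 * pi)
        pos <- c(rr * cos(aa), rr * sin(aa))     # disc coordinates
        if (mode == "phase_coupled") {
            ph0 <- if (i %% 2 == 1) "G1" else "G2M"
        }
        xs <- ys <- numeric(p$n_frames)
        phs <- character(p$n_frames)
        outwardDir <- atan2(pos[2], pos[1])
        for (f in 0:(p$n_frames - 1L)) {
            phs[f + 1] <- if (mode == "phase_coupled") ph0
                          else phaseAt(offsets[i], f, p$phase_durations)
            xs[f + 1] <- pos[1]; ys[f + 1] <- pos[2]
            if (f == p$n_frames - 1L) break
            spd <- p$cell_speed
            if (mode == "phase_coupled" && phs[f + 1] == "G2M")
                spd <- spd * p$speed_g2m_factor
            len <- spd * runif(1, 0.5, 1.5)
            ang <- if (mode == "directed")
                outwardDir + rnorm(1, 0, 0.35) else runif(1, 0, 2 * pi)
            step <- len * c(cos(ang), sin(ang))
            cand <- pos + step
            if (sqrt(sum(cand^2)) > Rin) cand <- pos - step  # reflect inward
            pos <- cand
        }
        cells[[i]] <- data.frame(cell_id = i, t = 0:(p$n_frames - 1L),
                                 x_disc = xs, y_disc = ys, phase = phs)
    }
    cells <- if (p$n_cells > 0) do.call(rbind, cells) else
        data.frame(cell_id = integer(0), t = integer(0), x_disc = numeric(0),
                   y_disc = numeric(0), phase = character(0))
    center <- c(p$width / 2, p$height / 2)
    cells$x_ref <- cells$x_disc + center[1]
    cells$y_ref <- cells$y_disc + center[2]
    ## raw positions: apply the cumulative motion of each frame
    th <- cumul$theta[cells$t + 1] * pi / 180
    px <- cells$x_ref - center[1]; py <- cells$y_ref - center[2]
    cells$x_raw <- cos(th) * px + sin(th) * py + center[1] + cumul$dx[cells$t + 1]
    cells$y_raw <- -sin(th) * px + cos(th) * py + center[2] + cumul$dy[cells$t + 1]

    new("SyntheticScene", seed = as.integer(seed), params = p,
        motionScript = script, cumulativeMotion = cumul,
        cells = cells[, c("cell_id", "t", "x_ref", "y_ref", "x_raw", "y_raw",
                          "phase")],
        texture = texture)
}

softDisc <- function(h, w, center, radius, edge = 2) {
    xs <- matrix(0:(w - 1), h, w, byrow = TRUE) - center[1]
    ys <- matrix(0:(h - 1), h, w) - center[2]
    r <- sqrt(xs^2 + ys^2)
    pmin(pmax((radius + edge - r) / (2 * edge), 0), 1)
}

phaseAmplitudes <- function(phase, peak) {
    switch(phase,
           G1 = c(red = peak, green = 0),
           S = c(red = 0.7 * peak, green = 0.7 * peak),
           G2M = c(red = 0, green = peak),
           c(red = 0, green = 0))
}

#' Render a synthetic scene into a FrameStack
#'
#' Per frame: the textured disc is transformed by the cumulative scripted
#' motion (bilinear), cells are rendered as 2D Gaussian spots into the red
#' and green channels with phase-coded intensities (G1 red, S red+green,
#' G2/M green), and additive Gaussian noise is applied. The brightfield
#' channel carries the disc texture. Rendering is deterministic for a given
#' scene.
#'
#' @param scene a [SyntheticScene-class].
#' @param pixelSizeUm,frameIntervalMin calibration stamped on the stack.
#' @return A [FrameStack-class] with channels brightfield=1, red=2, green=3.
#' @export
renderStack <- function(scene, pixelSizeUm = 1.3, frameIntervalMin = 60) {
    p <- scene@params
    h <- p$height; w <- p$width
    center <- c(w / 2, h / 2)
    arr <- array(0, c(h, w, 3, p$n_frames))
    set.seed(scene@seed + 1000003L)   # noise stream, independent of the script
    for (t in seq_len(p$n_frames)) {
        Rt <- p$disc_radius_px * (1 + p$growth_rate * (t - 1))
        bf0 <- scene@texture * softDisc(h, w, center, Rt)
        cm <- scene@cumulativeMotion[t, ]
        bf <- applyTransform(bf0, RigidTransform(cm$dx, cm$dy, cm$theta, center))
        rows <- scene@cells[scene@cells$t == t - 1L, , drop = FALSE]
        if (nrow(rows)) {
            amps <- t(vapply(rows$phase, phaseAmplitudes, c(red = 0, green = 0),
                             peak = p$cell_peak))
            red <- render_spots_cpp(h, w, rows$x_raw, rows$y_raw, amps[, "red"],
                                    p$cell_sigma)
            green <- render_spots_cpp(h, w, rows$x_raw, rows$y_raw,
                                      amps[, "green"], p$cell_sigma)
        } else {
            red <- green <- matrix(0, h, w)
        }
        if (p$noise_sigma > 0) {
            bf <- bf + matrix(rnorm(h * w, 0, p$noise_sigma), h, w)
            red <- red + matrix(rnorm(h * w, 0, p$noise_sigma), h, w)
            green <- green + matrix(rnorm(h * w, 0, p$noise_sigma), h, w)
        }
        arr[, , 1, t] <- pmax(bf, 0)
        arr[, , 2, t] <- pmax(red, 0)
        arr[, , 3, t] <- pmax(green, 0)
    }
    FrameStack(arr, c(brightfield = 1, red = 2, green = 3),
               pixelSizeUm, frameIntervalMin)
}

#' Compare estimated transforms with scripted truth
#'
#' @param result a [RegistrationResult-class].
#' @param scene the [SyntheticScene-class] the registered stack was rendered
#'   from.
#' @return list: `perPair` data.frame of signed errors (estimate - truth)
#'   per pair, `median_abs_dx`, `median_abs_dy`, `median_abs_dtheta`, and
#'   `cum_theta_err` (absolute cumulative rotation error per frame).
#' @export
evaluateRegistration <- function(result, scene) {
    est <- result@pairTransforms
    tr <- scene@motionScript
    if (length(est) != nrow(tr))
        inputError("result has %d pairs but scene scripts %d", length(est), nrow(tr))
    perPair <- data.frame(
        pair = tr$pair,
        dx_err = vapply(est, function(x) x@dx, 0) - tr$dx,
        dy_err = vapply(est, function(x) x@dy, 0) - tr$dy,
        dtheta_err = wrapAngle(vapply(est, function(x) x@theta, 0) - tr$dtheta))
    cumErr <- abs(wrapAngle(
        vapply(result@cumulative, function(x) x@theta, 0) -
            scene@cumulativeMotion$theta))
    list(perPair = perPair,
         median_abs_dx = median(abs(perPair$dx_err)),
         median_abs_dy = median(abs(perPair$dy_err)),
         median_abs_dtheta = median(abs(perPair$dtheta_err)),
         cum_theta_err = cumErr)
}

#' Score tracked trajectories against scripted truth
#'
#' Per frame, detections are greedily matched to truth positions within
#' `matchDistPx`. Recall is matched truth points over all truth points;
#' link accuracy is the fraction of consecutive matched truth steps whose
#' two detections belong to the same trajectory; phase accuracy is computed
#' over matched detections.
#'
#' @param trajectories data.frame from [linkTracks()] in registered
#'   coordinates.
#' @param scene the source [SyntheticScene-class].
#' @param matchDistPx match radius in px (default 3).
#' @param offset (dx, dy) added to truth positions (the frame-0 recentering
#'   shift of the registration, when nonzero).
#' @return list: recall, precision, link_accuracy, phase_accuracy,
#'   n_truth, n_matched.
#' @export
evaluateTracking <- function(trajectories, scene, matchDistPx = 3,
                             offset = c(0, 0)) {
    truth <- scene@cells
    truth$x <- truth$x_ref + offset[1]
    truth$y <- truth$y_ref + offset[2]
    nTruth <- nrow(truth)
    if (!nrow(trajectories))
        return(list(recall = 0, precision = NA_real_, link_accuracy = NA_real_,
                    phase_accuracy = NA_real_, n_truth = nTruth, n_matched = 0L))
    ## matched[i] = trajectory row index matched to truth row i
    matched <- rep(NA_integer_, nTruth)
    for (tt in unique(truth$t)) {
        ti <- which(truth$t == tt)
        di <- which(trajectories$t == tt)
        if (!length(di)) next
        dm <- outer(truth$x[ti], trajectories$x[di], "-")^2 +
              outer(truth$y[ti], trajectories$y[di], "-")^2
        cand <- which(dm <= matchDistPx^2, arr.ind = TRUE)
        if (!nrow(cand)) next
        cand <- cand[order(dm[cand]), , drop = FALSE]
        usedT <- logical(length(ti)); usedD <- logical(length(di))
        for (r in seq_len(nrow(cand))) {
            a <- cand[r, 1]; b <- cand[r, 2]
            if (usedT[a] || usedD[b]) next
            usedT[a] <- TRUE; usedD[b] <- TRUE
            matched[ti[a]] <- di[b]
        }
    }
    nMatched <- sum(!is.na(matched))
    recall <- nMatched / nTruth
    precision <- nMatched / nrow(trajectories)
    phaseAcc <- if (nMatched)
        mean(truth$phase[!is.na(matched)] ==
             trajectories$phase[matched[!is.na(matched)]]) else NA_real_
    ## link accuracy over consecutive matched truth steps
    ok <- 0L; tot <- 0L
    for (id in unique(truth$cell_id)) {
        ti <- which(truth$cell_id == id)
        ti <- ti[order(truth$t[ti])]
        for (k in seq_len(length(ti) - 1)) {
            a <- matched[ti[k]]; b <- matched[ti[k + 1]]
            if (truth$t[ti[k + 1]] - truth$t[ti[k]] != 1) next
            if (is.na(a) || is.na(b)) next
            tot <- tot + 1L
            if (trajectories$cell_id[a] == trajectories$cell_id[b]) ok <- ok + 1L
        }
    }
    list(recall = recall, precision = precision,
         link_accuracy = if (tot) ok / tot else NA_real_,
         phase_accuracy = phaseAcc, n_truth = nTruth, n_matched = nMatched)
}
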