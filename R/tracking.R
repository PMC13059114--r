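## FUCCI cell detection, hue-based phase calling, and trajectory linking.

#' Hue of a red/green intensity pair (half-angle scale)
#'
#' Hue of the colour (R = red, G = green, B = 0) under the standard HSV hue
#' formula, divided by 2, so the occupied red-to-green range is [0, 60]:
#' pure red -> 0, equal red/green (yellow) -> 30, pure green -> 60.
#'
#' @param red,green non-negative channel intensities (vectorised).
#' @return hue in degrees on the half-angle scale `[0, 180)`.
#' @export
hueOf <- function(red, green) {
    if (any(red < 0 | green < 0)) inputError("intensities must be non-negative")
    if (any(red + green <= 0))
        inputError("undefined hue: both channels are zero")
    ## full-angle hue of (R, G, B = 0); the minimum channel is B = 0, so
    ## max = R  ->  H = 60 G / R   (red..yellow, 0..60)
    ## max = G  ->  H = 120 - 60 R / G  (yellow..green, 60..120)
    h <- ifelse(red >= green, 60 * green / red, 120 - 60 * red / green)
    h / 2
}

#' Classify cell-cycle phase from hue
#'
#' G1 (red) below `tG1S`, S (yellow band) between the cuts, G2/M (green) at
#' or above `tSG2M`; detections with both channels under the intensity floor
#' are UNKNOWN.
#'
#' @param hue half-angle hue (degrees).
#' @param red,green channel intensities.
#' @param tG1S,tSG2M hue cut points, `0 < tG1S < tSG2M < 60`.
#' @param intensityFloor minimum channel intensity for a confident call.
#' @return character vector in `{"G1", "S", "G2M", "UNKNOWN"}`.
#' @export
classifyPhase <- function(hue, red, green, tG1S = 25, tSG2M = 45,
                          intensityFloor = 0.05) {
    if (!(tG1S > 0 && tG1S < tSG2M && tSG2M < 60))
        configError("phase thresholds must satisfy 0 < tG1S < tSG2M < 60")
    out <- ifelse(hue < tG1S, "G1", ifelse(hue < tSG2M, "S", "G2M"))
    out[red < intensityFloor & green < intensityFloor] <- "UNKNOWN"
    out
}

## local maxima of a matrix (8-neighbourhood, strictly greater than border)
localMaxima <- function(m) {
    h <- nrow(m); w <- ncol(m)
    pad <- matrix(-Inf, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- m
    ok <- matrix(TRUE, h, w)
    for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        ok <- ok & (m >= pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)])
    }
    ok
}

## scale-normalised (negated) Laplacian-of-Gaussian kernel: the response to
## a unit-amplitude Gaussian spot of width sigma peaks at the matching scale
## with the same magnitude at every scale
logKernel <- function(sigma) {
    r <- ceiling(4 * sigma)
    xs <- -r:r
    xx <- matrix(xs, 2 * r + 1, 2 * r + 1)
    yy <- t(xx)
    g <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
    g <- g / sum(g)
    lg <- (xx^2 + yy^2 - 2 * sigma^2) / sigma^4 * g
    lg <- lg - mean(lg)           # zero DC response
    -sigma^2 * lg
}

#' Detect FUCCI-labelled cells in a registered frame
#'
#' Detections are local maxima of a multi-scale, scale-normalised
#' Laplacian-of-Gaussian response on the red + green sum image: maxima are
#' found per scale and deduplicated across scales (highest response wins
#' within a minimum separation), which keeps nearby spots separable. Per
#' detection, mean red/green intensities are averaged over a disc of the
#' detected scale and the hue is computed with [hueOf()].
#'
#' @param red,green channel matrices of one registered frame.
#' @param minIntensity minimum summed mean intensity for a detection.
#' @param sigmaRange candidate spot scales (Gaussian sigmas, px).
#' @param minAreaPx minimum footprint in px^2.
#' @param respFloor minimum scale-normalised response (rejects noise maxima;
#'   the response to a unit-amplitude matched spot is about 0.25).
#' @return data.frame with columns x, y (0-based subpixel), red_i, green_i,
#'   hue, area_px, sigma. Empty frames give a zero-row frame.
#' @export
detectCells <- function(red, green, minIntensity = 0.1,
                        sigmaRange = c(2, 3, 4), minAreaPx = 4,
                        respFloor = 0.05) {
    s <- red + green
    h <- nrow(s); w <- ncol(s)
    empty <- data.frame(x = numeric(0), y = numeric(0), red_i = numeric(0),
                        green_i = numeric(0), hue = numeric(0),
                        area_px = numeric(0), sigma = numeric(0))
    cand <- NULL
    for (i in seq_along(sigmaRange)) {
        resp <- as.matrix(EBImage::filter2(EBImage::Image(s),
                                           logKernel(sigmaRange[i])))
        idx <- which(localMaxima(resp) & resp > respFloor, arr.ind = TRUE)
        if (!nrow(idx)) next
        cand <- rbind(cand, data.frame(
            iy = idx[, 1], ix = idx[, 2], sigma = sigmaRange[i],
            resp = resp[idx],
            offy = vapply(seq_len(nrow(idx)), function(r) {
                iy <- idx[r, 1]; ix <- idx[r, 2]
                if (iy > 1 && iy < h)
                    quadPeakOffset(resp[iy - 1, ix], resp[iy, ix], resp[iy + 1, ix])
                else 0
            }, 0),
            offx = vapply(seq_len(nrow(idx)), function(r) {
                iy <- idx[r, 1]; ix <- idx[r, 2]
                if (ix > 1 && ix < w)
                    quadPeakOffset(resp[iy, ix - 1], resp[iy, ix], resp[iy, ix + 1])
                else 0
            }, 0)))
    }
    if (is.null(cand) || !nrow(cand)) return(empty)
    ## cross-scale dedup: strongest response wins within 2 px
    cand <- cand[order(-cand$resp), , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (r in seq_len(nrow(cand))) {
        if (!keep[r]) next
        later <- which(keep & seq_len(nrow(cand)) > r)
        if (!length(later)) break
        d2 <- (cand$ix[later] - cand$ix[r])^2 + (cand$iy[later] - cand$iy[r])^2
        keep[later[d2 < 4]] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
    out <- empty
    for (r in seq_len(nrow(cand))) {
        iy <- cand$iy[r]; ix <- cand$ix[r]; sg <- cand$sigma[r]
        rad <- max(1, round(sg))
        ys <- max(1, iy - rad):min(h, iy + rad)
        xs <- max(1, ix - rad):min(w, ix + rad)
        dy2 <- outer((ys - iy)^2, (xs - ix)^2, "+")
        inDisc <- dy2 <= rad^2
        area <- sum(inDisc)
        if (area < minAreaPx) next
        ri <- mean(red[ys, xs][inDisc])
        gi <- mean(green[ys, xs][inDisc])
        if (ri + gi < minIntensity) next
        out[nrow(out) + 1, ] <- list(ix - 1 + cand$offx[r], iy - 1 + cand$offy[r],
                                     ri, gi, hueOf(max(ri, 0), max(gi, 0)),
                                     area, sg)
    }
    out
}

#' Detect cells across a registered stack
#'
#' Runs [detectCells()] on every frame and appends phase calls.
#'
#' @param stack a registered [FrameStack-class].
#' @param tG1S,tSG2M,intensityFloor see [classifyPhase()].
#' @param ... passed to [detectCells()].
#' @return data.frame: t (0-based frame), x, y, red_i, green_i, hue,
#'   area_px, phase.
#' @export
detectStack <- function(stack, tG1S = 25, tSG2M = 45, intensityFloor = 0.05, ...) {
    res <- lapply(seq_len(nFrames(stack)), function(t) {
        d <- detectCells(getChannel(stack, t, "red"),
                         getChannel(stack, t, "green"), ...)
        if (nrow(d)) d$t <- t - 1L
        d
    })
    res <- res[vapply(res, nrow, 0L) > 0]
    if (!length(res))
        return(data.frame(t = integer(0), x = numeric(0), y = numeric(0),
                          red_i = numeric(0), green_i = numeric(0),
                          hue = numeric(0), area_px = numeric(0),
                          phase = character(0)))
    det <- do.call(rbind, res)
    det$phase <- classifyPhase(det$hue, det$red_i, det$green_i,
                               tG1S, tSG2M, intensityFloor)
    det[, c("t", "x", "y", "red_i", "green_i", "hue", "area_px", "phase")]
}

#' Link detections into trajectories
#'
#' Greedy globally-nearest-pair linking between active tracks and the
#' detections of each frame: candidate pairs within the distance budget are
#' sorted by distance and matched one-to-one; a track may bridge up to
#' `maxGap` missing frames with the budget scaled by the gap length.
#' Tracks with fewer than 2 detections are discarded.
#'
#' @param detections data.frame from [detectStack()] (needs t, x, y; other
#'   columns are carried along).
#' @param maxLinkDistPx maximum per-frame link distance in px.
#' @param maxGap maximum number of bridged missing frames.
#' @return data.frame of trajectories: cell_id plus all detection columns,
#'   ordered by cell_id then t.
#' @export
linkTracks <- function(detections, maxLinkDistPx = 30, maxGap = 2) {
    if (!nrow(detections))
        return(cbind(cell_id = integer(0), detections))
    det <- detections[order(detections$t), , drop = FALSE]
    det$.row <- seq_len(nrow(det))
    ts <- sort(unique(det$t))
    ## active tracks: list of (id, lastT, lastX, lastY, rows)
    tracks <- list()
    nextId <- 1L
    assign <- integer(nrow(det))
    for (tt in ts) {
        rows <- det[det$t == tt, , drop = FALSE]
        free <- rep(TRUE, nrow(rows))
        if (length(tracks)) {
            lastT <- vapply(tracks, function(x) x$lastT, 0)
            open <- which(tt - lastT >= 1 & tt - lastT <= maxGap + 1)
            if (length(open)) {
                cand <- do.call(rbind, lapply(open, function(ti) {
                    tr <- tracks[[ti]]
                    gap <- tt - tr$lastT
                    d <- sqrt((rows$x - tr$lastX)^2 + (rows$y - tr$lastY)^2)
                    ok <- which(d <= maxLinkDistPx * gap)
                    if (!length(ok)) return(NULL)
                    data.frame(ti = ti, di = ok, dist = d[ok], gap = gap)
                }))
                if (!is.null(cand) && nrow(cand)) {
                    cand <- cand[order(cand$dist), , drop = FALSE]
                    usedT <- logical(length(tracks)); usedD <- logical(nrow(rows))
                    for (i in seq_len(nrow(cand))) {
                        ti <- cand$ti[i]; di <- cand$di[i]
                        if (usedT[ti] || usedD[di]) next
                        usedT[ti] <- TRUE; usedD[di] <- TRUE
                        tracks[[ti]]$lastT <- tt
                        tracks[[ti]]$lastX <- rows$x[di]
                        tracks[[ti]]$lastY <- rows$y[di]
                        tracks[[ti]]$rows <- c(tracks[[ti]]$rows, rows$.row[di])
                        free[di] <- FALSE
                    }
                }
            }
        }
        for (di in which(free)) {
            tracks[[length(tracks) + 1]] <- list(
                id = nextId, lastT = tt, lastX = rows$x[di], lastY = rows$y[di],
                rows = rows$.row[di])
            nextId <- nextId + 1L
        }
    }
    keep <- Filter(function(tr) length(tr$rows) >= 2, tracks)
    if (!length(keep))
        return(cbind(cell_id = integer(0),
                     detections[integer(0), , drop = FALSE]))
    out <- do.call(rbind, lapply(seq_along(keep), function(i) {
        tr <- keep[[i]]
        part <- det[det$.row %in% tr$rows, , drop = FALSE]
        part$.row <- NULL
        cbind(cell_id = i, part)
    }))
    out[order(out$cell_id, out$t), , drop = FALSE]
}
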