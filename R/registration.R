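## Rigid frame-to-frame registration: translation by zero-normalised
## cross-correlation template matching, rotation by normalised squared
## difference matching on polar-unwrapped frames, iteratively refined with
## damped updates.

## ---- transform algebra ----

rotVec <- function(thetaDeg, v) {
    th <- thetaDeg * pi / 180
    c(cos(th) * v[1] + sin(th) * v[2],
      -sin(th) * v[1] + cos(th) * v[2])
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#'
#' Both transforms must share the same pivot. The composed transform has
#' `theta = a@theta + b@theta` and translation `R(a@theta) t_b + t_a`.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
    tb <- rotVec(a@theta, c(b@dx, b@dy))
    RigidTransform(dx = tb[1] + a@dx, dy = tb[2] + a@dy,
                   theta = a@theta + b@theta, center = a@center)
}

#' Invert a rigid transform
#'
#' @param x a [RigidTransform-class].
#' @return The inverse transform (same pivot); composing a transform with
#'   its inverse yields the identity.
#' @export
invertTransform <- function(x) {
    t2 <- rotVec(-x@theta, c(x@dx, x@dy))
    RigidTransform(dx = -t2[1], dy = -t2[2], theta = -x@theta, center = x@center)
}

#' Apply a rigid transform to image data
#'
#' Rotates about the transform's pivot (counterclockwise on a y-down display
#' for positive theta), then translates; bilinear interpolation, zero fill
#' outside the source. An identity transform returns the input unchanged.
#'
#' @param frame matrix or (height, width, channel) array.
#' @param transform a [RigidTransform-class].
#' @return transformed frame, same shape.
#' @export
applyTransform <- function(frame, transform) {
    if (transform@dx == 0 && transform@dy == 0 && transform@theta == 0)
        return(frame)
    cx <- transform@center[1]; cy <- transform@center[2]
    if (length(dim(frame)) == 2 || is.null(dim(frame)))
        return(warp_rigid_cpp(frame, transform@dx, transform@dy,
                              transform@theta, cx, cy))
    d <- dim(frame)
    out <- array(0, d)
    for (c in seq_len(d[3]))
        out[, , c] <- warp_rigid_cpp(matrix(frame[, , c], d[1], d[2]),
                                     transform@dx, transform@dy,
                                     transform@theta, cx, cy)
    out
}

## ---- templates and translation ----

#' Select matching templates inside the assembloid
#'
#' Picks `nTemplates` square patches at the highest-local-variance positions
#' inside the hull mask eroded so every patch lies fully within the
#' structure; selected centers are pairwise at least `templateSizePx` apart.
#'
#' @param gray grayscale matrix (reference frame).
#' @param mask an [AssembloidMask-class] for `gray`.
#' @param nTemplates number of templates (>= 6 by convention).
#' @param templateSizePx patch side length in px.
#' @return list of templates: each has `x`, `y` (0-based top-left), `cx`,
#'   `cy` (0-based center) and `patch` (matrix). A warning is raised when
#'   the best available texture is flat (zero variance).
#' @export
selectTemplates <- function(gray, mask, nTemplates = 6, templateSizePx = 64) {
    h <- nrow(gray); w <- ncol(gray)
    half <- templateSizePx / 2
    dm <- as.matrix(EBImage::distmap(EBImage::Image(mask@mask)))
    ok <- dm >= half * sqrt(2) + 1
    ## also keep full patch inside the image
    okIdx <- which(ok, arr.ind = TRUE)
    if (nrow(okIdx) > 0) {
        cxs <- okIdx[, 2] - 1; cys <- okIdx[, 1] - 1
        keep <- cxs - half >= 0 & cys - half >= 0 &
            cxs + half <= w - 1 & cys + half <= h - 1
        okIdx <- okIdx[keep, , drop = FALSE]
    }
    if (nrow(okIdx) < nTemplates)
        registrationError(paste0(
            "assembloid too small for %d templates of %d px: enlarge the mask, ",
            "reduce nTemplates or templateSizePx"), nTemplates, templateSizePx)
    ## local variance over a box about the template size
    k <- templateSizePx - 1 + templateSizePx %% 2  # nearest odd
    box <- matrix(1 / (k * k), k, k)
    mu <- as.matrix(EBImage::filter2(EBImage::Image(gray), box))
    mu2 <- as.matrix(EBImage::filter2(EBImage::Image(gray^2), box))
    lv <- pmax(mu2 - mu^2, 0)
    vals <- lv[okIdx]
    ord <- order(vals, decreasing = TRUE)
    sel <- list()
    selx <- numeric(0); sely <- numeric(0)
    for (i in ord) {
        cx <- okIdx[i, 2] - 1; cy <- okIdx[i, 1] - 1
        if (length(selx) &&
            any(sqrt((selx - cx)^2 + (sely - cy)^2) < templateSizePx)) next
        x0 <- round(cx - half); y0 <- round(cy - half)
        sel[[length(sel) + 1]] <- list(
            x = x0, y = y0, cx = cx, cy = cy,
            patch = gray[(y0 + 1):(y0 + templateSizePx),
                         (x0 + 1):(x0 + templateSizePx)])
        selx <- c(selx, cx); sely <- c(sely, cy)
        if (length(sel) == nTemplates) break
    }
    if (length(sel) < nTemplates)
        registrationError("could only place %d of %d non-overlapping templates",
                          length(sel), nTemplates)
    if (max(vals) <= 1e-10)
        warning("templates selected from zero-variance (featureless) texture")
    sel
}

## subpixel peak of a 2D score surface around its max; NA cells -> -Inf
peakSubpixel <- function(scores, maximize = TRUE) {
    s <- scores
    s[is.na(s)] <- if (maximize) -Inf else Inf
    idx <- if (maximize) which(s == max(s), arr.ind = TRUE) else
        which(s == min(s), arr.ind = TRUE)
    ## ties -> offset closest to zero (matrix center)
    ctr <- (dim(s) + 1) / 2
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    best <- idx[which.min(d2), ]
    iy <- best[1]; ix <- best[2]
    offy <- offx <- 0
    if (iy > 1 && iy < nrow(s) && all(is.finite(s[(iy - 1):(iy + 1), ix]))) {
        v <- s[(iy - 1):(iy + 1), ix]; if (!maximize) v <- -v
        offy <- quadPeakOffset(v[1], v[2], v[3])
    }
    if (ix > 1 && ix < ncol(s) && all(is.finite(s[iy, (ix - 1):(ix + 1)]))) {
        v <- s[iy, (ix - 1):(ix + 1)]; if (!maximize) v <- -v
        offx <- quadPeakOffset(v[1], v[2], v[3])
    }
    list(iy = iy, ix = ix, offy = offy, offx = offx, score = scores[iy, ix])
}

#' Estimate the translation of a frame relative to a reference
#'
#' Each template from the reference is matched against the moving frame by
#' zero-normalised cross-correlation over a bounded search window; the peak
#' is refined to subpixel precision by a quadratic fit. The reported
#' displacement is the componentwise median over templates whose peak score
#' reaches `scoreFloor`; `quality` is the median peak score.
#'
#' @param ref,mov grayscale matrices (`ref` is the frame the templates came
#'   from).
#' @param templates list from [selectTemplates()].
#' @param searchPx search radius in px (window is `2*searchPx + 1` wide).
#' @param scoreFloor minimum correlation score for a template to vote.
#' @return list `(dx, dy, quality, nUsed)`: `(dx, dy)` is the motion of
#'   `mov` relative to `ref` (positive dx = content moved rightward).
#' @export
estimateTranslation <- function(ref, mov, templates, searchPx = 48,
                                scoreFloor = 0.5) {
    dxs <- dys <- scores <- numeric(0)
    for (tp in templates) {
        sm <- match_zncc_cpp(mov, tp$patch, tp$x, tp$y, as.integer(searchPx))
        if (all(is.na(sm))) next
        pk <- peakSubpixel(sm, maximize = TRUE)
        if (is.na(pk$score) || pk$score < scoreFloor) next
        if (pk$score >= 1 - 1e-9) {          # perfect lattice match: exact
            pk$offx <- 0; pk$offy <- 0
        }
        dxs <- c(dxs, pk$ix - 1 - searchPx + pk$offx)
        dys <- c(dys, pk$iy - 1 - searchPx + pk$offy)
        scores <- c(scores, pk$score)
    }
    if (!length(dxs))
        stError(c("noMatchError", "registrationError"),
                "no template matched above score floor %.2f", scoreFloor)
    list(dx = median(dxs), dy = median(dys), quality = median(scores),
         nUsed = length(dxs))
}

## ---- polar unwrapping and rotation ----

#' PolarImage: a frame resampled to (radius, angle) axes
#'
#' @slot img matrix; rows = radius 0..(rMax-1) px, columns = angle bins of
#'   `dthetaBin` degrees starting at 0 (y-down angle convention; the angular
#'   axis wraps).
#' @slot center (cx, cy) used for the unwrap, 0-based.
#' @slot dthetaBin angular bin width in degrees.
#' @export
setClass("PolarImage", representation(
    img = "matrix", center = "numeric", dthetaBin = "numeric"
))

setValidity("PolarImage", function(object) {
    na <- 360 / object@dthetaBin
    if (abs(na - round(na)) > 1e-9) return("dthetaBin must divide 360 exactly")
    if (ncol(object@img) != round(na)) return("column count must equal 360/dthetaBin")
    TRUE
})

setMethod("show", "PolarImage", function(object) {
    cat(sprintf("PolarImage: %d radii x %d angle bins (%.3g deg/bin), center (%.1f, %.1f)\n",
                nrow(object@img), ncol(object@img), object@dthetaBin,
                object@center[1], object@center[2]))
})

#' Polar-unwrap a frame about a center
#'
#' Resamples the image so the vertical axis is radius and the horizontal
#' axis is angle; a rotation of the source about the center becomes a
#' circular horizontal shift (a counterclockwise rotation by delta shifts
#' content left by `delta / dthetaBin` columns). Bilinear sampling; points
#' beyond the image border read as 0.
#'
#' @param gray grayscale matrix.
#' @param center (cx, cy), 0-based.
#' @param rMax maximum radius in px (> 0).
#' @param dthetaBin angular bin width in degrees; must divide 360.
#' @return A [PolarImage-class].
#' @export
polarUnwrap <- function(gray, center, rMax, dthetaBin = 0.25) {
    if (rMax <= 0) configError("rMax must be > 0")
    na <- 360 / dthetaBin
    if (abs(na - round(na)) > 1e-9) configError("dthetaBin must divide 360")
    img <- polar_unwrap_cpp(gray, center[1], center[2], as.integer(ceiling(rMax)),
                            dthetaBin)
    new("PolarImage", img = img, center = as.numeric(center), dthetaBin = dthetaBin)
}

#' Estimate rotation between two polar-unwrapped frames
#'
#' Up to `nRegions` rectangular regions tiled across an informative radius
#' band of the reference polar image are matched against the moving polar
#' image by normalised squared difference (lower = better) over circular
#' angular shifts; each accepted region's offset is refined to
#' subpixel-bin precision by a quadratic fit and the rotation is the median
#' of accepted offsets (offsets are bounded well inside a half-turn, so the
#' linear median coincides with the circular median).
#'
#' @param polarRef,polarMov [PolarImage-class] objects with identical bins
#'   and dimensions.
#' @param nRegions maximum number of regions (<= 40 by convention).
#' @param maxShiftDeg angular search half-range in degrees.
#' @param scoreCeiling maximum normalised-squared-difference score for a
#'   region to vote.
#' @param radialBand informative band as fractions of the radius range
#'   (default 25%-95%).
#' @return rotation in degrees: the angle by which the source of `polarMov`
#'   is rotated relative to the source of `polarRef` (CCW positive).
#' @export
estimateRotation <- function(polarRef, polarMov, nRegions = 40,
                             maxShiftDeg = 20, scoreCeiling = 0.3,
                             radialBand = c(0.25, 0.95)) {
    if (!identical(dim(polarRef@img), dim(polarMov@img)) ||
        polarRef@dthetaBin != polarMov@dthetaBin)
        inputError("polar images must share bins and dimensions")
    nr <- nrow(polarRef@img); na <- ncol(polarRef@img)
    r0 <- floor(radialBand[1] * nr); r1 <- floor(radialBand[2] * nr)
    nAng <- min(10L, nRegions)
    nRad <- max(1L, min(nRegions %/% nAng, 4L))
    bandRows <- r1 - r0
    rh <- bandRows %/% nRad
    cw <- na %/% nAng
    maxShift <- as.integer(round(maxShiftDeg / polarRef@dthetaBin))
    offs <- numeric(0)
    for (ri in seq_len(nRad)) {
        for (ai in seq_len(nAng)) {
            rr0 <- r0 + (ri - 1) * rh
            cc0 <- (ai - 1) * cw
            sc <- match_ssd_polar_cpp(polarRef@img, polarMov@img,
                                      as.integer(rr0), as.integer(rh),
                                      as.integer(cc0), as.integer(cw), maxShift)
            i <- which.min(sc)
            if (!is.finite(sc[i]) || sc[i] > scoreCeiling) next
            off <- i - 1 - maxShift
            if (sc[i] > 1e-12 && i > 1 && i < length(sc))  # exact match: no refine
                off <- off + quadPeakOffset(-sc[i - 1], -sc[i], -sc[i + 1])
            offs <- c(offs, off)
        }
    }
    if (!length(offs))
        stError(c("noMatchError", "registrationError"),
                "no polar region matched below score ceiling %.2f", scoreCeiling)
    ## content shift s columns => source rotation of -s * bin (see polarUnwrap)
    -median(offs) * polarRef@dthetaBin
}

## ---- pair and stack registration ----

registrationDefaults <- function() list(
    nTemplates = 6L, templateSizePx = 64L, nRegions = 40L, dthetaBin = 0.25,
    convTolPx = 0.5, convTolDeg = 0.1, maxIterations = 15L, damping = 0.5,
    searchPx = 48L, refineSearchPx = 10L, maxShiftDeg = 20,
    scoreFloor = 0.5, scoreCeiling = 0.3, smoothingSigma = 2,
    minAreaPx = 1000, smoothTheta = FALSE
)

mergeParams <- function(params) {
    def <- registrationDefaults()
    unknown <- setdiff(names(params), names(def))
    if (length(unknown)) configError("unknown registration parameter '%s'", unknown[1])
    def[names(params)] <- params
    def
}

#' Register one frame pair
#'
#' Estimates the rigid motion (dx, dy, theta) of `mov` relative to `ref` by
#' iterative refinement: (1) template-matching translation with a damped
#' update, (2) rotation from polar-unwrapped frames with a damped update,
#' (3) translation re-estimated at the updated alignment; the loop stops
#' when both per-iteration updates fall below the convergence tolerances or
#' `maxIterations` is reached. All matching is restricted to the hull mask.
#'
#' @param ref,mov grayscale matrices.
#' @param mask an [AssembloidMask-class] for `ref`; segmented from `ref`
#'   when `NULL`.
#' @param params named list overriding [registrationDefaults()]: notably
#'   `nTemplates` (6), `templateSizePx` (64), `nRegions` (40), `dthetaBin`
#'   (0.25 deg), `convTolPx` (0.5), `convTolDeg` (0.1), `maxIterations`
#'   (15), `damping` (0.5).
#' @param init optional [RigidTransform-class] initial motion estimate.
#' @return list with `transform` (a [RigidTransform-class]: estimated
#'   motion of `mov`; apply [invertTransform()] of it to `mov` to align it
#'   with `ref`) and `diagnostics` (`iterations`, `converged`, `residual`).
#' @export
registerPair <- function(ref, mov, mask = NULL, params = list(), init = NULL) {
    p <- mergeParams(params)
    h <- nrow(ref); w <- ncol(ref)
    center <- c(w / 2, h / 2)
    if (is.null(mask))
        mask <- segmentAssembloid(ref, smoothingSigma = p$smoothingSigma,
                                  minAreaPx = p$minAreaPx)
    templates <- selectTemplates(ref, mask, p$nTemplates, p$templateSizePx)
    hullR <- max(sqrt((mask@hull[, 1] - center[1])^2 +
                      (mask@hull[, 2] - center[2])^2))
    rMax <- min(hullR, min(w, h) / 2 - 1)
    polarRef <- polarUnwrap(ref, center, rMax, p$dthetaBin)

    M <- if (is.null(init)) RigidTransform(center = center) else
        RigidTransform(init@dx, init@dy, init@theta, center)
    iter <- 0L; converged <- FALSE; residual <- NA_real_
    repeat {
        iter <- iter + 1L
        movC <- applyTransform(mov, invertTransform(M))
        est <- estimateTranslation(ref, movC, templates,
                                   searchPx = if (iter == 1L) p$searchPx
                                              else p$refineSearchPx,
                                   scoreFloor = p$scoreFloor)
        u1 <- p$damping * c(est$dx, est$dy)
        M <- composeTransforms(M, RigidTransform(u1[1], u1[2], 0, center))

        movC <- applyTransform(mov, invertTransform(M))
        polarMov <- polarUnwrap(movC, center, rMax, p$dthetaBin)
        dth <- estimateRotation(polarRef, polarMov, p$nRegions, p$maxShiftDeg,
                                p$scoreCeiling)
        uTh <- p$damping * dth
        M <- composeTransforms(M, RigidTransform(0, 0, uTh, center))

        movC <- applyTransform(mov, invertTransform(M))
        est2 <- estimateTranslation(ref, movC, templates,
                                    searchPx = p$refineSearchPx,
                                    scoreFloor = p$scoreFloor)
        u2 <- p$damping * c(est2$dx, est2$dy)
        M <- composeTransforms(M, RigidTransform(u2[1], u2[2], 0, center))
        residual <- est2$quality

        if (max(abs(c(u1, u2))) < p$convTolPx && abs(uTh) < p$convTolDeg) {
            converged <- TRUE
            break
        }
        if (iter >= p$maxIterations) break
    }
    list(transform = M,
         diagnostics = list(iterations = iter, converged = converged,
                            residual = residual))
}

grayRecipe <- function(stack) {
    roles <- names(stack@channelRoles)
    nc <- dim(stack@data)[3]
    if ("brightfield" %in% roles) {
        function(frame) toGray(frame, stack@channelRoles[["brightfield"]])
    } else {
        wts <- rep(0, nc)
        wts[stack@channelRoles[["red"]]] <- 1
        wts[stack@channelRoles[["green"]]] <- 1
        function(frame) toGray(frame, wts)
    }
}

#' Register a whole time-lapse stack
#'
#' Frame 0 is segmented and recentered on its centroid; every consecutive
#' pair is then registered with [registerPair()] against the motion-corrected
#' predecessor (so the reference is always the centered structure), and the
#' per-pair motions are composed into cumulative transforms back to frame 0.
#' A failed pair is recorded as identity motion with a warning and
#' registration continues.
#'
#' @param stack a [FrameStack-class]; the brightfield channel (or the
#'   red+green mean when absent) is used as the matching grayscale.
#' @param params see [registerPair()]; additionally `smoothTheta = TRUE`
#'   applies a 3-point running median to the per-pair theta series.
#' @return A [RegistrationResult-class].
#' @export
registerStack <- function(stack, params = list()) {
    p <- mergeParams(params)
    gray <- grayRecipe(stack)
    nT <- nFrames(stack)
    d <- frameDim(stack)
    center <- c(d[2] / 2, d[1] / 2)

    g0 <- gray(getFrame(stack, 1))
    mask0 <- segmentAssembloid(g0, smoothingSigma = p$smoothingSigma,
                               minAreaPx = p$minAreaPx)
    rc <- recenterFrame(g0, mask0@centroid)
    refShift <- rc$shift
    hull0 <- sweep(mask0@hull, 2, refShift, "+")
    mask0 <- new("AssembloidMask", mask = fillConvexPolygon(hull0, d[1], d[2]),
                 hull = hull0, centroid = mask0@centroid + refShift,
                 areaPx = mask0@areaPx)

    grays <- vector("list", nT)
    grays[[1]] <- rc$frame
    for (t in 2:nT)
        grays[[t]] <- shiftMatrix(gray(getFrame(stack, t)), refShift[1], refShift[2])

    ident <- RigidTransform(center = center)
    cumulative <- vector("list", nT); cumulative[[1]] <- ident
    pairs <- vector("list", nT - 1)
    diag <- data.frame(pair = seq_len(nT - 1), iterations = NA_integer_,
                       converged = FALSE, residual = NA_real_)
    Mprev <- ident
    refC <- grays[[1]]
    for (k in 2:nT) {
        res <- tryCatch(
            registerPair(refC, grays[[k]], mask = mask0, params = params,
                         init = Mprev),
            registrationError = function(e) e)
        if (inherits(res, "error")) {
            warning(sprintf("pair %d->%d failed (%s); identity carried forward",
                            k - 1, k, conditionMessage(res)))
            Mtot <- Mprev
            diag$iterations[k - 1] <- 0L
        } else {
            Mtot <- res$transform
            diag$iterations[k - 1] <- res$diagnostics$iterations
            diag$converged[k - 1] <- res$diagnostics$converged
            diag$residual[k - 1] <- res$diagnostics$residual
        }
        pairs[[k - 1]] <- composeTransforms(Mtot, invertTransform(Mprev))
        cumulative[[k]] <- Mtot
        Mprev <- Mtot
        refC <- applyTransform(grays[[k]], invertTransform(Mtot))
    }
    if (isTRUE(p$smoothTheta) && nT > 3) {
        th <- vapply(pairs, function(x) x@theta, 0)
        thS <- th
        for (i in 2:(length(th) - 1)) thS[i] <- median(th[(i - 1):(i + 1)])
        for (i in seq_along(pairs))
            pairs[[i]] <- RigidTransform(pairs[[i]]@dx, pairs[[i]]@dy, thS[i], center)
        for (k in 2:nT)
            cumulative[[k]] <- composeTransforms(pairs[[k - 1]], cumulative[[k - 1]])
    }
    new("RegistrationResult", pairTransforms = pairs, cumulative = cumulative,
        diagnostics = diag, refShift = as.numeric(refShift), center = center)
}

#' Apply a registration result to a stack
#'
#' Recenters every frame by the frame-0 shift and warps it by the inverse of
#' its cumulative motion, yielding a stack in which the assembloid stays
#' centered and orientation-fixed.
#'
#' @param stack the original [FrameStack-class].
#' @param result a [RegistrationResult-class] from [registerStack()].
#' @return a registered [FrameStack-class].
#' @export
applyRegistration <- function(stack, result) {
    nT <- nFrames(stack)
    d <- dim(stack@data)
    out <- array(0, d)
    for (t in seq_len(nT)) {
        fr <- getFrame(stack, t)
        if (length(dim(fr)) == 2) dim(fr) <- c(d[1], d[2], 1L)
        for (c in seq_len(d[3]))
            fr[, , c] <- shiftMatrix(matrix(fr[, , c], d[1], d[2]),
                                     result@refShift[1], result@refShift[2])
        out[, , , t] <- applyTransform(fr, invertTransform(result@cumulative[[t]]))
    }
    FrameStack(out, stack@channelRoles, stack@pixelSizeUm, stack@frameIntervalMin)
}

#' Map registered coordinates back to raw-frame coordinates
#'
#' @param xy two-column matrix of registered (x, y), 0-based.
#' @param result a [RegistrationResult-class].
#' @param t frame index (1-based).
#' @return two-column matrix of raw-frame coordinates.
#' @export
registeredToRaw <- function(xy, result, t) {
    M <- result@cumulative[[t]]
    th <- M@theta * pi / 180
    ctr <- M@center
    px <- xy[, 1] - ctr[1]; py <- xy[, 2] - ctr[2]
    rx <- cos(th) * px + sin(th) * py + ctr[1] + M@dx - result@refShift[1]
    ry <- -sin(th) * px + cos(th) * py + ctr[2] + M@dy - result@refShift[2]
    cbind(x = rx, y = ry)
}
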