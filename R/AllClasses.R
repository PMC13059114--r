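#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats median sd quantile rnorm runif setNames t.test
#' @importFrom utils read.csv write.csv head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib spheroTrack, .registration = TRUE
NULL

#' FrameStack: a calibrated multi-channel time-lapse
#'
#' Ordered multi-channel 2D image sequence with physical calibration. Pixel
#' data live in a 4D array `[y, x, channel, t]` (row = y downward, column = x
#' rightward, 0-based positions reported by all analysis functions).
#' Intensities are stored as doubles; integer inputs are preserved exactly.
#'
#' @slot data numeric 4D array, dim = (height, width, n_channels, n_frames).
#' @slot channelRoles named integer vector mapping roles (subset of
#'   `"brightfield"`, `"red"`, `"green"`) to channel indices (1-based).
#' @slot pixelSizeUm microns per pixel (> 0).
#' @slot frameIntervalMin minutes between consecutive frames (> 0).
#' @export
setClass("FrameStack", representation(
    data = "array",
    channelRoles = "integer",
    pixelSizeUm = "numeric",
    frameIntervalMin = "numeric"
))

setValidity("FrameStack", function(object) {
    d <- dim(object@data)
    if (length(d) != 4) return("data must be a 4D array (y, x, channel, t)")
    if (d[4] < 2) return("a FrameStack needs at least 2 frames")
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
    if (object@frameIntervalMin <= 0) return("frameIntervalMin must be > 0")
    roles <- names(object@channelRoles)
    bad <- setdiff(roles, c("brightfield", "red", "green"))
    if (length(bad)) return(paste("unknown channel role:", bad[1]))
    if (any(object@channelRoles < 1L | object@channelRoles > d[3]))
        return("channelRoles index out of range")
    TRUE
})

#' Construct a FrameStack
#'
#' @param data 4D numeric array (height, width, n_channels, n_frames), or a
#'   list of per-frame arrays (height, width, n_channels) with identical
#'   dimensions.
#' @param channelRoles named integer/numeric vector, e.g.
#'   `c(brightfield = 1, red = 2, green = 3)`.
#' @param pixelSizeUm microns per pixel.
#' @param frameIntervalMin minutes between frames.
#' @return A [FrameStack-class] object.
#' @export
FrameStack <- function(data, channelRoles, pixelSizeUm = 1, frameIntervalMin = 60) {
    if (is.list(data)) {
        dims <- lapply(data, dim)
        if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1)
            formatError("frames have inconsistent dimensions")
        d3 <- dims[[1]]
        if (length(d3) == 2) d3 <- c(d3, 1L)
        arr <- array(0, c(d3[1], d3[2], d3[3], length(data)))
        for (t in seq_along(data)) arr[, , , t] <- data[[t]]
        data <- arr
    }
    if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
    bad <- setdiff(names(channelRoles), c("brightfield", "red", "green"))
    if (length(bad)) configError("unknown channel role '%s'", bad[1])
    new("FrameStack", data = data,
        channelRoles = setNames(as.integer(channelRoles), names(channelRoles)),
        pixelSizeUm = pixelSizeUm, frameIntervalMin = frameIntervalMin)
}

#' AssembloidMask: segmented structure outline
#'
#' Binary mask of the assembloid together with the convex hull of its outer
#' contour, the hull centroid, and the hull area.
#'
#' @slot mask logical matrix (same size as the source frame).
#' @slot hull two-column matrix of (x, y) hull vertices, 0-based, subpixel.
#' @slot centroid numeric (cx, cy), 0-based subpixel.
#' @slot areaPx hull area in px^2.
#' @export
setClass("AssembloidMask", representation(
    mask = "matrix", hull = "matrix", centroid = "numeric", areaPx = "numeric"
))

setValidity("AssembloidMask", function(object) {
    if (object@areaPx <= 0) return("hull area must be > 0")
    if (length(object@centroid) != 2) return("centroid must be (cx, cy)")
    if (ncol(object@hull) != 2) return("hull must be an (x, y) matrix")
    TRUE
})

#' RigidTransform: per-frame-pair rigid motion
#'
#' A rigid transform (dx, dy, theta) about a pivot: a point p maps to
#' `R(theta) (p - center) + center + (dx, dy)`, with theta in degrees,
#' positive = counterclockwise on a y-down display. As returned by
#' [registerPair()] it describes the estimated motion of the moving frame
#' relative to the reference; the correction that re-aligns the moving frame
#' is its inverse ([invertTransform()]).
#'
#' @slot dx,dy translation in pixels.
#' @slot theta rotation in degrees, normalised to (-180, 180].
#' @slot center pivot (cx, cy), 0-based pixels.
#' @export
setClass("RigidTransform", representation(
    dx = "numeric", dy = "numeric", theta = "numeric", center = "numeric"
))

#' @param dx,dy translation in pixels.
#' @param theta rotation (degrees, CCW on a y-down display).
#' @param center rotation pivot (cx, cy).
#' @rdname RigidTransform-class
#' @export
RigidTransform <- function(dx = 0, dy = 0, theta = 0, center = c(0, 0)) {
    new("RigidTransform", dx = dx, dy = dy, theta = wrapAngle(theta),
        center = as.numeric(center))
}

#' RegistrationResult: per-pair and cumulative transforms
#'
#' @slot pairTransforms list of [RigidTransform-class], one per consecutive
#'   frame pair (estimated motion of frame k relative to frame k-1).
#' @slot cumulative list of [RigidTransform-class], motion of frame k
#'   relative to frame 0 (`cumulative[[1]]` is the identity).
#' @slot diagnostics data.frame with one row per pair: iterations, converged,
#'   residual (median translation-match score at convergence).
#' @slot refShift integer (dx, dy) recentering shift applied to frame 0.
#' @slot center rotation pivot used (image center), 0-based.
#' @export
setClass("RegistrationResult", representation(
    pairTransforms = "list", cumulative = "list", diagnostics = "data.frame",
    refShift = "numeric", center = "numeric"
))

#' SyntheticScene: ground-truthed rendering script
#'
#' Everything needed to render a synthetic FUCCI assembloid video and to
#' evaluate registration/tracking against known truth.
#'
#' @slot seed integer seed the scene was drawn with.
#' @slot params list of generation parameters (frame size, disc, motion
#'   bounds, cell count/behaviour, noise).
#' @slot motionScript data.frame: pair, dx, dy, dtheta — true per-pair rigid
#'   motion of the disc.
#' @slot cumulativeMotion data.frame: t, dx, dy, theta — composed motion of
#'   frame t relative to frame 0.
#' @slot cells data.frame of truth tracks: cell_id, t, x_ref, y_ref
#'   (frame-0/disc coordinates), x_raw, y_raw (rendered position after
#'   motion), phase.
#' @slot texture matrix: the disc texture of frame 0 (brightfield-like).
#' @export
setClass("SyntheticScene", representation(
    seed = "integer", params = "list", motionScript = "data.frame",
    cumulativeMotion = "data.frame", cells = "data.frame", texture = "matrix"
))

## ---- accessors ----

#' @describeIn FrameStack-class number of frames
#' @param x,object a FrameStack.
#' @export
nFrames <- function(x) dim(x@data)[4]

#' @describeIn FrameStack-class image dimensions as c(height, width)
#' @export
frameDim <- function(x) dim(x@data)[1:2]

#' @describeIn FrameStack-class one frame as (height, width, channel) array
#' @param t frame index, 1-based.
#' @export
getFrame <- function(x, t) x@data[, , , t, drop = FALSE][, , , 1, drop = TRUE]

#' @describeIn FrameStack-class one channel of one frame as a matrix
#' @param role channel role name ("brightfield", "red", "green").
#' @export
getChannel <- function(x, t, role) {
    if (!role %in% names(x@channelRoles))
        configError("channel role '%s' not present in stack", role)
    ch <- x@channelRoles[[role]]
    matrix(x@data[, , ch, t], dim(x@data)[1], dim(x@data)[2])
}

#' @describeIn FrameStack-class pixel size accessor (um/px)
#' @export
pixelSizeUm <- function(x) x@pixelSizeUm

#' @describeIn FrameStack-class frame interval accessor (minutes)
#' @export
frameIntervalMin <- function(x) x@frameIntervalMin

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("FrameStack: %d frames, %dx%d px, %d channel(s)\n",
                d[4], d[2], d[1], d[3]))
    cat(sprintf("  roles: %s\n", paste(sprintf("%s=%d", names(object@channelRoles),
                object@channelRoles), collapse = ", ")))
    cat(sprintf("  calibration: %.4g um/px, %.4g min/frame\n",
                object@pixelSizeUm, object@frameIntervalMin))
})

setMethod("show", "RigidTransform", function(object) {
    cat(sprintf("RigidTransform: dx=%.3f px, dy=%.3f px, theta=%.3f deg (pivot %.1f, %.1f)\n",
                object@dx, object@dy, object@theta, object@center[1], object@center[2]))
})

setMethod("show", "AssembloidMask", function(object) {
    cat(sprintf("AssembloidMask: centroid (%.2f, %.2f), hull area %.1f px^2, %d hull vertices\n",
                object@centroid[1], object@centroid[2], object@areaPx, nrow(object@hull)))
})

setMethod("show", "RegistrationResult", function(object) {
    n <- length(object@pairTransforms)
    cat(sprintf("RegistrationResult: %d frame pairs, %d converged, mean iterations %.1f\n",
                n, sum(object@diagnostics$converged),
                mean(object@diagnostics$iterations)))
})

setMethod("show", "SyntheticScene", function(object) {
    p <- object@params
    cat(sprintf("SyntheticScene: %d frames %dx%d px, disc r=%g px, %d cells, seed %d\n",
                p$n_frames, p$width, p$height, p$disc_radius_px,
                p$n_cells, object@seed))
})

#' @describeIn AssembloidMask-class centroid accessor (0-based cx, cy)
#' @export
maskCentroid <- function(x) x@centroid

#' @describeIn AssembloidMask-class hull area accessor (px^2)
#' @export
maskAreaPx <- function(x) x@areaPx

#' @describeIn RegistrationResult-class per-pair + cumulative transform table
#' @export
transformTable <- function(x) {
    pt <- x@pairTransforms
    cm <- x@cumulative
    n <- length(cm)
    data.frame(
        t = seq_len(n) - 1L,
        dx_px = c(NA, vapply(pt, function(p) p@dx, 0)),
        dy_px = c(NA, vapply(pt, function(p) p@dy, 0)),
        theta_deg = c(NA, vapply(pt, function(p) p@theta, 0)),
        cum_dx_px = vapply(cm, function(p) p@dx, 0),
        cum_dy_px = vapply(cm, function(p) p@dy, 0),
        cum_theta_deg = vapply(cm, function(p) p@theta, 0),
        iterations = c(NA, x@diagnostics$iterations),
        converged = c(NA, x@diagnostics$converged),
        residual = c(NA, x@diagnostics$residual)
    )
}
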