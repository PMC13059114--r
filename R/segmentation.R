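## Assembloid outline extraction: smoothing, thresholding, largest component,
## convex hull, centroid, and recentering on the centroid.

## Shoelace area of an (x, y) polygon (vertices in order).
polygonArea <- function(xy) {
    n <- nrow(xy)
    if (n < 3) return(0)
    x <- xy[, 1]; y <- xy[, 2]
    j <- c(2:n, 1)
    abs(sum(x * y[j] - x[j] * y)) / 2
}

## Rasterise a convex polygon: logical matrix of pixels whose centers fall
## inside (or on) the hull. Scanline over rows with edge intersections.
fillConvexPolygon <- function(xy, h, w) {
    out <- matrix(FALSE, h, w)
    n <- nrow(xy)
    if (n < 3) return(out)
    ys <- xy[, 2]
    for (row in max(0, floor(min(ys))):min(h - 1, ceiling(max(ys)))) {
        xs <- numeric(0)
        for (k in seq_len(n)) {
            k2 <- if (k == n) 1 else k + 1
            y1 <- xy[k, 2]; y2 <- xy[k2, 2]
            if ((y1 <= row && y2 >= row) || (y2 <= row && y1 >= row)) {
                if (y1 == y2) {
                    xs <- c(xs, xy[k, 1], xy[k2, 1])
                } else {
                    f <- (row - y1) / (y2 - y1)
                    xs <- c(xs, xy[k, 1] + f * (xy[k2, 1] - xy[k, 1]))
                }
            }
        }
        if (length(xs) >= 2) {
            x0 <- max(0, ceiling(min(xs) - 1e-9))
            x1 <- min(w - 1, floor(max(xs) + 1e-9))
            if (x1 >= x0) out[row + 1, (x0 + 1):(x1 + 1)] <- TRUE
        }
    }
    out
}

#' Segment the assembloid in a grayscale frame
#'
#' Gaussian smoothing, global thresholding (Otsu by default), retention of
#' the largest connected foreground component, and computation of that
#' component's convex hull, filled hull mask, geometric centroid, and hull
#' area. The hull serves downstream as the mask restricting all template
#' matching to the biological structure.
#'
#' @param gray grayscale matrix (non-constant).
#' @param smoothingSigma Gaussian sigma in px (default 2).
#' @param thresholdMethod `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold on the smoothed image (used when
#'   `thresholdMethod = "fixed"`), on the intensity scale of `gray`.
#' @param minAreaPx minimum component area in px^2 (default 1000).
#' @return An [AssembloidMask-class]: `mask` is the filled convex hull,
#'   `hull` its (x, y) vertices (0-based), `centroid` the mean pixel position
#'   of the filled hull, `areaPx` the hull polygon area.
#' @export
segmentAssembloid <- function(gray, smoothingSigma = 2,
                              thresholdMethod = c("otsu", "fixed"),
                              threshold = NULL, minAreaPx = 1000) {
    thresholdMethod <- match.arg(thresholdMethod)
    rng <- range(gray)
    if (rng[1] == rng[2]) segmentationError("no assembloid found: constant image")
    sm <- if (smoothingSigma > 0)
        as.matrix(EBImage::gblur(EBImage::Image(gray), sigma = smoothingSigma))
    else gray
    thr <- if (thresholdMethod == "otsu") {
        norm <- (sm - min(sm)) / (max(sm) - min(sm))
        EBImage::otsu(EBImage::Image(norm)) * (max(sm) - min(sm)) + min(sm)
    } else {
        if (is.null(threshold)) configError("fixed threshold requested but none given")
        threshold
    }
    bw <- sm > thr
    lab <- EBImage::bwlabel(EBImage::Image(bw))
    labm <- as.matrix(lab)
    if (max(labm) == 0) segmentationError("no assembloid found: empty threshold")
    sizes <- tabulate(labm[labm > 0])
    big <- which.max(sizes)
    if (sizes[big] < minAreaPx)
        segmentationError("no assembloid found: largest component %d px < %d",
                          sizes[big], minAreaPx)
    idx <- which(labm == big, arr.ind = TRUE)
    ## 0-based (x, y) pixel centers of the component
    pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    hidx <- grDevices::chull(pts[, 1], pts[, 2])
    hull <- pts[hidx, , drop = FALSE]
    mask <- fillConvexPolygon(hull, nrow(gray), ncol(gray))
    midx <- which(mask, arr.ind = TRUE)
    centroid <- c(mean(midx[, 2]) - 1, mean(midx[, 1]) - 1)
    new("AssembloidMask", mask = mask, hull = hull, centroid = centroid,
        areaPx = polygonArea(hull))
}

## integer translation of a matrix with zero fill
shiftMatrix <- function(m, dx, dy) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    srcx <- seq_len(w) - dx; srcy <- seq_len(h) - dy
    okx <- srcx >= 1 & srcx <= w; oky <- srcy >= 1 & srcy <= h
    out[oky, okx] <- m[srcy[oky], srcx[okx]]
    out
}

#' Recenter a frame on a centroid
#'
#' Applies the integer-rounded translation that places `centroid` at the
#' image center (width/2, height/2); vacated pixels are zero-filled.
#'
#' @param frame (height, width, channel) array or a matrix.
#' @param centroid (cx, cy), 0-based.
#' @return list with `frame` (translated) and `shift` (applied integer
#'   (dx, dy)).
#' @export
recenterFrame <- function(frame, centroid) {
    d <- dim(frame)
    h <- d[1]; w <- d[2]
    shift <- round(c(w / 2, h / 2) - centroid)
    if (length(d) == 2) {
        out <- shiftMatrix(frame, shift[1], shift[2])
    } else {
        out <- array(0, d)
        for (c in seq_len(d[3]))
            out[, , c] <- shiftMatrix(matrix(frame[, , c], h, w), shift[1], shift[2])
    }
    list(frame = out, shift = shift)
}

#' Export a mask as an 8-bit PNG
#'
#' @param mask an [AssembloidMask-class] or logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
    m <- if (is(mask, "AssembloidMask")) mask@mask else mask
    png::writePNG(m * 1.0, path)
    invisible(path)
}
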