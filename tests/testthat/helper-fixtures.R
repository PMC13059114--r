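## Shared fixtures, built in code.

## a bright disc (optionally textured) on dark background
makeDisc <- function(size = 256, radius = 80, center = c(size / 2, size / 2),
                     textured = FALSE, seed = 42) {
    xs <- matrix(0:(size - 1), size, size, byrow = TRUE) - center[1]
    ys <- matrix(0:(size - 1), size, size) - center[2]
    r <- sqrt(xs^2 + ys^2)
    disc <- pmin(pmax((radius + 2 - r) / 4, 0), 1)
    if (!textured) return(disc)
    set.seed(seed)
    wn <- matrix(rnorm(size * size), size, size)
    bp <- as.matrix(EBImage::gblur(EBImage::Image(wn), 5)) -
        as.matrix(EBImage::gblur(EBImage::Image(wn), 14))
    bp <- (bp - mean(bp)) / sd(bp)
    matrix(pmin(pmax(0.55 + 0.2 * as.numeric(bp), 0.15), 0.95), size, size) * disc
}

## small-scene parameter set that keeps unit tests fast
smallSceneParams <- function(...) {
    modifyList(list(width = 256L, height = 256L, n_frames = 6L,
                    disc_radius_px = 80, n_cells = 8L, t_max = 3, r_max = 2,
                    max_drift = 12), list(...))
}

smallRegParams <- function(...) {
    modifyList(list(templateSizePx = 32L, searchPx = 24L), list(...))
}

## independent convex-hull-area oracle: gift wrapping + shoelace
giftWrapHullArea <- function(p) {
    p <- unique(p)
    n <- nrow(p)
    if (n < 3) return(0)
    start <- which.min(p[, 1] + 1e-9 * p[, 2])
    hull <- start
    repeat {
        cur <- hull[length(hull)]
        cand <- setdiff(seq_len(n), cur)
        nxt <- cand[1]
        for (k in cand[-1]) {
            cr <- (p[nxt, 1] - p[cur, 1]) * (p[k, 2] - p[cur, 2]) -
                (p[nxt, 2] - p[cur, 2]) * (p[k, 1] - p[cur, 1])
            d1 <- sum((p[k, ] - p[cur, ])^2)
            d2 <- sum((p[nxt, ] - p[cur, ])^2)
            if (cr < 0 || (cr == 0 && d1 > d2)) nxt <- k
        }
        if (nxt == start) break
        hull <- c(hull, nxt)
        if (length(hull) > n) stop("gift wrap failed")
    }
    xy <- p[hull, , drop = FALSE]
    m <- nrow(xy)
    if (m < 3) return(0)
    j <- c(2:m, 1)
    abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

## closed-form pooled-variance two-sample t (textbook formula)
studentTOracle <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
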