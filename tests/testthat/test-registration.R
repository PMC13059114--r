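## textured reference used across registration tests
regDisc <- makeDisc(size = 384, radius = 120, textured = TRUE, seed = 9)
regCenter <- c(192, 192)
regMask <- segmentAssembloid(regDisc)

test_that("rigid transform algebra composes and inverts correctly", {
    a <- RigidTransform(3, -2, 10, regCenter)
    b <- RigidTransform(-1, 5, -4, regCenter)
    ab <- composeTransforms(a, b)
    expect_equal(ab@theta, 6)
    id <- composeTransforms(a, invertTransform(a))
    expect_equal(c(id@dx, id@dy, id@theta), c(0, 0, 0), tolerance = 1e-12)
    ## action on a point matches matrix algebra
    p <- c(250, 150)
    th <- a@theta * pi / 180
    pa <- c(cos(th) * (p[1] - 192) + sin(th) * (p[2] - 192) + 192 + a@dx,
            -sin(th) * (p[1] - 192) + cos(th) * (p[2] - 192) + 192 + a@dy)
    thb <- b@theta * pi / 180
    pb <- c(cos(thb) * (pa[1] - 192) + sin(thb) * (pa[2] - 192) + 192 + b@dx,
            -sin(thb) * (pa[1] - 192) + cos(thb) * (pa[2] - 192) + 192 + b@dy)
    thc <- composeTransforms(b, a)  # apply a first, then b
    thcr <- thc@theta * pi / 180
    pc <- c(cos(thcr) * (p[1] - 192) + sin(thcr) * (p[2] - 192) + 192 + thc@dx,
            -sin(thcr) * (p[1] - 192) + cos(thcr) * (p[2] - 192) + 192 + thc@dy)
    expect_equal(pb, pc, tolerance = 1e-10)
})

test_that("applyTransform follows the documented geometry", {
    ## identity is bit-identical
    expect_identical(applyTransform(regDisc, RigidTransform(center = regCenter)),
                     regDisc)
    ## +90 deg CCW (y-down display): pixel right of center moves above center
    img <- matrix(0, 128, 128)
    img[65, 115] <- 1   # 0-based (x=114, y=64) = center (64,64) + (50, 0)
    out <- applyTransform(img, RigidTransform(0, 0, 90, c(64, 64)))
    peak <- which(out == max(out), arr.ind = TRUE)
    expect_equal(unname(peak[1, ]), c(64 - 50 + 1, 64 + 1), tolerance = 1)
    ## transform then inverse reproduces the interior
    tr <- RigidTransform(4, -3, 7, regCenter)
    rt <- applyTransform(applyTransform(regDisc, tr), invertTransform(tr))
    inner <- as.logical(EBImage::erode(EBImage::Image(regMask@mask),
                                       EBImage::makeBrush(31, "disc")))
    expect_lt(max(abs(rt[inner] - regDisc[inner])), 0.03 * max(regDisc))
})

test_that("selectTemplates honors count, containment and spacing", {
    tps <- selectTemplates(regDisc, regMask, nTemplates = 6, templateSizePx = 32)
    expect_length(tps, 6)
    ctrs <- t(vapply(tps, function(tp) c(tp$cx, tp$cy), c(0, 0)))
    ## all centers inside the hull
    expect_true(all(sqrt((ctrs[, 1] - regCenter[1])^2 +
                         (ctrs[, 2] - regCenter[2])^2) < 120))
    d <- as.matrix(dist(ctrs))
    expect_true(all(d[upper.tri(d)] >= 32))
    ## featureless texture still yields patches, with a warning
    flat <- makeDisc(size = 384, radius = 120)
    mf <- segmentAssembloid(flat)
    expect_warning(selectTemplates(flat, mf, 6, 32), "zero-variance")
    ## too-small structure errors
    tiny <- makeDisc(size = 128, radius = 20)
    mt <- segmentAssembloid(tiny, minAreaPx = 100)
    expect_error(selectTemplates(tiny, mt, 6, 64), class = "registrationError")
})

test_that("translation estimation is exact on integer shifts and close on subpixel", {
    tps <- selectTemplates(regDisc, regMask, 6, 32)
    mov <- spheroTrack:::shiftMatrix(regDisc, 5, -3)
    est <- estimateTranslation(regDisc, mov, tps, searchPx = 12)
    expect_equal(c(est$dx, est$dy), c(5, -3), tolerance = 1e-9)
    est0 <- estimateTranslation(regDisc, regDisc, tps, searchPx = 12)
    expect_equal(c(est0$dx, est0$dy), c(0, 0), tolerance = 1e-9)
    ## subpixel shift rendered with interpolation
    movS <- applyTransform(regDisc, RigidTransform(2.5, 0, 0, regCenter))
    estS <- estimateTranslation(regDisc, movS, tps, searchPx = 12)
    expect_lt(abs(estS$dx - 2.5), 0.5)
    expect_lt(abs(estS$dy), 0.5)
    ## nothing matches on a blank frame
    expect_error(estimateTranslation(regDisc, matrix(0, 384, 384), tps, 12),
                 class = "noMatchError")
})

test_that("polarUnwrap geometry: radial symmetry, spot position, rotation shift", {
    size <- 256; ctr <- c(128, 128)
    xs <- matrix(0:(size - 1), size, size, byrow = TRUE) - ctr[1]
    ys <- matrix(0:(size - 1), size, size) - ctr[2]
    radial <- sqrt(xs^2 + ys^2)
    p <- polarUnwrap(radial, ctr, 100, 0.5)
    rowSpread <- apply(p@img[10:90, ], 1, function(r) diff(range(r)))
    expect_lt(max(rowSpread), 0.02 * 100)     # rows constant on radial images
    ## bright spot at angle 90 deg (y-down: below center), radius 50
    img <- matrix(0, size, size)
    img[128 + 50 + 1, 128 + 1] <- 1
    ps <- polarUnwrap(img, ctr, 100, 0.5)
    pk <- which(ps@img == max(ps@img), arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), c(50 + 1, 90 / 0.5 + 1))
    expect_error(polarUnwrap(radial, ctr, 0), class = "configError")
})

test_that("rotation of the source equals a circular column shift of the polar image", {
    dtheta <- 0.5
    rot <- applyTransform(regDisc, RigidTransform(0, 0, 2 * dtheta, regCenter))
    p0 <- polarUnwrap(regDisc, regCenter, 110, dtheta)
    p1 <- polarUnwrap(rot, regCenter, 110, dtheta)
    ## CCW rotation by delta shifts columns left by delta/dtheta = 2
    shifted <- p0@img[, c(3:720, 1, 2)]
    band <- 20:100
    expect_lt(max(abs(p1@img[band, ] - shifted[band, ])),
              0.04 * diff(range(regDisc)))
})

test_that("estimateRotation recovers constructed shifts and true rotations", {
    p0 <- polarUnwrap(regDisc, regCenter, 110, 0.25)
    expect_equal(estimateRotation(p0, p0), 0, tolerance = 1e-9)
    ## constructed circular shift: 12 columns left = +3 deg rotation
    na <- ncol(p0@img)
    pShift <- new("PolarImage", img = p0@img[, c(13:na, 1:12)],
                  center = p0@center, dthetaBin = 0.25)
    expect_equal(estimateRotation(p0, pShift), 3, tolerance = 1e-6)
    ## real rotation of the textured disc
    rot <- applyTransform(regDisc, RigidTransform(0, 0, 3, regCenter))
    p1 <- polarUnwrap(rot, regCenter, 110, 0.25)
    expect_lt(abs(estimateRotation(p0, p1) - 3), 0.5)
    ## rotation equivariance: a further delta shifts the estimate by delta
    rot2 <- applyTransform(regDisc, RigidTransform(0, 0, 5.5, regCenter))
    p2 <- polarUnwrap(rot2, regCenter, 110, 0.25)
    expect_lt(abs(estimateRotation(p0, p2) - 5.5), 0.5)
})

test_that("registerPair recovers a known rigid motion within tolerance", {
    prm <- smallRegParams()
    same <- registerPair(regDisc, regDisc, mask = regMask, params = prm)
    expect_equal(c(same$transform@dx, same$transform@dy, same$transform@theta),
                 c(0, 0, 0), tolerance = 0.05)
    expect_equal(same$diagnostics$iterations, 1)
    expect_true(same$diagnostics$converged)

    tr <- RigidTransform(4, -6, 2, regCenter)
    mov <- applyTransform(regDisc, tr)
    res <- registerPair(regDisc, mov, mask = regMask, params = prm)
    expect_lt(abs(res$transform@dx - 4), 1)
    expect_lt(abs(res$transform@dy + 6), 1)
    expect_lt(abs(res$transform@theta - 2), 0.5)
    expect_lte(res$diagnostics$iterations, 15)
})

test_that("registerPair tolerates noise on a pure rotation", {
    set.seed(31)
    nconv <- 0; nok <- 0; reps <- 5
    for (r in seq_len(reps)) {
        mov <- applyTransform(regDisc, RigidTransform(0, 0, 5, regCenter))
        mov <- mov + matrix(rnorm(length(mov), 0, 0.1 * max(regDisc)),
                            nrow(mov), ncol(mov))
        res <- registerPair(regDisc, mov, mask = regMask,
                            params = smallRegParams())
        if (abs(res$transform@theta - 5) < 0.5) nok <- nok + 1
        if (res$diagnostics$converged) nconv <- nconv + 1
    }
    expect_gte(nok, reps - 1)
    expect_gte(nconv, ceiling(0.9 * reps))
})

test_that("registerStack recovers a scripted 10-frame video and survives a bad pair", {
    sc <- generateScene(list(width = 384L, height = 384L, n_frames = 10L,
                             disc_radius_px = 120, n_cells = 5L,
                             t_max = 4, r_max = 3, max_drift = 16), seed = 21)
    st <- renderStack(sc)
    reg <- registerStack(st, smallRegParams())
    ev <- evaluateRegistration(reg, sc)
    expect_lt(max(abs(ev$perPair$dx_err)), 1)
    expect_lt(max(abs(ev$perPair$dy_err)), 1)
    expect_lt(max(abs(ev$perPair$dtheta_err)), 0.5)
    expect_lt(tail(ev$cum_theta_err, 1), 1.5)
    ## static scene: all transforms identity within tolerance
    sc0 <- generateScene(list(width = 384L, height = 384L, n_frames = 4L,
                              disc_radius_px = 120, n_cells = 5L,
                              t_max = 0, r_max = 0), seed = 22)
    expect_true(all(abs(sc0@motionScript$dx) == 0))
    reg0 <- registerStack(renderStack(sc0), smallRegParams())
    tt <- transformTable(reg0)[-1, ]
    expect_lt(max(abs(c(tt$dx_px, tt$dy_px))), 0.5)
    expect_lt(max(abs(tt$theta_deg)), 0.25)
    ## a destroyed middle frame yields identity for its pairs, with a warning
    bad <- st
    bad@data[, , , 5] <- 0
    wr <- capture_warnings(regB <- registerStack(bad, smallRegParams()))
    expect_true(any(grepl("identity carried forward", wr)))
    expect_equal(length(regB@pairTransforms), 9)
    p5 <- regB@pairTransforms[[4]]   # pair into the blank frame
    expect_equal(c(p5@dx, p5@dy, p5@theta), c(0, 0, 0))
})

test_that("registered frames keep the assembloid centered", {
    sc <- generateScene(list(width = 384L, height = 384L, n_frames = 6L,
                             disc_radius_px = 120, n_cells = 5L,
                             t_max = 5, r_max = 3, max_drift = 20), seed = 23)
    st <- renderStack(sc)
    reg <- registerStack(st, smallRegParams())
    rst <- applyRegistration(st, reg)
    for (t in seq_len(nFrames(rst))) {
        m <- segmentAssembloid(getChannel(rst, t, "brightfield"))
        expect_lt(max(abs(maskCentroid(m) - c(192, 192))), 3)
    }
})
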