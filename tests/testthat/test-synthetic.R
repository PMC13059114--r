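test_that("scene generation is deterministic and honors motion bounds", {
    a <- generateScene(smallSceneParams(), seed = 17)
    b <- generateScene(smallSceneParams(), seed = 17)
    expect_identical(a@motionScript, b@motionScript)
    expect_identical(a@cells, b@cells)
    expect_identical(a@texture, b@texture)
    expect_true(all(abs(a@motionScript$dx) <= 3))
    expect_true(all(abs(a@motionScript$dtheta) <= 2))
    ## zero bounds give an identity script
    z <- generateScene(smallSceneParams(t_max = 0, r_max = 0), seed = 17)
    expect_true(all(z@motionScript[, c("dx", "dy", "dtheta")] == 0))
    ## cells stay inside the disc
    r <- sqrt((a@cells$x_ref - 128)^2 + (a@cells$y_ref - 128)^2)
    expect_true(all(r <= 80))
    expect_error(generateScene(list(disc_radius_px = 200, width = 256L,
                                    height = 256L)), class = "configError")
    expect_error(generateScene(list(bogus = 1)), class = "configError")
})

test_that("phase-coupled mode doubles the mean scripted step of G2/M cells", {
    sc <- generateScene(smallSceneParams(n_cells = 50L, n_frames = 12L,
                                         cell_mode = "phase_coupled"), seed = 19)
    cells <- sc@cells
    stepLen <- function(sub) {
        sub <- sub[order(sub$t), ]
        mean(sqrt(diff(sub$x_ref)^2 + diff(sub$y_ref)^2))
    }
    byCell <- vapply(split(cells, cells$cell_id), stepLen, 0)
    phase <- vapply(split(cells, cells$cell_id), function(s) s$phase[1], "")
    ratio <- mean(byCell[phase == "G2M"]) / mean(byCell[phase == "G1"])
    expect_lt(abs(ratio - 2), 2 * 0.05 * 2)   # within ~5% of the 2x coupling
})

test_that("rendering follows the phase-color contract and the motion script", {
    sc <- generateScene(smallSceneParams(n_cells = 1L, t_max = 0, r_max = 0,
                                         cell_speed = 0, noise_sigma = 0),
                        seed = 23)
    st <- renderStack(sc)
    truth <- sc@cells[sc@cells$t == 0, ]
    red <- getChannel(st, 1, "red"); green <- getChannel(st, 1, "green")
    if (truth$phase == "G1") {
        pk <- which(red == max(red), arr.ind = TRUE)
        expect_lt(max(abs(c(pk[1, 2] - 1, pk[1, 1] - 1) -
                          c(truth$x_raw, truth$y_raw))), 0.51)
        expect_lt(max(green), 1e-6)
    } else {
        expect_true(max(red) >= 0 && max(green) >= 0)
    }
    ## theta script {1, 1}: frame 3 is frame 1 rotated by 2 degrees
    scr <- generateScene(smallSceneParams(n_frames = 3L, n_cells = 0L,
                                          noise_sigma = 0), seed = 29)
    scr@motionScript$dx <- c(0, 0); scr@motionScript$dy <- c(0, 0)
    scr@motionScript$dtheta <- c(1, 1)
    scr@cumulativeMotion$dx <- 0; scr@cumulativeMotion$dy <- 0
    scr@cumulativeMotion$theta <- c(0, 1, 2)
    str <- renderStack(scr)
    f0 <- getChannel(str, 1, "brightfield")
    f2 <- getChannel(str, 3, "brightfield")
    f0rot <- applyTransform(f0, RigidTransform(0, 0, 2, c(128, 128)))
    ctr <- 60:200
    expect_lt(max(abs(f2[ctr, ctr] - f0rot[ctr, ctr])),
              0.05 * diff(range(f0)))
})

test_that("identical (params, seed) render byte-identical stacks", {
    p <- smallSceneParams(n_frames = 3L)
    s1 <- renderStack(generateScene(p, seed = 31))
    s2 <- renderStack(generateScene(p, seed = 31))
    expect_identical(s1@data, s2@data)
})

test_that("evaluateRegistration reports signed errors against the script", {
    sc <- generateScene(smallSceneParams(n_frames = 4L), seed = 37)
    center <- c(128, 128)
    ## perfect estimates: zero error
    pairs <- lapply(seq_len(3), function(k)
        RigidTransform(sc@motionScript$dx[k], sc@motionScript$dy[k],
                       sc@motionScript$dtheta[k], center))
    cum <- vector("list", 4); cum[[1]] <- RigidTransform(center = center)
    for (k in 2:4) cum[[k]] <- composeTransforms(pairs[[k - 1]], cum[[k - 1]])
    res <- new("RegistrationResult", pairTransforms = pairs, cumulative = cum,
               diagnostics = data.frame(pair = 1:3, iterations = 1L,
                                        converged = TRUE, residual = 1),
               refShift = c(0, 0), center = center)
    ev <- evaluateRegistration(res, sc)
    expect_equal(max(abs(as.matrix(ev$perPair[, -1]))), 0, tolerance = 1e-10)
    expect_equal(max(ev$cum_theta_err), 0, tolerance = 1e-10)
    ## constant +0.3 deg bias shows up as exactly 0.3 median error
    pairsB <- lapply(pairs, function(p)
        RigidTransform(p@dx, p@dy, p@theta + 0.3, center))
    resB <- new("RegistrationResult", pairTransforms = pairsB, cumulative = cum,
                diagnostics = res@diagnostics, refShift = c(0, 0),
                center = center)
    expect_equal(evaluateRegistration(resB, sc)$median_abs_dtheta, 0.3)
    ## length mismatch
    expect_error(evaluateRegistration(res, generateScene(smallSceneParams(
        n_frames = 6L), seed = 37)), class = "inputError")
})

test_that("evaluateTracking scores a perfect and an empty tracker", {
    sc <- generateScene(smallSceneParams(n_frames = 4L, n_cells = 5L), seed = 41)
    perfect <- sc@cells
    perfect$x <- perfect$x_ref; perfect$y <- perfect$y_ref
    perfect <- perfect[, c("cell_id", "t", "x", "y", "phase")]
    ev <- evaluateTracking(perfect, sc)
    expect_equal(ev$recall, 1)
    expect_equal(ev$link_accuracy, 1)
    expect_equal(ev$phase_accuracy, 1)
    empty <- perfect[integer(0), ]
    expect_equal(evaluateTracking(empty, sc)$recall, 0)
})
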