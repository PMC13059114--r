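test_that("path length and net displacement follow their definitions", {
    still <- data.frame(x = rep(3, 5), y = rep(4, 5))
    expect_equal(pathLength(still), 0)
    tr345 <- data.frame(x = c(0, 3, 3), y = c(0, 4, 4))
    expect_equal(pathLength(tr345), 5)
    expect_equal(netDisplacement(data.frame(x = c(0, 10), y = c(0, 0)), 0.65), 6.5)
    loop <- data.frame(x = c(0, 5, 5, 0, 0), y = c(0, 0, 5, 5, 0))
    expect_equal(netDisplacement(loop), 0)
    expect_error(pathLength(data.frame(x = 1, y = 1)), class = "metricError")
    ## random walks against a stepwise oracle
    set.seed(2)
    for (r in 1:10) {
        p <- data.frame(x = cumsum(rnorm(20)), y = cumsum(rnorm(20)))
        oracle <- 0
        for (i in 2:20) oracle <- oracle +
            sqrt((p$x[i] - p$x[i - 1])^2 + (p$y[i] - p$y[i - 1])^2)
        expect_equal(pathLength(p, 1.3), oracle * 1.3, tolerance = 1e-9)
        expect_gte(pathLength(p) - netDisplacement(p), -1e-12)
    }
})

test_that("convex hull area matches geometry and a brute-force oracle", {
    sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
    expect_equal(convexHullArea(sq), 1)
    col <- data.frame(x = 1:10, y = 2 * (1:10))
    expect_equal(convexHullArea(col), 0)
    expect_equal(convexHullArea(sq[1:2, ]), 0)
    set.seed(5)
    for (r in 1:100) {
        n <- sample(3:50, 1)
        p <- cbind(runif(n, 0, 100), runif(n, 0, 100))
        expect_equal(convexHullArea(p), giftWrapHullArea(p), tolerance = 1e-9)
    }
    ## permutation invariance and monotonicity under point addition
    p <- cbind(runif(20), runif(20))
    expect_equal(convexHullArea(p[sample(20), ]), convexHullArea(p))
    expect_gte(convexHullArea(rbind(p, c(2, 2))), convexHullArea(p))
})

test_that("dominantPhase uses the mode with a later-phase tie-break", {
    expect_equal(dominantPhase(rep("G1", 4)), "G1")
    expect_equal(dominantPhase(c(rep("G1", 6), rep("G2M", 4))), "G1")
    expect_equal(dominantPhase(c(rep("G1", 5), rep("G2M", 5))), "G2M")
    expect_equal(dominantPhase(c("UNKNOWN", "UNKNOWN")), "UNKNOWN")
    expect_equal(dominantPhase(c("UNKNOWN", "S", "UNKNOWN")), "S")
})

test_that("rankAndRatio orders by CHA and reports set ratios", {
    met <- data.frame(cell_id = 1:100, cha_um2 = 1:100,
                      dominant_phase = c(rep("G1", 50), rep("G2M", 50)))
    rr <- rankAndRatio(met, N = 50)
    expect_true(is.na(rr$top_ratio))        # top set all G2M: no G1
    expect_equal(rr$bottom_ratio, 0)        # bottom set all G1
    expect_false(rr$overlapping)
    expect_equal(sum(rr$top_counts), 50)
    ## small cohort: both sets are the whole cohort, flagged overlapping
    sm <- met[1:30, ]
    rs <- rankAndRatio(sm, N = 50)
    expect_equal(rs$N, 30)
    expect_true(rs$overlapping)
    expect_setequal(rs$top_ids, rs$bottom_ids)
    ## deterministic under CHA ties
    tie <- data.frame(cell_id = 1:10, cha_um2 = 5,
                      dominant_phase = rep(c("G1", "G2M"), 5))
    r1 <- rankAndRatio(tie, N = 3); r2 <- rankAndRatio(tie, N = 3)
    expect_identical(r1$top_ids, r2$top_ids)
})

test_that("infiltration percentage is a bounded area fraction", {
    mask <- matrix(FALSE, 20, 20); mask[5:14, 5:14] <- TRUE   # 100 px
    fl <- matrix(0, 20, 20)
    expect_equal(infiltrationPercentage(mask, fl, 0.5), 0)
    fl[mask] <- 1
    expect_equal(infiltrationPercentage(mask, fl, 0.5), 100)
    fl[, ] <- 0; fl[5:9, 5:14] <- 1                            # half the mask
    expect_equal(infiltrationPercentage(mask, fl, 0.5), 50)
    ## monotone in fluorescent area
    fl2 <- fl; fl2[10, 5:14] <- 1
    expect_gt(infiltrationPercentage(mask, fl2, 0.5),
              infiltrationPercentage(mask, fl, 0.5))
    expect_error(infiltrationPercentage(matrix(FALSE, 20, 20), fl, 0.5),
                 class = "metricError")
    expect_error(infiltrationPercentage(mask, matrix(0, 5, 5), 0.5),
                 class = "inputError")
})

test_that("compareGroups reproduces the pooled-variance Student's t", {
    same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t_statistic, 0)
    expect_equal(same$p_value, 1)
    const <- compareGroups(c(2, 2), c(2, 2))
    expect_equal(const$p_value, 1)
    expect_equal(compareGroups(c(1, 1), c(2, 2))$p_value, 0)
    set.seed(6)
    a <- c(0, 0, 0, 0) + rnorm(4, 0, 1e-3)
    b <- c(1, 1, 1, 1) + rnorm(4, 0, 1e-3)
    got <- compareGroups(a, b)
    orc <- studentTOracle(a, b)
    expect_equal(got$t_statistic, orc$t, tolerance = 1e-9)
    expect_equal(got$p_value, orc$p, tolerance = 1e-9)
})

test_that("migrationMetrics assembles a consistent per-cell table", {
    tr <- rbind(
        data.frame(cell_id = 1, t = 0:3, x = c(0, 3, 3, 0), y = c(0, 4, 4, 0),
                   phase = c("G1", "G1", "S", "G1")),
        data.frame(cell_id = 2, t = 0:2, x = c(10, 13, 16), y = 5,
                   phase = "G2M"))
    met <- migrationMetrics(tr, pixelSizeUm = 2)
    expect_equal(met$path_length_um[met$cell_id == 1], (5 + 0 + 5) * 2)
    expect_equal(met$net_displacement_um[met$cell_id == 1], 0)
    expect_equal(met$cha_um2[met$cell_id == 2], 0)   # collinear
    expect_equal(met$dominant_phase, c("G1", "G2M"))
    expect_true(all(met$path_length_um >= met$net_displacement_um))
})
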