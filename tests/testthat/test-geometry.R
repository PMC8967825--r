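test_that("block-mean binning reduces constant and sparse volumes exactly", {
    v <- VoxelVolume(array(7, c(4L, 4L, 4L)), c(1, 1, 1))
    b <- binVolume(v, 4L)
    expect_identical(dim(b), c(1L, 1L, 1L))
    expect_equal(intensityData(b)[1, 1, 1], 7)
    expect_equal(spacing(b), c(4, 4, 4))

    expect_identical(intensityData(binVolume(v, 1L)), intensityData(v))
    expect_identical(spacing(binVolume(v, 1L)), spacing(v))

    a <- array(0, c(8L, 8L, 8L))
    a[3, 5, 7] <- 8
    b2 <- binVolume(VoxelVolume(a, c(1, 1, 1)), 2L)
    expect_equal(intensityData(b2)[2, 3, 4], 1)   # 8 / 2^3
    expect_equal(sum(intensityData(b2) != 0), 1L)
})

test_that("binning preserves the global mean on evenly divisible axes", {
    set.seed(1)
    a <- array(runif(6 * 8 * 4), c(6L, 8L, 4L))
    b <- binVolume(VoxelVolume(a, c(1, 2, 3)), c(3L, 2L, 4L))
    expect_equal(mean(intensityData(b)), mean(a))
    ## trailing partial blocks average over the voxels they contain
    a5 <- array(seq_len(5), c(5L, 1L, 1L))
    b5 <- binVolume(VoxelVolume(a5, c(1, 1, 1)), c(2L, 1L, 1L))
    expect_equal(as.numeric(intensityData(b5)), c(1.5, 3.5, 5))
})

test_that("binning rejects factors larger than the axis", {
    v <- VoxelVolume(array(0, c(4L, 4L, 4L)), c(1, 1, 1))
    expect_error(binVolume(v, c(5L, 1L, 1L)), "exceeds")
})

test_that("adaptive binarization follows the local-mean threshold rule", {
    v <- VoxelVolume(array(3, c(8L, 8L, 8L)), c(1, 1, 1))
    ## sensitivity 0.5 -> c = 1: constant volume is all ties -> foreground
    expect_true(all(intensityData(adaptiveBinarize(v, 0.5, c(3L, 3L, 3L)))))
    ## sensitivity 0.4 -> c = 1.2: constant I < 1.2 I -> background
    expect_false(any(intensityData(adaptiveBinarize(v, 0.4, c(3L, 3L, 3L)))))
})

test_that("adaptive binarization matches a brute-force local-mean oracle", {
    set.seed(42)
    ## 10/23 two-level data admit no exact threshold ties at these
    ## sensitivities, so the oracle comparison is unambiguous
    a <- array(sample(c(10, 23), 9 * 8 * 7, replace = TRUE), c(9L, 8L, 7L))
    v <- VoxelVolume(a, c(1, 1, 1))
    for (sens in c(0.4, 0.55)) {
        got <- intensityData(adaptiveBinarize(v, sens, c(3L, 5L, 3L)))
        want <- a >= 2 * (1 - sens) * bruteLocalMean(a, c(3L, 5L, 3L))
        expect_identical(got, want)
    }
})

test_that("the foreground set grows monotonically with sensitivity", {
    set.seed(11)
    a <- array(rpois(16^3, 20), c(16L, 16L, 16L))
    v <- VoxelVolume(a, c(1, 1, 1))
    prev <- intensityData(adaptiveBinarize(v, 0.2))
    for (s in c(0.4, 0.6, 0.8, 1)) {
        cur <- intensityData(adaptiveBinarize(v, s))
        expect_true(all(cur[prev]))   # prev foreground stays foreground
        prev <- cur
    }
})

test_that("binarization rejects invalid windows", {
    v <- VoxelVolume(array(1, c(8L, 8L, 8L)), c(1, 1, 1))
    expect_error(adaptiveBinarize(v, 0.4, c(4L, 3L, 3L)), "odd")
    expect_error(adaptiveBinarize(v, 0.4, c(9L, 3L, 3L)), "axis length")
})

test_that("surface extraction returns boundary voxels of the largest component", {
    m <- array(FALSE, c(9L, 9L, 9L))
    m[3:7, 3:7, 3:7] <- TRUE            # solid 5^3 cube
    pc <- extractSurface(new("BinaryMask", data = m, spacing = c(1, 1, 1)))
    expect_identical(nPoints(pc), 98L)  # 5^3 - 3^3

    m1 <- array(FALSE, c(5L, 5L, 5L))
    m1[3, 4, 2] <- TRUE
    pc1 <- extractSurface(new("BinaryMask", data = m1, spacing = c(2, 3, 4)))
    expect_equal(surfacePoints(pc1), cbind(4, 9, 4), ignore_attr = TRUE)

    ## two components: only the larger one contributes
    m2 <- array(FALSE, c(12L, 12L, 12L))
    m2[2:6, 2:6, 2:6] <- TRUE           # 125 voxels
    m2[10, 10, 10] <- TRUE              # far-away singleton
    pc2 <- extractSurface(new("BinaryMask", data = m2, spacing = c(1, 1, 1)))
    expect_identical(nPoints(pc2), 98L)
    expect_false(any(surfacePoints(pc2)[, 1] == 9))
})

test_that("surface extraction requires foreground", {
    m <- new("BinaryMask", data = array(FALSE, c(4L, 4L, 4L)),
             spacing = c(1, 1, 1))
    expect_error(extractSurface(m), "no foreground")
})

test_that("the algebraic sphere fit is exact on noiseless samples", {
    ctr <- c(10, -5, 2.5)
    pts <- rbind(ctr + c(30, 0, 0), ctr - c(30, 0, 0),
                 ctr + c(0, 30, 0), ctr - c(0, 30, 0),
                 ctr + c(0, 0, 30), ctr - c(0, 0, 30))
    s <- fitSphere(pts)
    expect_lt(max(abs(sphereCenter(s) - ctr)), 1e-9)
    expect_lt(abs(sphereRadius(s) - 30), 1e-9)
    expect_lt(rmsResidual(s), 1e-9)

    ## translation equivariance
    s2 <- fitSphere(sweep(pts, 2L, c(100, 200, -50), `+`))
    expect_equal(sphereCenter(s2), ctr + c(100, 200, -50), tolerance = 1e-9)
    expect_equal(sphereRadius(s2), sphereRadius(s), tolerance = 1e-12)
})

test_that("the sphere fit rejects degenerate point sets", {
    expect_error(fitSphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
                 "at least 4")
    coplanar <- cbind(runif(10), runif(10), 5)
    expect_error(fitSphere(coplanar), "coplanar|degenerate")
})

test_that("the sphere fit recovers noisy spheres to sub-voxel accuracy", {
    set.seed(99)
    errs <- replicate(20, {
        z <- runif(500, -1, 1); th <- runif(500, 0, 2 * pi)
        s <- sqrt(1 - z^2)
        pts <- 300 * cbind(z, s * sin(th), s * cos(th)) +
            matrix(rnorm(1500, 0, 0.5), ncol = 3)
        pts <- sweep(pts, 2L, c(10, 20, 30), `+`)
        f <- fitSphere(pts)
        c(sqrt(sum((sphereCenter(f) - c(10, 20, 30))^2)),
          abs(sphereRadius(f) - 300))
    })
    expect_lt(max(errs[1, ]), 0.2)
    expect_lt(max(errs[2, ]), 0.2)
})
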