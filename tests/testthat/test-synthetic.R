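test_that("a spec without sources renders a constant background", {
    spec <- EmbryoSpec(volumeShape = c(32L, 32L, 32L), voxelSpacing = c(2, 2, 2),
                       sphereRadius = 15, nCells = 0L, yolkAmplitude = 0,
                       background = 5, noiseModel = "none")
    sim <- generateVolume(spec)
    expect_true(all(intensityData(sim$volume) == 5))
    expect_identical(nrow(cellPositions(sim$truth)), 0L)
    expect_identical(trueCounts(sim$truth), c(whole = 0L))
})

test_that("ground-truth cells sit exactly on the requested shell", {
    for (off in c(-6, 0, 4)) {
        spec <- EmbryoSpec(nCells = 40L, shellOffset = off,
                           noiseModel = "none", seed = 5L)
        sim <- generateVolume(spec)
        pts <- cellPositions(sim$truth)
        r <- sqrt(rowSums(sweep(pts, 2L, sphereCenter(sim$truth))^2))
        expect_lt(max(abs(r - (100 + off))), 1e-6)
        ## lat/lon is consistent with the cartesian positions
        ll <- cellLatLon(sim$truth)
        back <- latlonToCartesian(ll[, 1], ll[, 2], 100 + off,
                                  sphereModel(sphereCenter(sim$truth), 100))
        expect_lt(max(abs(back - pts)), 1e-6)
    }
})

test_that("pairwise cell separations respect the spec minimum", {
    for (seed in c(2L, 9L)) {
        sim <- generateVolume(EmbryoSpec(nCells = 150L, seed = seed,
                                         noiseModel = "none"))
        d <- dist(cellPositions(sim$truth))
        expect_gte(min(d), 12)
    }
})

test_that("identical specs generate bit-identical volumes and truth", {
    spec <- EmbryoSpec(nCells = 200L, seed = 7L)
    a <- generateVolume(spec)
    b <- generateVolume(spec)
    expect_identical(intensityData(a$volume), intensityData(b$volume))
    expect_identical(cellPositions(a$truth), cellPositions(b$truth))
})

test_that("noiseless total intensity matches the analytic Gaussian mass", {
    spec <- EmbryoSpec(nCells = 50L, background = 2, noiseModel = "none",
                       seed = 4L)
    sim <- generateVolume(spec)
    voxvol <- prod(spacing(sim$volume))
    measured <- sum(intensityData(sim$volume) - 2) * voxvol
    expected <- 50 * 110 * (2 * pi)^1.5 * 3^3
    expect_lt(abs(measured - expected) / expected, 0.01)
})

test_that("an overcrowded shell fails with the achievable density", {
    spec0 <- EmbryoSpec(volumeShape = c(64L, 64L, 64L), sphereRadius = 40,
                        nCells = 500L)
    expect_error(generateVolume(spec0), "shell too crowded.*roughly [0-9]+")
})

test_that("time courses scale true counts by the growth multipliers", {
    base <- EmbryoSpec(volumeShape = c(64L, 64L, 64L), sphereRadius = 40,
                       nCells = 20L, noiseModel = "none")
    tc <- TimeCourseSpec(base, c("1dpf", "2dpf", "3dpf"),
                         controlMultipliers = c(1, 2, 3),
                         perturbedMultipliers = c(1, 1, 1))
    recs <- generateTimecourse(tc)
    expect_length(recs, 6L)
    ctrl <- Filter(function(r) r$condition == "control", recs)
    pert <- Filter(function(r) r$condition == "perturbed", recs)
    expect_identical(vapply(ctrl, function(r) trueCounts(r$truth)[["whole"]],
                            integer(1)), c(20L, 40L, 60L))
    expect_identical(vapply(pert, function(r) trueCounts(r$truth)[["whole"]],
                            integer(1)), c(20L, 20L, 20L))
    ## per-timepoint streams are deterministic and distinct
    recs2 <- generateTimecourse(tc)
    expect_identical(cellPositions(recs[[3]]$truth),
                     cellPositions(recs2[[3]]$truth))
    expect_false(identical(cellPositions(recs[[1]]$truth),
                           cellPositions(recs[[2]]$truth)))
})

test_that("an empty timepoint list gives an empty time course", {
    tc <- TimeCourseSpec(EmbryoSpec(nCells = 5L), character(0),
                         numeric(0), numeric(0))
    expect_identical(generateTimecourse(tc), list())
})

test_that("fixtures round-trip volumes, spacing and counts", {
    dir <- withr::local_tempdir()
    spec <- EmbryoSpec(volumeShape = c(48L, 96L, 96L),
                       voxelSpacing = c(2, 0.5, 0.5),
                       sphereCenter = c(47, 23.75, 23.75), sphereRadius = 12,
                       cellSigma = 1.5, nCells = 10L,
                       minCellSeparation = 4, noiseModel = "poisson",
                       seed = 3L)
    sim <- generateVolume(spec, rois = list(
        ROIBox("upper", lo = c(0, 0, 0), hi = c(47, 47.5, 47.5))))
    writeFixture(sim$volume, sim$truth, dir)
    back <- readFixture(dir)
    ## poisson-noise volumes are integer-valued, hence exactly representable
    expect_identical(intensityData(back$volumes$embryo),
                     intensityData(sim$volume))
    expect_identical(spacing(back$volumes$embryo), c(2, 0.5, 0.5))
    expect_identical(trueCounts(back$truths$embryo),
                     trueCounts(sim$truth))
    expect_equal(cellPositions(back$truths$embryo),
                 cellPositions(sim$truth))
})
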