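test_that("baseline subtraction removes constants and bounds the output", {
    v <- VoxelVolume(array(42, c(16L, 16L, 16L)), c(2, 2, 2))
    out <- subtractBaseline(v, 10)
    expect_lt(max(intensityData(out)), 1e-9)

    set.seed(6)
    r <- VoxelVolume(array(rpois(16^3, 30), c(16L, 16L, 16L)), c(2, 2, 2))
    sub <- intensityData(subtractBaseline(r, 10))
    expect_true(all(sub >= 0))
    expect_true(all(sub <= intensityData(r)))
})

test_that("a broad baseline barely attenuates an isolated blob", {
    a <- array(0, c(33L, 33L, 33L))
    v0 <- VoxelVolume(a, c(1, 1, 1))
    b <- SphereMap:::.blob_patch(dim(a), c(1, 1, 1), c(16, 16, 16), 3, 100)
    a[b$rng[[1]], b$rng[[2]], b$rng[[3]]] <- b$patch
    v <- VoxelVolume(a, c(1, 1, 1))
    sub <- subtractBaseline(v, 15)
    expect_gt(max(intensityData(sub)), 0.9 * max(a))
})

test_that("sub-voxel baseline scales warn instead of failing", {
    v <- VoxelVolume(array(1, c(8L, 8L, 8L)), c(2, 2, 2))
    expect_warning(subtractBaseline(v, 0.5), "below one voxel")
})

test_that("spot detection is empty on empty volumes and exact without noise", {
    z <- VoxelVolume(array(0, c(32L, 32L, 32L)), c(2, 2, 2))
    expect_length(detectSpots(z, SpotParams()), 0L)

    sim <- generateVolume(EmbryoSpec(nCells = 200L, noiseModel = "none",
                                     seed = 12L))
    det <- detectSpots(sim$volume, SpotParams())
    expect_length(det, 200L)
    ## every centroid within one voxel (2 um) of its true cell
    d2 <- outer(rowSums(spotCentroids(det)^2),
                rowSums(cellPositions(sim$truth)^2), `+`) -
        2 * spotCentroids(det) %*% t(cellPositions(sim$truth))
    expect_lt(sqrt(max(apply(d2, 2L, min))), 2)
})

test_that("adding one well-separated cell adds exactly one detection", {
    s50 <- generateVolume(EmbryoSpec(nCells = 50L, noiseModel = "none",
                                     seed = 31L))
    s51 <- generateVolume(EmbryoSpec(nCells = 51L, noiseModel = "none",
                                     seed = 31L))
    ## the rejection stream is shared, so the first 50 cells coincide
    expect_identical(cellPositions(s50$truth),
                     cellPositions(s51$truth)[1:50, ])
    n50 <- length(detectSpots(s50$volume, SpotParams()))
    n51 <- length(detectSpots(s51$volume, SpotParams()))
    expect_identical(n51, n50 + 1L)
})

test_that("detected counts are non-increasing in the threshold", {
    sim <- generateVolume(EmbryoSpec(nCells = 100L, seed = 17L))
    counts <- vapply(c(5, 15, 25, 50, 90, 120), function(thr)
        length(detectSpots(sim$volume, SpotParams(detectionThreshold = thr))),
        integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("ROI counting honours the inclusive-lo/exclusive-hi rule", {
    s <- new("SpotSet",
        centroids = rbind(c(5, 5, 10), c(5, 5, 20)),
        peakIntensities = c(1, 2), minSeparation = 0)
    expect_identical(countInROI(s, ROIBox("all", c(0, 0, 0),
                                          c(100, 100, 100))), 2L)
    expect_identical(countInROI(s, ROIBox("slab", c(0, 0, 15),
                                          c(100, 100, 25))), 1L)
    ## a spot exactly on the upper bound is excluded, on the lower included
    expect_identical(countInROI(s, ROIBox("edge", c(0, 0, 10),
                                          c(100, 100, 20))), 1L)
})

test_that("counts over a partition of space sum to the total", {
    sim <- generateVolume(EmbryoSpec(nCells = 150L, seed = 23L))
    det <- detectSpots(sim$volume, SpotParams())
    half1 <- ROIBox("left", c(-1e6, -1e6, -1e6), c(1e6, 127, 1e6))
    half2 <- ROIBox("right", c(-1e6, 127, -1e6), c(1e6, 1e6, 1e6))
    expect_identical(countInROI(det, half1) + countInROI(det, half2),
                     length(det))
})

test_that("time-course quantification reproduces ground truth exactly", {
    base <- EmbryoSpec(volumeShape = c(64L, 64L, 64L), sphereRadius = 40,
                       nCells = 20L, noiseModel = "none")
    tc <- TimeCourseSpec(base, c("1dpf", "2dpf", "3dpf"),
                         controlMultipliers = c(1, 2, 3),
                         perturbedMultipliers = c(1, 1, 1))
    recs <- generateTimecourse(tc)
    tab <- quantifyTimecourse(recs, SpotParams())
    whole <- tab[tab$roi == "whole", ]
    ctrl <- whole$count[whole$condition == "control"]
    pert <- whole$count[whole$condition == "perturbed"]
    expect_identical(ctrl, c(20L, 40L, 60L))
    expect_identical(pert, c(20L, 20L, 20L))
    expect_true(all(diff(ctrl) > 0))
    expect_true(all(diff(ctrl - pert) > 0))   # gap widens over time
})

test_that("quantification includes named ROIs and flags label collisions", {
    sim <- generateVolume(EmbryoSpec(volumeShape = c(64L, 64L, 64L),
                                     sphereRadius = 40, nCells = 15L,
                                     noiseModel = "none", seed = 2L))
    rec <- list(volume = sim$volume, timepoint = "1dpf",
                condition = "control", embryo_id = "e1")
    trunk <- ROIBox("trunk", c(0, 0, 0), c(126, 126, 63))
    tab <- quantifyTimecourse(list(rec), SpotParams(), list(trunk))
    expect_setequal(tab$roi, c("whole", "trunk"))
    expect_lte(tab$count[tab$roi == "trunk"], tab$count[tab$roi == "whole"])
    expect_error(quantifyTimecourse(list(rec, rec), SpotParams()),
                 "duplicate")
    empty <- quantifyTimecourse(list(), SpotParams())
    expect_identical(nrow(empty), 0L)
    expect_identical(names(empty),
                     c("embryo_id", "condition", "timepoint", "roi", "count"))
})
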