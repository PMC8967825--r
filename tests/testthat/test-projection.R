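test_that("the Mercator ordinate matches its closed form and symmetry", {
    expect_equal(mercatorY(0, 5), 0, tolerance = 1e-12)
    ## ln(tan 75 deg), frozen from a 30-digit evaluation
    expect_equal(mercatorY(60, 1), 1.31695789692481670862504634731,
                 tolerance = 1e-9)
    phis <- c(5, 17.3, 45, 71, 89)
    expect_equal(mercatorY(-phis, 2), -mercatorY(phis, 2), tolerance = 1e-12)
    expect_error(mercatorY(90, 1), "singular")
    ## exact inverse
    expect_equal(inverseMercatorY(mercatorY(phis, 7), 7), phis,
                 tolerance = 1e-9)
})

test_that("grids place rows uniformly in Mercator y and columns in longitude", {
    g <- makeGrid(R = 100, nRows = 11, nCols = 4)
    expect_equal(gridLongitudes(g), c(45, 135, 225, 315))
    expect_equal(gridLatitudes(g)[6], 0, tolerance = 1e-12)   # odd -> equator
    expect_equal(gridLatitudes(g), -rev(gridLatitudes(g)), tolerance = 1e-9)
    y <- mercatorY(gridLatitudes(g), 100)
    expect_equal(diff(y), rep(diff(y)[1], 10), tolerance = 1e-9)

    ge <- makeGrid(R = 100, nRows = 9, nCols = 8, truncationLat = 90,
                   mode = "equirect")
    expect_equal(diff(gridLatitudes(ge)), rep(-20, 8), tolerance = 1e-12)
    expect_error(makeGrid(R = 100, nRows = 4, nCols = 4, truncationLat = 90),
                 "pole|diverges")
})

test_that("spherical/cartesian conversion matches its definition and inverts", {
    sp <- sphereModel(c(0, 0, 0), 50)
    expect_equal(latlonToCartesian(0, 0, 50, sp), cbind(z = 0, y = 0, x = 50),
                 tolerance = 1e-12)
    expect_equal(as.numeric(latlonToCartesian(90, 123, 50, sp)), c(50, 0, 0),
                 tolerance = 1e-9)
    set.seed(2)
    ll <- cbind(runif(50, -89, 89), runif(50, 0, 360))
    pts <- latlonToCartesian(ll[, 1], ll[, 2], 80, sp)
    back <- cartesianToLatlon(pts, sp)
    expect_equal(back[, "latitude"], ll[, 1], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(back[, "longitude"], ll[, 2], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(back[, "radius"], rep(80, 50), tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("volume sampling interpolates physically and fills outside", {
    a <- array(0, c(3L, 3L, 3L))
    a[2, 2, 2] <- 10
    a[2, 2, 3] <- 20
    v <- VoxelVolume(a, c(2, 2, 2))
    ## voxel centres hit exactly under both samplers
    expect_equal(sampleVolume(v, c(2, 2, 2)), 10)
    expect_equal(sampleVolume(v, c(2, 2, 2), sampler = "nearest"), 10)
    ## midpoint between centres of 10 and 20 -> 15
    expect_equal(sampleVolume(v, c(2, 2, 3)), 15)
    ## out of bounds -> fill, never an error
    expect_equal(sampleVolume(v, c(-1, 0, 0), fill = -7), -7)
    expect_equal(sampleVolume(v, c(0, 0, 4.01), fill = NA_real_), NA_real_)
})

test_that("a uniform shell projects to a uniform map away from truncation", {
    sh <- shellPhantom()                      # R = 100, amplitude 100
    sp <- sphereModel(c(127, 127, 127), 100)
    g <- makeGrid(R = 100, pixelSize = 2)
    img <- projectLayer(sh, sp, 0, g)
    core <- img[3:(nrow(img) - 2), ]
    expect_gt(min(core), 99)
    expect_lt(max(core), 101)
    ## a volume of zeros projects to zeros
    z <- VoxelVolume(array(0, c(16L, 16L, 16L)), c(16, 16, 16))
    expect_true(all(projectLayer(z, sp, 0, g) == 0))
})

test_that("a single cell projects to a peak at its true map position", {
    spec <- EmbryoSpec(nCells = 1L, noiseModel = "none", seed = 21L)
    sim <- generateVolume(spec)
    sp <- sphereModel(sphereCenter(sim$truth), 100)
    g <- makeGrid(R = 100, pixelSize = 2)
    img <- projectLayer(sim$volume, sp, 0, g)
    peak <- which(img == max(img), arr.ind = TRUE)[1, ]
    ll <- cellLatLon(sim$truth)
    i_true <- which.min(abs(gridLatitudes(g) - ll[1, 1]))
    j_true <- which.min(abs(gridLongitudes(g) - ll[1, 2]))
    expect_lte(abs(peak[1] - i_true), 1)
    expect_lte(abs(peak[2] - j_true), 1)
})

test_that("multi-layer stacks localize the cell shell radially", {
    spec <- EmbryoSpec(shellOffset = -4, noiseModel = "none", seed = 3L)
    sim <- generateVolume(spec)
    sp <- sphereModel(sphereCenter(sim$truth), 100)
    g <- makeGrid(R = 100, pixelSize = 2)
    st <- projectMultilayer(sim$volume, sp, layerOffsets(2, 10, 10), g)
    expect_length(mapLayers(st), 11L)
    best <- layerOffsetsOf(st)[which.max(vapply(mapLayers(st), sum,
                                                numeric(1)))]
    expect_equal(best, -4)
    ## a single-offset stack reproduces projectLayer exactly
    st1 <- projectMultilayer(sim$volume, sp, 0, g)
    expect_identical(mapLayers(st1)[[1]], projectLayer(sim$volume, sp, 0, g))
    ## the default layer spec spans 10 um inward at 2 um steps -> 6 layers
    expect_length(layerOffsets(step = 2, depthInward = 10), 6L)
    expect_error(projectMultilayer(sim$volume, sp, -150, g), "-150")
})

test_that("the cross-layer maximum dominates every layer", {
    spec <- EmbryoSpec(volumeShape = c(64L, 64L, 64L), sphereRadius = 40,
                       nCells = 30L, noiseModel = "none", seed = 8L)
    sim <- generateVolume(spec)
    sp <- sphereModel(sphereCenter(sim$truth), 40)
    g <- makeGrid(R = 40, pixelSize = 2)
    st <- projectMultilayer(sim$volume, sp, c(-4, -2, 0), g)
    mp <- maxProjectLayers(st)
    for (L in mapLayers(st)) expect_true(all(mp >= L))
    st1 <- projectMultilayer(sim$volume, sp, 0, g)
    expect_identical(maxProjectLayers(st1), mapLayers(st1)[[1]])
    expect_error(maxProjectLayers(
        new("MapLayerStack", offsets = numeric(0), layers = list(),
            grid = g, sphere = sp, sampler = "trilinear", fillValue = 0)),
        "empty")
})

test_that("small geodesic discs project conformally with sec(lat) scaling", {
    sp <- sphereModel(c(127, 127, 127), 100)
    g <- makeGrid(R = 100, pixelSize = 1)
    sizes <- numeric(3)
    lats <- c(0, 30, 60)
    for (k in seq_along(lats)) {
        dv <- discPhantom(discLat = lats[k], discLon = 180,
                          geodesicSigma = 4, radialSigma = 4)
        mom <- blobMoments(projectLayer(dv, sp, 0, g))
        expect_lt(abs(mom$aspect - 1), 0.05)
        sizes[k] <- mom$size
    }
    expect_lt(abs(sizes[2] / sizes[1] - 1 / cos(pi / 6)) * cos(pi / 6), 0.05)
    expect_lt(abs(sizes[3] / sizes[1] - 2) / 2, 0.05)
})

test_that("discs straddling the longitude seam conserve their intensity", {
    sp <- sphereModel(c(127, 127, 127), 100)
    g <- makeGrid(R = 100, pixelSize = 2)
    on_seam <- projectLayer(discPhantom(discLat = 0, discLon = 0,
                                        geodesicSigma = 4, radialSigma = 4),
                            sp, 0, g)
    off_seam <- projectLayer(discPhantom(discLat = 0, discLon = 180,
                                         geodesicSigma = 4, radialSigma = 4),
                             sp, 0, g)
    expect_lt(abs(sum(on_seam) / sum(off_seam) - 1), 0.01)
})

test_that("equatorial arc length per map column matches 2 pi R / nCols", {
    sp <- sphereModel(c(127, 127, 127), 100)
    g <- makeGrid(R = 100, pixelSize = 2)
    nc <- dim(g)[2]
    a <- intensityData(discPhantom(discLat = 0, discLon = 90,
                                   geodesicSigma = 3, radialSigma = 4))
    b <- intensityData(discPhantom(discLat = 0, discLon = 120,
                                   geodesicSigma = 3, radialSigma = 4))
    v <- VoxelVolume(a + b, c(2, 2, 2))
    img <- projectLayer(v, sp, 0, g)
    eq_row <- which.min(abs(gridLatitudes(g)))
    prof <- img[eq_row, ]
    p1 <- which.max(prof)
    prof2 <- prof
    win <- ((p1 - 10):(p1 + 10) - 1) %% nc + 1
    prof2[win] <- -Inf
    p2 <- which.max(prof2)
    sep_cols <- abs(p2 - p1)
    expect_lte(abs(sep_cols - 30 / 360 * nc), 1)
})
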