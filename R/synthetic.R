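#' Specify a synthetic spherical embryo
#'
#' Builds an [EmbryoSpec-class] describing one simulated light-sheet volume:
#' an approximately spherical embryo whose labelled cells sit on a concentric
#' shell, with optional interior (yolk) autofluorescence and a standard
#' camera noise model (Poisson shot noise on signal plus background via a
#' gain, then additive Gaussian read noise).
#'
#' Defaults describe the canonical small test embryo used throughout the
#' package: a 128^3 volume at 2 um isotropic spacing holding a 100 um-radius
#' embryo with 200 surface cells of blob sigma 3 um and peak amplitude 110
#' over a background of 10 (peak SNR ~ 10 under the default noise model).
#' The minimum cell separation of 12 um (= 4 cell sigma) is the regime in
#' which spot counting is exact at zero noise.
#'
#' @param volumeShape integer(3) voxels (planes, rows, cols).
#' @param voxelSpacing numeric(3) um (z, y, x).
#' @param sphereCenter numeric(3) um; default = centre of the volume.
#' @param sphereRadius um.
#' @param shellOffset signed radial position of the cell layer relative to
#'   the sphere surface, um.
#' @param nCells number of cells.
#' @param cellSigma Gaussian blob width, um (isotropic in physical space).
#' @param cellAmplitude blob peak intensity.
#' @param yolkAmplitude interior autofluorescence amplitude (0 = none).
#' @param background constant background intensity.
#' @param noiseModel one of \code{"none"}, \code{"gaussian"},
#'   \code{"poisson"}, \code{"poisson+gaussian"}.
#' @param gain intensity units per photon for the Poisson stage.
#' @param readSd Gaussian read-noise standard deviation, intensity units.
#' @param minCellSeparation pairwise minimum distance between cells, um.
#' @param seed PRNG seed.
#' @return An [EmbryoSpec-class].
#' @examples
#' spec <- EmbryoSpec(nCells = 50L, noiseModel = "none")
#' sim <- generateVolume(spec)
#' sim$volume
#' @export
EmbryoSpec <- function(volumeShape = c(128L, 128L, 128L),
                       voxelSpacing = c(2, 2, 2),
                       sphereCenter = (volumeShape - 1) * voxelSpacing / 2,
                       sphereRadius = 100,
                       shellOffset = 0,
                       nCells = 200L,
                       cellSigma = 3,
                       cellAmplitude = 110,
                       yolkAmplitude = 0,
                       background = 10,
                       noiseModel = "poisson+gaussian",
                       gain = 1,
                       readSd = 2,
                       minCellSeparation = 12,
                       seed = 1L) {
    new("EmbryoSpec",
        volumeShape = as.integer(volumeShape),
        voxelSpacing = as.numeric(voxelSpacing),
        sphereCenter = as.numeric(sphereCenter),
        sphereRadius = as.numeric(sphereRadius),
        shellOffset = as.numeric(shellOffset),
        nCells = as.integer(nCells),
        cellSigma = as.numeric(cellSigma),
        cellAmplitude = as.numeric(cellAmplitude),
        yolkAmplitude = as.numeric(yolkAmplitude),
        background = as.numeric(background),
        noiseModel = noiseModel,
        noiseParams = list(gain = as.numeric(gain), readSd = as.numeric(readSd)),
        minCellSeparation = as.numeric(minCellSeparation),
        seed = as.integer(seed))
}

#' Blob amplitude reaching a prescribed peak signal-to-noise ratio
#'
#' Under the camera model (Poisson on (signal + background) / gain scaled
#' back by the gain, plus Gaussian read noise of sd \code{readSd}), the peak
#' SNR of a blob of amplitude A over background B is
#' A / sqrt(gain (A + B) + readSd^2). This solves that relation for A.
#'
#' @param snr target peak signal-to-noise ratio.
#' @param background background intensity.
#' @param gain intensity units per photon.
#' @param readSd read-noise sd, intensity units.
#' @return The amplitude A (intensity units).
#' @examples
#' amplitudeForPeakSNR(10, background = 10, gain = 1, readSd = 2)
#' @export
amplitudeForPeakSNR <- function(snr, background, gain = 1, readSd = 0) {
    (snr^2 * gain +
        sqrt(snr^4 * gain^2 + 4 * snr^2 * (gain * background + readSd^2))) / 2
}

## uniform points on the shell of radius r around center, with pairwise
## separation >= minsep, by rejection sampling; budget = 200 draws per cell
.sample_shell <- function(n, center, r, minsep, budget = max(1000L, 200L * n)) {
    pts <- matrix(numeric(0), 0L, 3L)
    if (n == 0L) return(pts)
    attempts <- 0L
    minsep2 <- minsep^2
    while (nrow(pts) < n && attempts < budget) {
        attempts <- attempts + 1L
        z <- runif(1L, -1, 1)
        th <- runif(1L, 0, 2 * pi)
        s <- sqrt(1 - z^2)
        cand <- center + r * c(z, s * sin(th), s * cos(th))
        if (nrow(pts)) {
            d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 +
                (pts[, 3] - cand[3])^2
            if (min(d2) < minsep2) next
        }
        pts <- rbind(pts, cand)
    }
    if (nrow(pts) < n) {
        area_cell <- sqrt(3) / 2 * minsep^2
        capacity <- floor(0.547 * 4 * pi * r^2 / area_cell)
        .stopf(paste0(
            "shell too crowded: placed %d of %d cells after %d attempts ",
            "(separation %g um on a %g um shell supports roughly %d cells)"),
            nrow(pts), n, attempts, minsep, r, capacity)
    }
    dimnames(pts) <- NULL
    pts
}

## isotropic-in-um Gaussian blob at p (z,y,x um), evaluated analytically
## on the anisotropic voxel grid within +/- 4 sigma; returns the voxel
## ranges and the additive patch (the caller does the subassignment so the
## large volume array is modified in place, not copied per cell)
.blob_patch <- function(d, spacing, p, sigma, amplitude) {
    rng <- lapply(1:3, function(ax) {
        lo <- max(1L, as.integer(floor((p[ax] - 4 * sigma) / spacing[ax])) + 1L)
        hi <- min(d[ax],
                  as.integer(ceiling((p[ax] + 4 * sigma) / spacing[ax])) + 1L)
        lo:hi
    })
    dz2 <- ((rng[[1]] - 1) * spacing[1] - p[1])^2
    dy2 <- ((rng[[2]] - 1) * spacing[2] - p[2])^2
    dx2 <- ((rng[[3]] - 1) * spacing[3] - p[3])^2
    q <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    list(rng = rng, patch = amplitude * exp(-q / (2 * sigma^2)))
}

## squared distance of every voxel centre to 'center' (um)
.radius2_array <- function(d, spacing, center) {
    dz2 <- ((seq_len(d[1]) - 1) * spacing[1] - center[1])^2
    dy2 <- ((seq_len(d[2]) - 1) * spacing[2] - center[2])^2
    dx2 <- ((seq_len(d[3]) - 1) * spacing[3] - center[3])^2
    outer(outer(dz2, dy2, `+`), dx2, `+`)
}

.apply_noise <- function(a, model, params) {
    if (model == "none") return(a)
    n <- length(a)
    if (model %in% c("poisson", "poisson+gaussian")) {
        gain <- params$gain
        a <- gain * rpois(n, a / gain)
    }
    if (model %in% c("gaussian", "poisson+gaussian")) {
        a <- a + rnorm(n, 0, params$readSd)
    }
    a
}

.latlon_of <- function(pts, center, r) {
    dz <- pts[, 1] - center[1]
    dy <- pts[, 2] - center[2]
    dx <- pts[, 3] - center[3]
    lat <- asin(pmin(1, pmax(-1, dz / r))) * 180 / pi
    lon <- (atan2(dy, dx) * 180 / pi) %% 360
    cbind(latitude = lat, longitude = lon)
}

.in_box <- function(pts, lo, hi) {
    pts[, 1] >= lo[1] & pts[, 1] < hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] < hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] < hi[3]
}

.roi_counts <- function(pts, rois) {
    counts <- c(whole = nrow(pts))
    for (roi in rois)
        counts[roi@name] <- if (nrow(pts))
            sum(.in_box(pts, roi@lo, roi@hi)) else 0L
    vapply(counts, as.integer, integer(1))
}

#' Generate a synthetic embryo volume with exact ground truth
#'
#' Renders the embryo described by an [EmbryoSpec-class]: cells are placed
#' uniformly at random on the shell at radius
#' \code{sphereRadius + shellOffset} with the requested pairwise separation
#' (rejection sampling; an error names the achievable density when the shell
#' is too crowded), each cell is an analytically evaluated Gaussian blob
#' isotropic in um, the optional yolk fills the sphere interior with a soft
#' (cell-sigma) edge, and camera noise is applied last. The whole simulation
#' is a deterministic function of the spec (seeded PRNG), so identical specs
#' give bit-identical volumes. Intensities are clipped at zero after read
#' noise so volumes remain valid non-negative [VoxelVolume-class] objects.
#'
#' @param spec an [EmbryoSpec-class].
#' @param rois optional list of [ROIBox-class]; true per-ROI counts are
#'   recorded in the ground truth (a \code{"whole"} count is always present).
#' @param timepoint optional label attached to the volume.
#' @return \code{list(volume = VoxelVolume, truth = GroundTruth)}.
#' @examples
#' sim <- generateVolume(EmbryoSpec(nCells = 5L, noiseModel = "none"))
#' trueCounts(sim$truth)
#' @export
generateVolume <- function(spec, rois = list(), timepoint = NA_character_) {
    validObject(spec)
    set.seed(spec@seed)
    d <- spec@volumeShape
    sp <- spec@voxelSpacing
    r_shell <- spec@sphereRadius + spec@shellOffset

    pts <- .sample_shell(spec@nCells, spec@sphereCenter, r_shell,
                         spec@minCellSeparation)

    vol <- array(spec@background, dim = d)
    if (spec@yolkAmplitude > 0) {
        r <- sqrt(.radius2_array(d, sp, spec@sphereCenter))
        edge <- exp(-pmax(0, r - spec@sphereRadius)^2 /
                    (2 * spec@cellSigma^2))
        vol <- vol + spec@yolkAmplitude * edge
    }
    for (i in seq_len(nrow(pts))) {
        b <- .blob_patch(d, sp, pts[i, ], spec@cellSigma, spec@cellAmplitude)
        vol[b$rng[[1]], b$rng[[2]], b$rng[[3]]] <-
            vol[b$rng[[1]], b$rng[[2]], b$rng[[3]]] + b$patch
    }
    vol <- array(.apply_noise(vol, spec@noiseModel, spec@noiseParams), dim = d)
    vol[vol < 0] <- 0

    truth <- new("GroundTruth",
        sphereCenter = spec@sphereCenter, sphereRadius = spec@sphereRadius,
        shellOffset = spec@shellOffset, cellPositions = pts,
        cellLatLon = .latlon_of(pts, spec@sphereCenter, r_shell),
        roiCounts = .roi_counts(pts, rois))
    list(volume = VoxelVolume(vol, sp, timepoint), truth = truth)
}

#' Specify a two-condition synthetic time course
#'
#' @param base an [EmbryoSpec-class]; per-timepoint cell counts are
#'   \code{round(nCells(base) * multiplier)}.
#' @param timepoints labels (e.g. \code{c("1dpf", "2dpf", "3dpf")}).
#' @param controlMultipliers,perturbedMultipliers positive per-timepoint
#'   growth multipliers; the control series must be non-decreasing.
#' @return A [TimeCourseSpec-class].
#' @export
TimeCourseSpec <- function(base = EmbryoSpec(),
                           timepoints = c("1dpf", "2dpf", "3dpf"),
                           controlMultipliers = c(1, 2, 3),
                           perturbedMultipliers = c(1, 1, 1)) {
    new("TimeCourseSpec", base = base, timepoints = as.character(timepoints),
        controlMultipliers = as.numeric(controlMultipliers),
        perturbedMultipliers = as.numeric(perturbedMultipliers))
}

#' Generate a synthetic two-condition time course
#'
#' One volume per (timepoint, condition) pair. Each volume gets its own PRNG
#' stream derived deterministically from the base seed and the (timepoint,
#' condition) labels, so the whole course is reproducible and individual
#' volumes can be regenerated independently. The default multipliers emulate
#' the qualitative wildtype-versus-morphant pattern: the control population
#' grows across days while the perturbed one fails to keep pace.
#'
#' @param tc a [TimeCourseSpec-class].
#' @param rois optional list of [ROIBox-class] recorded in each ground truth.
#' @return A list of records, each
#'   \code{list(timepoint, condition, embryo_id, volume, truth)}; empty
#'   timepoints give an empty list.
#' @examples
#' tc <- TimeCourseSpec(EmbryoSpec(nCells = 20L, noiseModel = "none"),
#'                      timepoints = c("1dpf", "2dpf"),
#'                      controlMultipliers = c(1, 2),
#'                      perturbedMultipliers = c(1, 1))
#' length(generateTimecourse(tc))
#' @export
generateTimecourse <- function(tc, rois = list()) {
    validObject(tc)
    out <- list()
    mult <- list(control = tc@controlMultipliers,
                 perturbed = tc@perturbedMultipliers)
    for (i in seq_along(tc@timepoints)) {
        label <- tc@timepoints[i]
        for (cond in c("control", "perturbed")) {
            spec_i <- tc@base
            spec_i@nCells <- as.integer(round(tc@base@nCells * mult[[cond]][i]))
            spec_i@seed <- .derive_seed(tc@base@seed, label, cond)
            sim <- generateVolume(spec_i, rois = rois, timepoint = label)
            out[[length(out) + 1L]] <- list(
                timepoint = label, condition = cond,
                embryo_id = paste(cond, label, sep = "_"),
                volume = sim$volume, truth = sim$truth)
        }
    }
    out
}

#' Analytic spherical-shell phantom
#'
#' A noiseless volume whose intensity is a radial Gaussian shell,
#' \code{background + amplitude * exp(-(r - radius)^2 / (2 radialSigma^2))}
#' — uniform in every tangential direction. Used to calibrate projection
#' flatness and interpolation error against a closed form.
#'
#' @param volumeShape integer(3) voxels; @param voxelSpacing numeric(3) um.
#' @param center,radius sphere geometry, um.
#' @param amplitude,background intensities.
#' @param radialSigma radial Gaussian width, um.
#' @return A [VoxelVolume-class].
#' @export
shellPhantom <- function(volumeShape = c(128L, 128L, 128L),
                         voxelSpacing = c(2, 2, 2),
                         center = (volumeShape - 1) * voxelSpacing / 2,
                         radius = 100, amplitude = 100, radialSigma = 8,
                         background = 0) {
    r <- sqrt(.radius2_array(volumeShape, voxelSpacing, center))
    a <- background + amplitude * exp(-(r - radius)^2 / (2 * radialSigma^2))
    VoxelVolume(array(a, dim = volumeShape), voxelSpacing)
}

#' Geodesic-disc phantom on a spherical shell
#'
#' A noiseless volume carrying a single Gaussian-profiled patch on the
#' sphere: radial Gaussian of width \code{radialSigma} about \code{radius},
#' tangential Gaussian of width \code{geodesicSigma} in geodesic distance
#' from the patch centre at (\code{discLat}, \code{discLon}). Small patches
#' of this kind probe the conformality of the map projection: they must
#' project to round blobs whose linear size scales as sec(latitude).
#'
#' @inheritParams shellPhantom
#' @param discLat,discLon patch centre, degrees.
#' @param geodesicSigma tangential width, um (geodesic distance on the shell).
#' @param radialSigma radial width, um.
#' @return A [VoxelVolume-class].
#' @export
discPhantom <- function(volumeShape = c(128L, 128L, 128L),
                        voxelSpacing = c(2, 2, 2),
                        center = (volumeShape - 1) * voxelSpacing / 2,
                        radius = 100, discLat = 0, discLon = 180,
                        geodesicSigma = 8, radialSigma = 4, amplitude = 100) {
    d <- as.integer(volumeShape)
    z <- (seq_len(d[1]) - 1) * voxelSpacing[1] - center[1]
    y <- (seq_len(d[2]) - 1) * voxelSpacing[2] - center[2]
    x <- (seq_len(d[3]) - 1) * voxelSpacing[3] - center[3]
    Z <- array(z, dim = d)
    Y <- array(rep(y, each = d[1]), dim = d)
    X <- array(rep(x, each = d[1] * d[2]), dim = d)
    r <- sqrt(Z^2 + Y^2 + X^2)
    phi <- discLat * pi / 180
    lam <- discLon * pi / 180
    u <- c(sin(phi), cos(phi) * sin(lam), cos(phi) * cos(lam))  # (z, y, x)
    ca <- (Z * u[1] + Y * u[2] + X * u[3]) / pmax(r, 1e-12)
    geo <- radius * acos(pmin(1, pmax(-1, ca)))
    a <- amplitude * exp(-(r - radius)^2 / (2 * radialSigma^2)) *
        exp(-geo^2 / (2 * geodesicSigma^2))
    VoxelVolume(array(a, dim = d), voxelSpacing)
}

#' Write / read a synthetic fixture (volumes + ground truth)
#'
#' Volumes are written through [writeVolume()] (multi-page 32-bit float TIFF
#' with a JSON sidecar holding spacing and intensity scale); ground truth is
#' one JSON file per fixture with sphere geometry, cell positions (um and
#' lat/lon) and per-ROI counts. \code{readFixture} inverts the layout.
#'
#' @param volumes named list of [VoxelVolume-class] (or one volume).
#' @param truths matching named list of [GroundTruth-class] (or one).
#' @param dir fixture directory (created if needed).
#' @return \code{writeFixture}: the directory, invisibly;
#'   \code{readFixture}: \code{list(volumes =, truths =)}.
#' @export
writeFixture <- function(volumes, truths, dir) {
    if (is(volumes, "VoxelVolume")) volumes <- list(embryo = volumes)
    if (is(truths, "GroundTruth")) truths <- list(embryo = truths)
    if (!identical(names(volumes), names(truths)))
        .stopf("fixture '%s': volume and truth names differ", dir)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gt <- list()
    for (nm in names(volumes)) {
        writeVolume(volumes[[nm]], file.path(dir, paste0(nm, ".tif")))
        tr <- truths[[nm]]
        gt[[nm]] <- list(
            sphere = list(center = tr@sphereCenter, radius = tr@sphereRadius,
                          shell_offset = tr@shellOffset),
            cells = list(xyz = tr@cellPositions, latlon = tr@cellLatLon),
            counts = as.list(tr@roiCounts))
    }
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
    invisible(dir)
}

#' @rdname writeFixture
#' @export
readFixture <- function(dir) {
    gtfile <- file.path(dir, "ground_truth.json")
    if (!file.exists(gtfile))
        .stopf("fixture '%s': missing ground_truth.json", dir)
    gt <- jsonlite::read_json(gtfile, simplifyVector = TRUE)
    volumes <- list()
    truths <- list()
    for (nm in names(gt)) {
        volumes[[nm]] <- readVolume(file.path(dir, paste0(nm, ".tif")))
        g <- gt[[nm]]
        pos <- matrix(unlist(g$cells$xyz), ncol = 3)
        ll <- matrix(unlist(g$cells$latlon), ncol = 2,
                     dimnames = list(NULL, c("latitude", "longitude")))
        truths[[nm]] <- new("GroundTruth",
            sphereCenter = as.numeric(g$sphere$center),
            sphereRadius = as.numeric(g$sphere$radius),
            shellOffset = as.numeric(g$sphere$shell_offset),
            cellPositions = pos, cellLatLon = ll,
            roiCounts = vapply(g$counts, as.integer, integer(1)))
    }
    list(volumes = volumes, truths = truths)
}
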