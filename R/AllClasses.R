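#' @import methods
#' @importFrom stats rnorm rpois runif setNames
#' @importFrom utils write.csv read.csv packageVersion
#' @useDynLib SphereMap, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Conventions shared by every class in the package:
##  * axis order of all triples is (z, y, x) = (planes, rows, cols);
##  * all physical quantities are in micrometres (um);
##  * voxel index i (1-based) sits at physical coordinate (i - 1) * spacing,
##    i.e. the origin is the centre of the first voxel.

#' VoxelVolume: a 3D intensity volume with physical voxel spacing
#'
#' The universal input container of the package: a non-negative 3D intensity
#' array together with its physical voxel spacing in micrometres, ordered
#' (z, y, x) = (planes, rows, cols). Voxel \code{[i, j, k]} (1-based) is
#' centred at physical coordinate \code{(i-1, j-1, k-1) * spacing} um.
#'
#' @slot data numeric 3D array of non-negative intensities.
#' @slot spacing numeric(3), voxel spacing in um per axis (z, y, x);
#'   strictly positive, may be anisotropic.
#' @slot timepoint character(1) label (possibly \code{NA}).
#'
#' @seealso [VoxelVolume()] for the constructor, [binVolume()],
#'   [sampleVolume()], [readVolume()].
#' @exportClass VoxelVolume
setClass("VoxelVolume",
    representation(data = "array", spacing = "numeric", timepoint = "character"),
    prototype(timepoint = NA_character_))

setValidity("VoxelVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "'data' must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "'spacing' must be 3 strictly positive um values")
    if (length(object@data) && min(object@data) < 0)
        msg <- c(msg, "intensities must be non-negative")
    if (length(object@timepoint) != 1L)
        msg <- c(msg, "'timepoint' must be a single label")
    if (length(msg)) msg else TRUE
})

#' BinaryMask: a binarized volume
#'
#' Boolean 3D mask with the (possibly post-binning) voxel spacing of the
#' volume it was derived from.
#'
#' @slot data logical 3D array.
#' @slot spacing numeric(3) um spacing (z, y, x).
#' @seealso [adaptiveBinarize()], [extractSurface()]
#' @exportClass BinaryMask
setClass("BinaryMask",
    representation(data = "array", spacing = "numeric"))

setValidity("BinaryMask", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L || !is.logical(object@data))
        msg <- c(msg, "'data' must be a logical 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "'spacing' must be 3 strictly positive um values")
    if (length(msg)) msg else TRUE
})

#' SurfacePointCloud: candidate surface points in physical coordinates
#'
#' Physical (um) coordinates of putative embryo-surface voxels, as produced
#' by [extractSurface()]: the boundary voxels of the largest 26-connected
#' foreground component of a binarized volume.
#'
#' @slot points numeric matrix, one row per point, columns (z, y, x) in um.
#' @slot provenance character(1), \code{"boundary_voxels"} or
#'   \code{"mesh_vertices"}.
#' @seealso [fitSphere()]
#' @exportClass SurfacePointCloud
setClass("SurfacePointCloud",
    representation(points = "matrix", provenance = "character"),
    prototype(provenance = "boundary_voxels"))

setValidity("SurfacePointCloud", function(object) {
    msg <- character()
    if (ncol(object@points) != 3L)
        msg <- c(msg, "'points' must have 3 columns (z, y, x) in um")
    if (!object@provenance %in% c("boundary_voxels", "mesh_vertices"))
        msg <- c(msg, "unknown provenance")
    if (length(msg)) msg else TRUE
})

#' SphereModel: a fitted embryo bounding sphere
#'
#' Result of the algebraic linear least-squares sphere fit ([fitSphere()]):
#' centre and radius in um plus the root-mean-square radial residual of the
#' points used.
#'
#' @slot center numeric(3) um, (z, y, x).
#' @slot radius numeric(1) um, > 0.
#' @slot rmsResidual numeric(1) um, >= 0.
#' @slot nPoints integer(1), number of points used in the fit.
#' @exportClass SphereModel
setClass("SphereModel",
    representation(center = "numeric", radius = "numeric",
                   rmsResidual = "numeric", nPoints = "integer"))

setValidity("SphereModel", function(object) {
    msg <- character()
    if (length(object@center) != 3L) msg <- c(msg, "'center' must be (z, y, x)")
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0)
        msg <- c(msg, "'radius' must be a single positive um value")
    if (object@rmsResidual < 0) msg <- c(msg, "'rmsResidual' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' ProjectionGrid: latitude/longitude sampling of a map image
#'
#' Row/column geometry of a map image. In \code{"mercator"} mode rows are
#' uniform in the Mercator ordinate y = R ln tan(pi/4 + phi/2) between
#' -y(phi_max) and +y(phi_max) — the placement that makes the map conformal —
#' and the grid must be truncated below the poles; in \code{"equirect"} mode
#' rows are uniform in latitude and may reach +/-90 degrees. Columns are
#' always uniform in longitude on [0, 360). Row 1 is the +phi_max (top) side.
#'
#' @slot latitudes numeric, per-row centre latitude in degrees, decreasing.
#' @slot longitudes numeric, per-column centre longitude in degrees.
#' @slot truncationLat numeric(1), degrees; the map spans
#'   \code{[-truncationLat, +truncationLat]}.
#' @slot referenceRadius numeric(1) um; the radius R scaling Mercator y.
#' @slot mode character(1), \code{"mercator"} or \code{"equirect"}.
#' @seealso [makeGrid()], [projectLayer()]
#' @exportClass ProjectionGrid
setClass("ProjectionGrid",
    representation(latitudes = "numeric", longitudes = "numeric",
                   truncationLat = "numeric", referenceRadius = "numeric",
                   mode = "character"))

setValidity("ProjectionGrid", function(object) {
    msg <- character()
    if (!object@mode %in% c("mercator", "equirect"))
        msg <- c(msg, "mode must be 'mercator' or 'equirect'")
    tl <- object@truncationLat
    if (length(tl) != 1L || tl <= 0 || tl > 90 ||
        (object@mode == "mercator" && tl >= 90))
        msg <- c(msg, "truncationLat must be in (0, 90); < 90 in Mercator mode")
    if (length(object@latitudes) < 2L || any(diff(object@latitudes) >= 0))
        msg <- c(msg, "row latitudes must be strictly decreasing (row 1 = top)")
    if (length(object@longitudes) < 2L ||
        any(object@longitudes < 0 | object@longitudes >= 360))
        msg <- c(msg, "longitudes must lie in [0, 360)")
    if (object@referenceRadius <= 0)
        msg <- c(msg, "referenceRadius must be positive")
    if (length(msg)) msg else TRUE
})

#' MapLayerStack: per-shell Mercator map images
#'
#' One 2D map image per concentric shell, indexed by the radial offset (um)
#' of the shell from the fitted sphere radius.
#'
#' @slot offsets numeric, radial offsets in um, one per layer.
#' @slot layers list of numeric matrices, all of the grid's shape.
#' @slot grid the shared [ProjectionGrid-class].
#' @slot sphere the [SphereModel-class] that anchors the shells.
#' @slot sampler character(1), \code{"trilinear"} or \code{"nearest"}.
#' @slot fillValue numeric(1) used for out-of-volume samples.
#' @seealso [projectMultilayer()], [maxProjectLayers()]
#' @exportClass MapLayerStack
setClass("MapLayerStack",
    representation(offsets = "numeric", layers = "list",
                   grid = "ProjectionGrid", sphere = "SphereModel",
                   sampler = "character", fillValue = "numeric"))

setValidity("MapLayerStack", function(object) {
    msg <- character()
    if (length(object@offsets) != length(object@layers))
        msg <- c(msg, "one offset per layer required")
    shp <- c(length(object@grid@latitudes), length(object@grid@longitudes))
    ok <- vapply(object@layers, function(m) identical(dim(m), shp), logical(1))
    if (length(ok) && !all(ok))
        msg <- c(msg, "all layer images must share the grid shape")
    if (length(msg)) msg else TRUE
})

#' EmbryoSpec: parameters of a synthetic spherical embryo
#'
#' Full description of one simulated embryo volume: geometry of the bounding
#' sphere, the radial shell carrying the fluorescent cells, blob photometry,
#' optional interior (yolk) autofluorescence, camera noise and the PRNG seed.
#' [generateVolume()] turns a spec into a volume plus exact ground truth.
#'
#' @slot volumeShape integer(3), voxels per axis (planes, rows, cols).
#' @slot voxelSpacing numeric(3) um (z, y, x); may be anisotropic.
#' @slot sphereCenter numeric(3) um (z, y, x).
#' @slot sphereRadius numeric(1) um.
#' @slot shellOffset numeric(1) um, signed radial position of the cell layer
#'   relative to the sphere surface (negative = inside).
#' @slot nCells integer(1) >= 0.
#' @slot cellSigma numeric(1) um, isotropic Gaussian blob width.
#' @slot cellAmplitude numeric(1), blob peak intensity.
#' @slot yolkAmplitude numeric(1), interior autofluorescence amplitude
#'   (0 disables the yolk).
#' @slot background numeric(1), constant background intensity.
#' @slot noiseModel character(1): \code{"none"}, \code{"gaussian"},
#'   \code{"poisson"} or \code{"poisson+gaussian"}.
#' @slot noiseParams named list: \code{gain} (intensity units per photon,
#'   Poisson) and \code{readSd} (Gaussian read-noise sd, intensity units).
#' @slot minCellSeparation numeric(1) um, pairwise lower bound enforced by
#'   rejection sampling.
#' @slot seed integer(1) PRNG seed.
#' @seealso [EmbryoSpec()], [generateVolume()], [generateTimecourse()]
#' @exportClass EmbryoSpec
setClass("EmbryoSpec",
    representation(volumeShape = "integer", voxelSpacing = "numeric",
                   sphereCenter = "numeric", sphereRadius = "numeric",
                   shellOffset = "numeric", nCells = "integer",
                   cellSigma = "numeric", cellAmplitude = "numeric",
                   yolkAmplitude = "numeric", background = "numeric",
                   noiseModel = "character", noiseParams = "list",
                   minCellSeparation = "numeric", seed = "integer"))

setValidity("EmbryoSpec", function(object) {
    msg <- character()
    if (length(object@volumeShape) != 3L || any(object@volumeShape < 1L))
        msg <- c(msg, "'volumeShape' must be 3 positive integers")
    if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
        msg <- c(msg, "'voxelSpacing' must be 3 positive um values")
    if (object@sphereRadius <= 0) msg <- c(msg, "'sphereRadius' must be > 0")
    if (object@nCells < 0L) msg <- c(msg, "'nCells' must be >= 0")
    if (object@minCellSeparation < 0)
        msg <- c(msg, "'minCellSeparation' must be >= 0")
    if (any(c(object@cellAmplitude, object@yolkAmplitude,
              object@background) < 0))
        msg <- c(msg, "amplitudes and background must be >= 0")
    if (!object@noiseModel %in%
            c("none", "gaussian", "poisson", "poisson+gaussian"))
        msg <- c(msg, "unknown noise model")
    ## the sphere (incl. the cell shell) must sit inside the volume with
    ## a margin of at least 3 * cellSigma
    extent <- (object@volumeShape - 1L) * object@voxelSpacing
    reach <- object@sphereRadius + max(object@shellOffset, 0) +
        3 * object@cellSigma
    if (any(object@sphereCenter - reach < 0) ||
        any(object@sphereCenter + reach > extent))
        msg <- c(msg,
            "sphere does not fit inside the volume with a 3*cellSigma margin")
    if (object@sphereRadius + object@shellOffset <= 0)
        msg <- c(msg, "cell shell radius must be positive")
    if (length(msg)) msg else TRUE
})

#' GroundTruth: exact simulation ground truth
#'
#' The exact geometry behind a synthetic volume: sphere centre/radius, every
#' cell position (um and latitude/longitude) and true per-ROI counts.
#'
#' @slot sphereCenter numeric(3) um (z, y, x).
#' @slot sphereRadius numeric(1) um.
#' @slot shellOffset numeric(1) um.
#' @slot cellPositions numeric matrix, rows = cells, columns (z, y, x) um.
#' @slot cellLatLon numeric matrix, rows = cells, columns
#'   (latitude, longitude) degrees.
#' @slot roiCounts named integer vector of true counts per ROI
#'   (always includes \code{"whole"}).
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(sphereCenter = "numeric", sphereRadius = "numeric",
                   shellOffset = "numeric", cellPositions = "matrix",
                   cellLatLon = "matrix", roiCounts = "integer"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (ncol(object@cellPositions) != 3L)
        msg <- c(msg, "'cellPositions' must have columns (z, y, x)")
    if (nrow(object@cellLatLon) != nrow(object@cellPositions))
        msg <- c(msg, "'cellLatLon' must match 'cellPositions' row for row")
    if (length(object@roiCounts) && is.null(names(object@roiCounts)))
        msg <- c(msg, "'roiCounts' must be named")
    if (length(msg)) msg else TRUE
})

#' TimeCourseSpec: a two-condition developmental time course
#'
#' Growth of the labelled cell population over timepoints (e.g. 1, 2, 3 days
#' post-fertilization) for a control and a perturbed condition, expressed as
#' per-timepoint multipliers of the base cell count. Emulates the
#' wildtype-versus-morphant counting experiment.
#'
#' @slot base an [EmbryoSpec-class]; its \code{nCells} is the count unit.
#' @slot timepoints character vector of labels.
#' @slot controlMultipliers numeric, > 0, non-decreasing.
#' @slot perturbedMultipliers numeric, > 0.
#' @seealso [generateTimecourse()], [quantifyTimecourse()]
#' @exportClass TimeCourseSpec
setClass("TimeCourseSpec",
    representation(base = "EmbryoSpec", timepoints = "character",
                   controlMultipliers = "numeric",
                   perturbedMultipliers = "numeric"))

setValidity("TimeCourseSpec", function(object) {
    msg <- character()
    nt <- length(object@timepoints)
    if (length(object@controlMultipliers) != nt ||
        length(object@perturbedMultipliers) != nt)
        msg <- c(msg, "one multiplier per timepoint and condition required")
    if (any(c(object@controlMultipliers, object@perturbedMultipliers) <= 0))
        msg <- c(msg, "multipliers must be > 0")
    if (nt > 1L && any(diff(object@controlMultipliers) < 0))
        msg <- c(msg, "control multipliers must be non-decreasing")
    if (anyDuplicated(object@timepoints))
        msg <- c(msg, "timepoint labels must be unique")
    if (length(msg)) msg else TRUE
})

#' SpotParams: spot-detection parameters
#'
#' Parameters of the automated cell-picking workflow: baseline estimation
#' scale, detection threshold above baseline, physical minimum separation of
#' accepted spots and the expected spot width used for centroid refinement.
#'
#' @slot backgroundSigma numeric(1) um, Gaussian scale of the baseline.
#' @slot detectionThreshold numeric(1), intensity above baseline.
#' @slot minSeparation numeric(1) um; must be >= \code{expectedSpotSigma}.
#' @slot expectedSpotSigma numeric(1) um.
#' @seealso [SpotParams()], [detectSpots()]
#' @exportClass SpotParams
setClass("SpotParams",
    representation(backgroundSigma = "numeric", detectionThreshold = "numeric",
                   minSeparation = "numeric", expectedSpotSigma = "numeric"))

setValidity("SpotParams", function(object) {
    msg <- character()
    vals <- c(object@backgroundSigma, object@detectionThreshold,
              object@minSeparation, object@expectedSpotSigma)
    if (length(vals) != 4L || any(!is.finite(vals)) || any(vals <= 0))
        msg <- c(msg, "all parameters must be single positive values")
    else if (object@minSeparation < object@expectedSpotSigma)
        msg <- c(msg, "'minSeparation' must be >= 'expectedSpotSigma'")
    if (length(msg)) msg else TRUE
})

#' SpotSet: detected cell centroids
#'
#' Spot centroids (um) with peak intensities and the labels of the volume
#' they came from. Pairwise centroid distances respect the minimum
#' separation that was enforced at detection time.
#'
#' @slot centroids numeric matrix, rows = spots, columns (z, y, x) um.
#' @slot peakIntensities numeric, baseline-subtracted peak value per spot.
#' @slot timepoint character(1) label (possibly \code{NA}).
#' @slot condition character(1) label (possibly \code{NA}).
#' @slot minSeparation numeric(1) um enforced between centroids.
#' @seealso [detectSpots()], [countInROI()]
#' @exportClass SpotSet
setClass("SpotSet",
    representation(centroids = "matrix", peakIntensities = "numeric",
                   timepoint = "character", condition = "character",
                   minSeparation = "numeric"),
    prototype(timepoint = NA_character_, condition = NA_character_,
              minSeparation = 0))

setValidity("SpotSet", function(object) {
    msg <- character()
    n <- nrow(object@centroids)
    if (ncol(object@centroids) != 3L)
        msg <- c(msg, "'centroids' must have columns (z, y, x)")
    if (length(object@peakIntensities) != n)
        msg <- c(msg, "one peak intensity per centroid required")
    if (n > 1L && object@minSeparation > 0) {
        d <- stats::dist(object@centroids)
        if (min(d) < object@minSeparation - 1e-9)
            msg <- c(msg, "pairwise centroid distance below minSeparation")
    }
    if (length(msg)) msg else TRUE
})

#' ROIBox: an axis-aligned physical region of interest
#'
#' Axis-aligned box in um with an inclusive lower and exclusive upper bound
#' on every axis, so that boxes partitioning space give exactly additive
#' counts. Used e.g. for the trunk region of an embryo.
#'
#' @slot name character(1).
#' @slot lo numeric(3) um (z, y, x), inclusive.
#' @slot hi numeric(3) um (z, y, x), exclusive; \code{lo < hi} per axis.
#' @seealso [ROIBox()], [countInROI()]
#' @exportClass ROIBox
setClass("ROIBox",
    representation(name = "character", lo = "numeric", hi = "numeric"))

setValidity("ROIBox", function(object) {
    msg <- character()
    if (length(object@lo) != 3L || length(object@hi) != 3L)
        msg <- c(msg, "'lo' and 'hi' must be um triples (z, y, x)")
    else if (any(object@lo >= object@hi))
        msg <- c(msg, "'lo' must be strictly below 'hi' on every axis")
    if (length(object@name) != 1L || is.na(object@name) ||
        !nzchar(object@name))
        msg <- c(msg, "ROI needs a non-empty name")
    if (length(msg)) msg else TRUE
})
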