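#' Accessors for SphereMap classes
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return The slot value (see the individual methods).
#' @name accessors
#' @aliases intensityData spacing timepoint surfacePoints sphereCenter
#'   sphereRadius rmsResidual nPoints gridLatitudes gridLongitudes gridMode
#'   layerOffsetsOf mapLayers spotCentroids peakIntensities cellPositions
#'   cellLatLon trueCounts
NULL

#' @rdname accessors
#' @export
setGeneric("intensityData", function(x) standardGeneric("intensityData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))
#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(x) standardGeneric("surfacePoints"))
#' @rdname accessors
#' @export
setGeneric("sphereCenter", function(x) standardGeneric("sphereCenter"))
#' @rdname accessors
#' @export
setGeneric("sphereRadius", function(x) standardGeneric("sphereRadius"))
#' @rdname accessors
#' @export
setGeneric("rmsResidual", function(x) standardGeneric("rmsResidual"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("gridLatitudes", function(x) standardGeneric("gridLatitudes"))
#' @rdname accessors
#' @export
setGeneric("gridLongitudes", function(x) standardGeneric("gridLongitudes"))
#' @rdname accessors
#' @export
setGeneric("gridMode", function(x) standardGeneric("gridMode"))
#' @rdname accessors
#' @export
setGeneric("layerOffsetsOf", function(x) standardGeneric("layerOffsetsOf"))
#' @rdname accessors
#' @export
setGeneric("mapLayers", function(x) standardGeneric("mapLayers"))
#' @rdname accessors
#' @export
setGeneric("spotCentroids", function(x) standardGeneric("spotCentroids"))
#' @rdname accessors
#' @export
setGeneric("peakIntensities", function(x) standardGeneric("peakIntensities"))
#' @rdname accessors
#' @export
setGeneric("cellPositions", function(x) standardGeneric("cellPositions"))
#' @rdname accessors
#' @export
setGeneric("cellLatLon", function(x) standardGeneric("cellLatLon"))
#' @rdname accessors
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))

#' @rdname accessors
setMethod("intensityData", "VoxelVolume", function(x) x@data)
#' @rdname accessors
setMethod("intensityData", "BinaryMask", function(x) x@data)
#' @rdname accessors
setMethod("spacing", "VoxelVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "BinaryMask", function(x) x@spacing)
#' @rdname accessors
setMethod("timepoint", "VoxelVolume", function(x) x@timepoint)
#' @describeIn accessors dimensions of the underlying array.
#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@data))
#' @rdname accessors
setMethod("surfacePoints", "SurfacePointCloud", function(x) x@points)
#' @rdname accessors
setMethod("nPoints", "SurfacePointCloud", function(x) nrow(x@points))
#' @rdname accessors
setMethod("sphereCenter", "SphereModel", function(x) x@center)
#' @rdname accessors
setMethod("sphereRadius", "SphereModel", function(x) x@radius)
#' @rdname accessors
setMethod("rmsResidual", "SphereModel", function(x) x@rmsResidual)
#' @rdname accessors
setMethod("nPoints", "SphereModel", function(x) x@nPoints)
#' @rdname accessors
setMethod("sphereCenter", "GroundTruth", function(x) x@sphereCenter)
#' @rdname accessors
setMethod("sphereRadius", "GroundTruth", function(x) x@sphereRadius)
#' @rdname accessors
setMethod("cellPositions", "GroundTruth", function(x) x@cellPositions)
#' @rdname accessors
setMethod("cellLatLon", "GroundTruth", function(x) x@cellLatLon)
#' @rdname accessors
setMethod("trueCounts", "GroundTruth", function(x) x@roiCounts)
#' @rdname accessors
setMethod("gridLatitudes", "ProjectionGrid", function(x) x@latitudes)
#' @rdname accessors
setMethod("gridLongitudes", "ProjectionGrid", function(x) x@longitudes)
#' @rdname accessors
setMethod("gridMode", "ProjectionGrid", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("dim", "ProjectionGrid",
    function(x) c(length(x@latitudes), length(x@longitudes)))
#' @rdname accessors
setMethod("layerOffsetsOf", "MapLayerStack", function(x) x@offsets)
#' @rdname accessors
setMethod("mapLayers", "MapLayerStack", function(x) x@layers)
#' @rdname accessors
setMethod("spotCentroids", "SpotSet", function(x) x@centroids)
#' @rdname accessors
setMethod("peakIntensities", "SpotSet", function(x) x@peakIntensities)
#' @rdname accessors
setMethod("timepoint", "SpotSet", function(x) x@timepoint)
#' @describeIn accessors number of spots.
#' @export
setMethod("length", "SpotSet", function(x) nrow(x@centroids))

setMethod("show", "VoxelVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("VoxelVolume %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
    cat(sprintf("  spacing: %s um\n", paste(format(object@spacing), collapse = " x ")))
    cat(sprintf("  extent : %s um\n",
        paste(format((d - 1) * object@spacing), collapse = " x ")))
    if (length(object@data))
        cat(sprintf("  range  : [%g, %g]\n", min(object@data), max(object@data)))
    if (!is.na(object@timepoint))
        cat(sprintf("  timepoint: %s\n", object@timepoint))
})

setMethod("show", "BinaryMask", function(object) {
    d <- dim(object@data)
    cat(sprintf("BinaryMask %d x %d x %d (%d foreground voxels)\n",
        d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "SurfacePointCloud", function(object) {
    cat(sprintf("SurfacePointCloud: %d points (%s)\n",
        nrow(object@points), object@provenance))
})

setMethod("show", "SphereModel", function(object) {
    cat(sprintf(
        "SphereModel: center (z, y, x) = (%.2f, %.2f, %.2f) um, radius %.2f um\n",
        object@center[1], object@center[2], object@center[3], object@radius))
    cat(sprintf("  rms residual %.3f um over %d points\n",
        object@rmsResidual, object@nPoints))
})

setMethod("show", "ProjectionGrid", function(object) {
    cat(sprintf("ProjectionGrid (%s): %d rows x %d cols, |lat| <= %g deg, R = %g um\n",
        object@mode, length(object@latitudes), length(object@longitudes),
        object@truncationLat, object@referenceRadius))
})

setMethod("show", "MapLayerStack", function(object) {
    cat(sprintf("MapLayerStack: %d layers, offsets [%g, %g] um, %d x %d px\n",
        length(object@layers),
        if (length(object@offsets)) min(object@offsets) else NA,
        if (length(object@offsets)) max(object@offsets) else NA,
        length(object@grid@latitudes), length(object@grid@longitudes)))
})

setMethod("show", "EmbryoSpec", function(object) {
    cat(sprintf(
        "EmbryoSpec: %s voxels @ %s um, R = %g um, %d cells (shell %+g um)\n",
        paste(object@volumeShape, collapse = "x"),
        paste(format(object@voxelSpacing), collapse = "x"),
        object@sphereRadius, object@nCells, object@shellOffset))
    cat(sprintf("  noise: %s, seed %d\n", object@noiseModel, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d cells on sphere R = %g um (shell %+g um)\n",
        nrow(object@cellPositions), object@sphereRadius, object@shellOffset))
})

setMethod("show", "SpotSet", function(object) {
    cat(sprintf("SpotSet: %d spots", nrow(object@centroids)))
    if (!is.na(object@timepoint))
        cat(sprintf(" [%s%s]", object@timepoint,
            if (!is.na(object@condition)) paste0(", ", object@condition) else ""))
    cat("\n")
})

setMethod("show", "ROIBox", function(object) {
    cat(sprintf("ROIBox '%s': z [%g, %g) y [%g, %g) x [%g, %g) um\n",
        object@name, object@lo[1], object@hi[1], object@lo[2], object@hi[2],
        object@lo[3], object@hi[3]))
})
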