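#' Mercator ordinate and its inverse
#'
#' \code{mercatorY} maps latitude phi (degrees) to the Mercator ordinate
#' \code{y = R * ln(tan(pi/4 + phi/2))} (um when R is in um); it is odd in
#' phi and singular at the poles, so \code{|phi| >= 90} is an error.
#' \code{inverseMercatorY} applies the exact inverse
#' \code{phi = 2 atan(exp(y / R)) - pi/2}.
#'
#' @param latitude degrees, \code{|latitude| < 90} (vectorized).
#' @param y Mercator ordinate, same units as \code{R}.
#' @param R reference radius.
#' @return Numeric vector (um for \code{mercatorY}, degrees for
#'   \code{inverseMercatorY}).
#' @examples
#' mercatorY(60, R = 1)             # ln(tan 75 deg) = 1.3169579...
#' inverseMercatorY(mercatorY(30, 5), 5)
#' @export
mercatorY <- function(latitude, R) {
    if (any(abs(latitude) >= 90))
        .stopf(paste0("Mercator ordinate is singular at the poles: ",
                      "|latitude| must be < 90 deg (got %g)"),
               max(abs(latitude)))
    phi <- latitude * pi / 180
    R * log(tan(pi / 4 + phi / 2))
}

#' @rdname mercatorY
#' @export
inverseMercatorY <- function(y, R) {
    (2 * atan(exp(y / R)) - pi / 2) * 180 / pi
}

#' Build a map-projection grid
#'
#' Columns are uniform in longitude, centred at \code{(j - 0.5) * 360 /
#' nCols}. In \code{"mercator"} mode, row centres are uniform in the
#' Mercator ordinate between \code{+y(truncationLat)} (row 1, top) and
#' \code{-y(truncationLat)} and converted back to latitude — the placement
#' that makes the map conformal; a truncation below the poles is
#' unavoidable there, default 85 degrees. In \code{"equirect"} mode rows are
#' uniform in latitude and \code{truncationLat = 90} is allowed, which makes
#' the full nominal -90..+90 latitude range expressible at the price of
#' conformality.
#'
#' When \code{nCols} is omitted it defaults to one column per
#' \code{pixelSize} of arc at the equator (\code{round(2 pi R /
#' pixelSize)}); when \code{nRows} is omitted it is chosen to give the same
#' physical scale (um per pixel) vertically.
#'
#' @param R reference radius in um (scale of the Mercator ordinate; use the
#'   fitted sphere radius so that all layers stay pixel-aligned).
#' @param nRows,nCols grid size (>= 2); see above for defaults.
#' @param truncationLat degrees; map spans \code{[-truncationLat,
#'   +truncationLat]}.
#' @param mode \code{"mercator"} (default) or \code{"equirect"}.
#' @param pixelSize um of equatorial arc per column, used only when
#'   \code{nCols} is \code{NULL} (a natural choice is the smallest voxel
#'   spacing of the volume to be projected).
#' @return A [ProjectionGrid-class].
#' @examples
#' g <- makeGrid(R = 100, nRows = 11, nCols = 4)
#' gridLongitudes(g)    # 45, 135, 225, 315
#' gridLatitudes(g)[6]  # middle row sits on the equator
#' @export
makeGrid <- function(R, nRows = NULL, nCols = NULL, truncationLat = 85,
                     mode = c("mercator", "equirect"), pixelSize = NULL) {
    mode <- match.arg(mode)
    if (R <= 0) .stopf("reference radius must be positive")
    if (truncationLat <= 0 || truncationLat > 90)
        .stopf("truncationLat must lie in (0, 90]")
    if (mode == "mercator" && truncationLat >= 90)
        .stopf(paste0("the Mercator ordinate diverges at the poles; ",
                      "truncationLat must be < 90 deg in mercator mode ",
                      "(use mode = 'equirect' to reach the poles)"))
    if (is.null(nCols)) {
        if (is.null(pixelSize))
            .stopf("either nCols or pixelSize must be given")
        nCols <- max(2L, as.integer(round(2 * pi * R / pixelSize)))
    }
    span <- if (mode == "mercator") 2 * mercatorY(truncationLat, R)
            else 2 * R * truncationLat * pi / 180
    if (is.null(nRows))
        nRows <- max(2L, as.integer(round(span / (2 * pi * R / nCols))))
    nRows <- as.integer(nRows)
    nCols <- as.integer(nCols)
    if (nRows < 2L || nCols < 2L) .stopf("grid must be at least 2 x 2")

    i <- seq_len(nRows)
    lats <- if (mode == "mercator") {
        ymax <- mercatorY(truncationLat, R)
        inverseMercatorY(ymax - (i - 0.5) * (2 * ymax / nRows), R)
    } else {
        truncationLat - (i - 0.5) * (2 * truncationLat / nRows)
    }
    lons <- (seq_len(nCols) - 0.5) * 360 / nCols
    new("ProjectionGrid", latitudes = lats, longitudes = lons,
        truncationLat = truncationLat, referenceRadius = R, mode = mode)
}

#' Spherical / cartesian coordinate conversion about a sphere model
#'
#' Latitude phi is measured from the equatorial plane with +90 degrees at
#' the +z pole; longitude lambda increases from the +x axis towards +y.
#' \code{latlonToCartesian} returns physical (z, y, x) um coordinates
#' \code{center + r (sin phi, cos phi sin lambda, cos phi cos lambda)};
#' \code{cartesianToLatlon} is its exact inverse.
#'
#' @param latitude,longitude degrees (vectorized).
#' @param radius sampling radius r > 0, um.
#' @param sphere a [SphereModel-class] providing the centre.
#' @param points numeric matrix with columns (z, y, x) um.
#' @return \code{latlonToCartesian}: matrix with columns (z, y, x) um;
#'   \code{cartesianToLatlon}: matrix with columns
#'   (latitude, longitude, radius).
#' @export
latlonToCartesian <- function(latitude, longitude, radius, sphere) {
    if (any(radius <= 0)) .stopf("sampling radius must be positive")
    phi <- latitude * pi / 180
    lam <- longitude * pi / 180
    cbind(z = sphere@center[1] + radius * sin(phi),
          y = sphere@center[2] + radius * cos(phi) * sin(lam),
          x = sphere@center[3] + radius * cos(phi) * cos(lam))
}

#' @rdname latlonToCartesian
#' @export
cartesianToLatlon <- function(points, sphere) {
    points <- as.matrix(points)
    dz <- points[, 1] - sphere@center[1]
    dy <- points[, 2] - sphere@center[2]
    dx <- points[, 3] - sphere@center[3]
    r <- sqrt(dz^2 + dy^2 + dx^2)
    cbind(latitude = asin(pmin(1, pmax(-1, dz / r))) * 180 / pi,
          longitude = (atan2(dy, dx) * 180 / pi) %% 360,
          radius = r)
}

#' Sample a volume at physical points
#'
#' Interpolates the volume at arbitrary um positions, honouring anisotropic
#' voxel spacing. \code{"trilinear"} interpolates between the 8 surrounding
#' voxel centres; \code{"nearest"} (meant for label images) picks the
#' closest centre. Points outside the voxel-centre bounding box return
#' \code{fill} — out of bounds is never an error.
#'
#' @param v a [VoxelVolume-class].
#' @param points numeric matrix with columns (z, y, x) um (a single point
#'   may be given as a vector).
#' @param sampler \code{"trilinear"} or \code{"nearest"}.
#' @param fill value returned outside the volume.
#' @return Numeric vector of sampled intensities, one per point.
#' @export
sampleVolume <- function(v, points, sampler = c("trilinear", "nearest"),
                         fill = 0) {
    stopifnot(is(v, "VoxelVolume"))
    sampler <- match.arg(sampler)
    if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
    d <- dim(v@data)
    t1 <- points[, 1] / v@spacing[1]
    t2 <- points[, 2] / v@spacing[2]
    t3 <- points[, 3] / v@spacing[3]
    inside <- t1 >= 0 & t1 <= d[1] - 1 &
              t2 >= 0 & t2 <= d[2] - 1 &
              t3 >= 0 & t3 <= d[3] - 1
    out <- rep(fill, nrow(points))
    if (!any(inside)) return(out)
    t1 <- t1[inside]; t2 <- t2[inside]; t3 <- t3[inside]

    if (sampler == "nearest") {
        i1 <- pmin(round(t1), d[1] - 1)
        i2 <- pmin(round(t2), d[2] - 1)
        i3 <- pmin(round(t3), d[3] - 1)
        out[inside] <- v@data[1 + i1 + d[1] * (i2 + d[2] * i3)]
        return(out)
    }

    f1 <- pmin(floor(t1), d[1] - 2); f1 <- pmax(f1, 0)
    f2 <- pmin(floor(t2), d[2] - 2); f2 <- pmax(f2, 0)
    f3 <- pmin(floor(t3), d[3] - 2); f3 <- pmax(f3, 0)
    w1 <- t1 - f1; w2 <- t2 - f2; w3 <- t3 - f3
    ## special case: a degenerate axis of length 1 (then f = 0, w = 0)
    if (d[1] == 1L) { f1[] <- 0; w1[] <- 0 }
    if (d[2] == 1L) { f2[] <- 0; w2[] <- 0 }
    if (d[3] == 1L) { f3[] <- 0; w3[] <- 0 }
    s1 <- min(1L, d[1] - 1L); s2 <- min(1L, d[2] - 1L); s3 <- min(1L, d[3] - 1L)
    at <- function(a, b, c)
        v@data[1 + (f1 + a * s1) + d[1] * ((f2 + b * s2) + d[2] * (f3 + c * s3))]
    val <-
        at(0, 0, 0) * (1 - w1) * (1 - w2) * (1 - w3) +
        at(1, 0, 0) * w1       * (1 - w2) * (1 - w3) +
        at(0, 1, 0) * (1 - w1) * w2       * (1 - w3) +
        at(1, 1, 0) * w1       * w2       * (1 - w3) +
        at(0, 0, 1) * (1 - w1) * (1 - w2) * w3 +
        at(1, 0, 1) * w1       * (1 - w2) * w3 +
        at(0, 1, 1) * (1 - w1) * w2       * w3 +
        at(1, 1, 1) * w1       * w2       * w3
    out[inside] <- val
    out
}

#' Project one spherical shell onto a map image
#'
#' Samples the volume on the sphere of radius \code{sphereRadius(sphere) +
#' radialOffset} at every (latitude, longitude) centre of the grid: pixel
#' \code{[i, j]} is the interpolated intensity at the cartesian position of
#' (row i latitude, column j longitude) — a direct mapping of volume values
#' onto the unwrapped map.
#'
#' @param v a [VoxelVolume-class].
#' @param sphere a [SphereModel-class].
#' @param radialOffset um offset from the fitted radius (negative = deeper).
#' @param grid a [ProjectionGrid-class].
#' @param sampler,fill see [sampleVolume()].
#' @return A numeric matrix of the grid's shape (rows = latitudes from
#'   +truncation down, cols = longitudes).
#' @export
projectLayer <- function(v, sphere, radialOffset = 0, grid,
                         sampler = "trilinear", fill = 0) {
    r <- sphere@radius + radialOffset
    if (r <= 0)
        .stopf("sampling radius %.3f um (offset %+g um) is not positive",
               r, radialOffset)
    nr <- length(grid@latitudes)
    nc <- length(grid@longitudes)
    lat <- rep(grid@latitudes, times = nc)
    lon <- rep(grid@longitudes, each = nr)
    pts <- latlonToCartesian(lat, lon, r, sphere)
    matrix(sampleVolume(v, pts, sampler, fill), nrow = nr, ncol = nc)
}

#' Radial offsets for a multi-layer projection
#'
#' Arithmetic sequence of radial offsets with the standard 2 um step,
#' spanning \code{depthInward} um below to \code{depthOutward} um above the
#' fitted radius.
#'
#' @param step um between consecutive layers (default 2).
#' @param depthInward,depthOutward um covered inside / outside the surface.
#' @return Numeric vector of offsets, ascending.
#' @examples
#' layerOffsets(step = 2, depthInward = 10)  # 6 layers: -10, -8, ..., 0
#' @export
layerOffsets <- function(step = 2, depthInward = 10, depthOutward = 0) {
    if (step <= 0) .stopf("layer step must be positive")
    seq(-depthInward, depthOutward, by = step)
}

#' Unwrap concentric shells into a map-layer stack
#'
#' One [projectLayer()] image per radial offset, ordered as given; the
#' default offsets use the standard 2 um step. Offsets whose sampling radius
#' would be non-positive abort with the offending offset.
#'
#' @inheritParams projectLayer
#' @param offsets numeric vector of radial offsets in um.
#' @return A [MapLayerStack-class].
#' @export
projectMultilayer <- function(v, sphere, offsets = layerOffsets(), grid,
                              sampler = "trilinear", fill = 0) {
    layers <- vector("list", length(offsets))
    for (k in seq_along(offsets)) {
        layers[[k]] <- tryCatch(
            projectLayer(v, sphere, offsets[k], grid, sampler, fill),
            error = function(e) .stopf("layer at offset %+g um: %s",
                                       offsets[k], conditionMessage(e)))
    }
    new("MapLayerStack", offsets = as.numeric(offsets), layers = layers,
        grid = grid, sphere = sphere, sampler = sampler,
        fillValue = as.numeric(fill))
}

#' Maximum-intensity projection across map layers
#'
#' Pixelwise maximum over all layers of the stack — the cross-depth map view
#' used for whole-surface snapshots.
#'
#' @param stack a [MapLayerStack-class] with at least one layer.
#' @return A numeric matrix of the grid's shape.
#' @export
maxProjectLayers <- function(stack) {
    stopifnot(is(stack, "MapLayerStack"))
    if (!length(stack@layers)) .stopf("empty layer stack")
    Reduce(pmax, stack@layers)
}
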