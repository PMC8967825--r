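#' Bin a volume by block averaging
#'
#' Each output voxel is the mean of its \code{factor} block of input voxels;
#' trailing partial blocks are averaged over the voxels they actually
#' contain. Mean (rather than sum) binning keeps intensity thresholds
#' scale-free across binning factors. The output spacing is the input
#' spacing times the factor. The default factor of 4 per axis matches the
#' standard pre-processing of whole-embryo volumes before surface
#' estimation.
#'
#' @param v a [VoxelVolume-class].
#' @param factor integer(3) (or a scalar, recycled) binning factor per axis
#'   (z, y, x); each must be >= 1 and no larger than the axis length.
#' @return The binned [VoxelVolume-class].
#' @examples
#' v <- VoxelVolume(array(7, c(4, 4, 4)), c(1, 1, 1))
#' intensityData(binVolume(v, 4))   # single voxel of value 7
#' @export
binVolume <- function(v, factor = c(4L, 4L, 4L)) {
    stopifnot(is(v, "VoxelVolume"))
    factor <- as.integer(rep(factor, length.out = 3L))
    d <- dim(v@data)
    if (any(factor < 1L)) .stopf("binning factors must be >= 1")
    if (any(factor > d))
        .stopf("binning factor (%s) exceeds volume shape (%s)",
               paste(factor, collapse = ","), paste(d, collapse = ","))
    a <- v@data
    for (ax in 1:3) {
        f <- factor[ax]
        if (f == 1L) next
        perm <- c(ax, setdiff(1:3, ax))
        ap <- aperm(a, perm)
        dp <- dim(ap)
        n <- dp[1]
        g <- rep(seq_len(ceiling(n / f)), each = f)[seq_len(n)]
        cnt <- tabulate(g)
        M <- rowsum(matrix(ap, nrow = n), group = g, reorder = TRUE) / cnt
        ap <- array(M, dim = c(length(cnt), dp[2], dp[3]))
        a <- aperm(ap, order(perm))
    }
    VoxelVolume(a, v@spacing * factor, v@timepoint)
}

#' Adaptive local-mean binarization
#'
#' A voxel is foreground iff its intensity is at least
#' \code{c * localMean} with \code{c = 2 * (1 - sensitivity)}; ties count as
#' foreground (judged with a 1e-9 relative tolerance, so exact rational ties
#' are stable under floating-point summation order). The local mean is a
#' separable box filter over \code{window}
#' with edge replication. Higher sensitivity lowers the factor \code{c} and
#' can only grow the foreground set (monotonicity). The default sensitivity
#' of 0.4 is the standard setting for embryo surface extraction; the default
#' window per axis is the smallest odd integer >= axis_length / 8, i.e.
#' local statistics at embryo scale.
#'
#' @param v a [VoxelVolume-class] (typically binned first).
#' @param sensitivity in \code{[0, 1]}.
#' @param window odd integer(3) box size per axis, or \code{NULL} for the
#'   default; each entry must be odd, >= 3 and <= the axis length.
#' @return A [BinaryMask-class] with the volume's spacing.
#' @export
adaptiveBinarize <- function(v, sensitivity = 0.4, window = NULL) {
    stopifnot(is(v, "VoxelVolume"))
    if (length(v@data) == 0L) .stopf("cannot binarize an empty volume")
    if (sensitivity < 0 || sensitivity > 1)
        .stopf("sensitivity must lie in [0, 1]")
    d <- dim(v@data)
    if (is.null(window)) {
        window <- vapply(d, function(n) {
            w <- max(3L, as.integer(ceiling(n / 8)))
            w <- if (w %% 2L == 0L) w + 1L else w
            min(w, if (n %% 2L == 1L) n else n - 1L)
        }, integer(1))
        window <- pmax(window, 3L)
    }
    window <- as.integer(rep(window, length.out = 3L))
    if (any(window %% 2L == 0L)) .stopf("window sizes must be odd")
    if (any(window < 3L) || any(window > d))
        .stopf("window must be >= 3 and <= the axis length on every axis")
    cc <- 2 * (1 - sensitivity)
    lm <- .box_mean3(v@data, window)
    thr <- cc * lm
    ## ties count as foreground; judge them with a 1e-9 relative tolerance
    ## so exact mathematical ties survive floating-point summation order
    fg <- (v@data - thr) >= -1e-9 * (abs(thr) + 1)
    new("BinaryMask", data = array(fg, dim = d), spacing = v@spacing)
}

#' Extract the surface point cloud of a binary mask
#'
#' Keeps the largest 26-connected foreground component and returns the
#' physical (um) coordinates of its boundary voxels — foreground voxels with
#' at least one background 6-neighbour, where the volume border counts as
#' background. This voxel-based isosurface is all the downstream sphere fit
#' needs; no mesh is triangulated.
#'
#' @param m a [BinaryMask-class] with at least one foreground voxel.
#' @return A [SurfacePointCloud-class] (provenance \code{"boundary_voxels"}).
#' @export
extractSurface <- function(m) {
    stopifnot(is(m, "BinaryMask"))
    if (!any(m@data)) .stopf("mask has no foreground voxels")
    d <- dim(m@data)
    comp <- .cpp_largest_component26(m@data, d)
    bnd <- .cpp_boundary6(comp, d)
    idx <- .linear_to_triple(which(bnd), d)
    new("SurfacePointCloud", points = .voxel_to_um(idx, m@spacing),
        provenance = "boundary_voxels")
}

#' Algebraic linear least-squares sphere fit
#'
#' Fits a sphere to a point cloud by solving the linear system
#' \code{x^2 + y^2 + z^2 = 2 a x + 2 b y + 2 c z + d} for \code{(a, b, c, d)}
#' in the least-squares sense; the centre is \code{(a, b, c)} and the radius
#' \code{sqrt(a^2 + b^2 + c^2 + d)}. The fit is exact (to numerical
#' round-off) on noiseless sphere samples and equivariant under rigid
#' translation of the cloud. Degenerate inputs — fewer than 4 points,
#' coplanar points (rank-deficient design matrix) or a non-positive fitted
#' squared radius — raise an error naming the degeneracy.
#'
#' @param pc a [SurfacePointCloud-class] or a numeric matrix with columns
#'   (z, y, x) in um.
#' @return A [SphereModel-class]; \code{rmsResidual} is the rms of
#'   \code{|p - center| - radius} over the points used.
#' @examples
#' pts <- rbind(c(40, -5, 2.5), c(-20, -5, 2.5), c(10, 25, 2.5),
#'              c(10, -35, 2.5), c(10, -5, 32.5), c(10, -5, -27.5))
#' fitSphere(pts)   # centre (10, -5, 2.5), radius 30, exactly
#' @export
fitSphere <- function(pc) {
    p <- if (is(pc, "SurfacePointCloud")) pc@points else as.matrix(pc)
    if (nrow(p) < 4L)
        .stopf("sphere fit needs at least 4 points, got %d", nrow(p))
    A <- cbind(2 * p, 1)
    b <- rowSums(p^2)
    qrA <- qr(A)
    if (qrA$rank < 4L)
        .stopf(paste0("degenerate point cloud (rank %d design matrix): ",
                      "points are coplanar or otherwise do not determine ",
                      "a sphere"), qrA$rank)
    beta <- qr.coef(qrA, b)
    center <- beta[1:3]
    r2 <- sum(center^2) + beta[4]
    if (!is.finite(r2) || r2 <= 0)
        .stopf("degenerate fit: non-positive squared radius (%g)", r2)
    radius <- sqrt(r2)
    res <- sqrt(rowSums(sweep(p, 2L, center)^2)) - radius
    new("SphereModel", center = unname(center), radius = unname(radius),
        rmsResidual = sqrt(mean(res^2)), nPoints = nrow(p))
}

#' One-call embryo surface estimation
#'
#' The standard surface pipeline: bin the raw volume (default 4 per axis),
#' adaptively binarize (default sensitivity 0.4), extract the boundary point
#' cloud of the largest component, and fit a sphere by linear least squares.
#'
#' @param v raw [VoxelVolume-class].
#' @param binning integer(3) binning factor.
#' @param sensitivity adaptive-threshold sensitivity.
#' @param window optional binarization window (see [adaptiveBinarize()]).
#' @return A [SphereModel-class].
#' @export
estimateSurface <- function(v, binning = c(4L, 4L, 4L), sensitivity = 0.4,
                            window = NULL) {
    b <- binVolume(v, binning)
    m <- adaptiveBinarize(b, sensitivity, window)
    fitSphere(extractSurface(m))
}
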