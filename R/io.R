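#' Read and write volumes as multi-page 32-bit TIFF
#'
#' Volumes are stored as multi-page 32-bit TIFF (one page per z plane,
#' deflate-compressed). The TIFF library quantizes samples onto a 32-bit
#' integer grid, so intensities are written as explicit fixed-point values:
#' \code{v = round(intensity / step)} with a power-of-two \code{step} chosen
#' so the full intensity range fits the 32 bits. The step, voxel spacing
#' (um), axis order and timepoint live in a JSON sidecar next to the image
#' (\code{<file>.tif} + \code{<file>.json}). Integer-valued intensities
#' (e.g. photon counts) round-trip exactly; arbitrary intensities are
#' quantized at \code{step/2}, about 1e-10 of the intensity range.
#'
#' Physical spacing is mandatory: a TIFF without a sidecar can only be read
#' with an explicit \code{spacing} argument — there is no silent default.
#'
#' @param v a [VoxelVolume-class].
#' @param path path of the \code{.tif} file.
#' @param spacing optional numeric(3) um override (required for plain TIFFs
#'   without a sidecar).
#' @return \code{writeVolume}: the path, invisibly; \code{readVolume}: a
#'   [VoxelVolume-class].
#' @export
writeVolume <- function(v, path) {
    stopifnot(is(v, "VoxelVolume"))
    d <- dim(v@data)
    q <- 4294967295                     # 2^32 - 1 sample levels
    mx <- if (length(v@data)) max(v@data) else 0
    p <- if (mx > 0) ceiling(log2(mx / q)) else 0
    step <- 2^p
    ## the writer truncates x * (2^32 - 1); centring each code on its bin
    ## ((v + 0.5) / q) makes the stored integer exactly v
    pages <- lapply(seq_len(d[1]), function(i)
        matrix((round(v@data[i, , ] / step) + 0.5) / q, d[2], d[3]))
    tryCatch(
        tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                        compression = "deflate", reduce = FALSE),
        error = function(e) .stopf("cannot write volume to '%s': %s",
                                   path, conditionMessage(e)))
    meta <- list(axis_order = "zyx", shape = d, spacing_um = v@spacing,
                 intensity_step_log2 = p, timepoint = v@timepoint)
    jsonlite::write_json(meta, .sidecar_path(path), digits = NA,
                         auto_unbox = TRUE)
    invisible(path)
}

.sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' @rdname writeVolume
#' @export
readVolume <- function(path, spacing = NULL) {
    if (!file.exists(path)) .stopf("volume file '%s' does not exist", path)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
        error = function(e) .stopf("cannot read volume from '%s': %s",
                                   path, conditionMessage(e)))
    if (is.matrix(pages) || !is.list(pages)) pages <- list(pages)
    step <- NULL
    tp <- NA_character_
    sc <- .sidecar_path(path)
    if (file.exists(sc)) {
        meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
        if (is.null(spacing)) spacing <- as.numeric(meta$spacing_um)
        if (!is.null(meta$intensity_step_log2))
            step <- 2^as.numeric(meta$intensity_step_log2)
        if (!is.null(meta$timepoint) && !is.na(meta$timepoint))
            tp <- as.character(meta$timepoint)
    }
    if (is.null(spacing))
        .stopf(paste0("'%s' carries no voxel spacing (no sidecar '%s') and ",
                      "no 'spacing' override was given; physical spacing in ",
                      "um is mandatory"), path, sc)
    d2 <- dim(pages[[1]])
    arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    if (!is.null(step)) {
        ## undo the fixed-point encoding: the reader returns k / 2^32
        arr <- round(arr * 4294967296) * step
    }
    VoxelVolume(arr, as.numeric(spacing), tp)
}

#' Serialize a sphere model to JSON
#'
#' Writes \code{\{center_um, radius_um, rms_residual_um, n_points\}}.
#'
#' @param sphere a [SphereModel-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSphereModel <- function(sphere, path) {
    jsonlite::write_json(
        list(center_um = sphere@center, radius_um = sphere@radius,
             rms_residual_um = sphere@rmsResidual,
             n_points = sphere@nPoints),
        path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeSphereModel
#' @export
readSphereModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("SphereModel", center = as.numeric(x$center_um),
        radius = as.numeric(x$radius_um),
        rmsResidual = as.numeric(x$rms_residual_um),
        nPoints = as.integer(x$n_points))
}
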