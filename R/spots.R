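#' Subtract the slowly varying baseline of a volume
#'
#' Estimates the baseline as a Gaussian blur of the volume at scale
#' \code{backgroundSigma} (um, converted per axis to voxels; reflective
#' boundaries) and subtracts it, clipping at zero. The output is therefore
#' everywhere >= 0 and <= the input. Choosing a sigma several times the spot
#' width removes background and slow shading while attenuating genuine
#' spots only marginally. A sigma below one voxel on every axis is almost a
#' no-op and triggers a warning (not an error).
#'
#' @param v a [VoxelVolume-class].
#' @param backgroundSigma baseline scale in um, > 0.
#' @return The baseline-subtracted [VoxelVolume-class].
#' @export
subtractBaseline <- function(v, backgroundSigma) {
    stopifnot(is(v, "VoxelVolume"))
    if (backgroundSigma <= 0) .stopf("backgroundSigma must be positive")
    sig_vox <- backgroundSigma / v@spacing
    if (all(sig_vox < 1))
        warning(sprintf(
            "backgroundSigma (%g um) is below one voxel on every axis; %s",
            backgroundSigma, "baseline subtraction will remove little"),
            call. = FALSE)
    d <- dim(v@data)
    bl <- .cpp_gaussian_blur3(v@data, d, sig_vox)
    out <- v@data - bl
    out[out < 0] <- 0
    VoxelVolume(array(out, dim = d), v@spacing, v@timepoint)
}

## greedy physical-distance suppression: peaks arrive ordered by priority;
## keep a peak iff it is >= minsep away from every peak kept so far
.greedy_suppress <- function(pts, minsep) {
    n <- nrow(pts)
    if (n <= 1L || minsep <= 0) return(rep(TRUE, n))
    keep <- logical(n)
    kept <- matrix(numeric(0), 0L, 3L)
    ms2 <- minsep^2
    for (i in seq_len(n)) {
        if (nrow(kept)) {
            d2 <- (kept[, 1] - pts[i, 1])^2 + (kept[, 2] - pts[i, 2])^2 +
                  (kept[, 3] - pts[i, 3])^2
            if (min(d2) < ms2) next
        }
        keep[i] <- TRUE
        kept <- rbind(kept, pts[i, , drop = FALSE])
    }
    keep
}

#' Detect fluorescent spots in a volume
#'
#' The automated cell-picking workflow: (1) subtract the baseline at scale
#' \code{backgroundSigma}; (2) find 26-neighbourhood local maxima with
#' baseline-subtracted value >= \code{detectionThreshold}; (3) order peaks
#' by descending intensity (ties broken by ascending (z, y, x) voxel index)
#' and greedily enforce the physical \code{minSeparation}; (4) refine each
#' surviving peak by the intensity-weighted centroid of the subtracted
#' volume in a +/- 2 \code{expectedSpotSigma} window. Should refinement pull
#' two centroids closer than \code{minSeparation}, the lower-priority one is
#' dropped, so the separation invariant holds exactly on the output. An
#' empty result is valid, not an error.
#'
#' @param v a [VoxelVolume-class].
#' @param params a [SpotParams-class].
#' @param timepoint,condition optional labels carried into the result.
#' @return A [SpotSet-class] with centroids in um (z, y, x) and
#'   baseline-subtracted peak intensities, ordered by descending peak.
#' @export
detectSpots <- function(v, params = SpotParams(),
                        timepoint = NULL, condition = NA_character_) {
    stopifnot(is(v, "VoxelVolume"), is(params, "SpotParams"))
    if (is.null(timepoint)) timepoint <- timepoint(v)
    sub <- subtractBaseline(v, params@backgroundSigma)
    d <- dim(sub@data)
    lin <- .cpp_local_maxima26(sub@data, d, params@detectionThreshold)
    empty <- new("SpotSet",
        centroids = matrix(numeric(0), 0L, 3L), peakIntensities = numeric(0),
        timepoint = as.character(timepoint), condition = as.character(condition),
        minSeparation = params@minSeparation)
    if (!length(lin)) return(empty)

    idx <- .linear_to_triple(lin, d)
    vals <- sub@data[lin]
    ## priority: descending peak value, ties by lexicographic (z, y, x)
    ord <- order(-vals, idx[, 1], idx[, 2], idx[, 3])
    idx <- idx[ord, , drop = FALSE]
    vals <- vals[ord]
    pts <- .voxel_to_um(idx, sub@spacing)
    keep <- .greedy_suppress(pts, params@minSeparation)
    idx <- idx[keep, , drop = FALSE]
    vals <- vals[keep]
    if (!nrow(idx)) return(empty)

    ## intensity-weighted centroid refinement in +/- 2 sigma windows
    hw <- pmax(1L, as.integer(ceiling(2 * params@expectedSpotSigma /
                                      sub@spacing)))
    cents <- matrix(0, nrow(idx), 3L)
    for (i in seq_len(nrow(idx))) {
        rng <- lapply(1:3, function(ax)
            max(1L, idx[i, ax] - hw[ax]):min(d[ax], idx[i, ax] + hw[ax]))
        w <- sub@data[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
        tw <- sum(w)
        if (tw <= 0) {
            cents[i, ] <- (idx[i, ] - 1) * sub@spacing
        } else {
            wz <- apply(w, 1L, sum); wy <- apply(w, 2L, sum)
            wx <- apply(w, 3L, sum)
            cents[i, ] <- c(
                sum((rng[[1]] - 1) * sub@spacing[1] * wz),
                sum((rng[[2]] - 1) * sub@spacing[2] * wy),
                sum((rng[[3]] - 1) * sub@spacing[3] * wx)) / tw
        }
    }
    ## refinement may have moved centroids: re-enforce the separation
    keep2 <- .greedy_suppress(cents, params@minSeparation)
    new("SpotSet", centroids = cents[keep2, , drop = FALSE],
        peakIntensities = vals[keep2],
        timepoint = as.character(timepoint),
        condition = as.character(condition),
        minSeparation = params@minSeparation)
}

#' Count spots inside a physical ROI box
#'
#' Counts centroids with \code{lo <= p < hi} on every axis. The
#' inclusive-lo / exclusive-hi rule makes counts over boxes that partition
#' space exactly additive.
#'
#' @param s a [SpotSet-class].
#' @param roi an [ROIBox-class].
#' @return Integer count.
#' @export
countInROI <- function(s, roi) {
    stopifnot(is(s, "SpotSet"), is(roi, "ROIBox"))
    if (!nrow(s@centroids)) return(0L)
    sum(.in_box(s@centroids, roi@lo, roi@hi))
}

#' Quantify a time course of volumes into a count table
#'
#' Runs [detectSpots()] and [countInROI()] on every volume of a (typically
#' [generateTimecourse()]-produced) record list and assembles one row per
#' embryo x timepoint x ROI. A \code{"whole"} ROI covering the full volume
#' is always included, and counts are reported per embryo, never pooled.
#'
#' @param records list of records, each a list with elements \code{volume}
#'   (a [VoxelVolume-class]), \code{timepoint}, \code{condition} and
#'   optionally \code{embryo_id} (default \code{embryo<k>}).
#' @param params a [SpotParams-class].
#' @param rois list of [ROIBox-class] counted in addition to \code{"whole"}.
#' @return A \code{data.frame} with columns \code{embryo_id},
#'   \code{condition}, \code{timepoint}, \code{roi}, \code{count} — the
#'   CSV-ready count table. Duplicate (embryo, timepoint, condition) labels
#'   are an error; an empty record list gives an empty table.
#' @export
quantifyTimecourse <- function(records, params = SpotParams(), rois = list()) {
    cols <- c("embryo_id", "condition", "timepoint", "roi", "count")
    if (!length(records)) {
        out <- data.frame(embryo_id = character(), condition = character(),
                          timepoint = character(), roi = character(),
                          count = integer())
        return(out[cols])
    }
    ids <- vapply(seq_along(records), function(k) {
        r <- records[[k]]
        id <- if (!is.null(r$embryo_id)) r$embryo_id else paste0("embryo", k)
        paste(id, r$timepoint, r$condition, sep = "\r")
    }, character(1))
    if (anyDuplicated(ids))
        .stopf("duplicate (embryo_id, timepoint, condition) labels in records")

    rows <- list()
    for (k in seq_along(records)) {
        r <- records[[k]]
        id <- if (!is.null(r$embryo_id)) r$embryo_id else paste0("embryo", k)
        spots <- detectSpots(r$volume, params,
                             timepoint = as.character(r$timepoint),
                             condition = as.character(r$condition))
        counts <- c(whole = length(spots),
                    vapply(rois, function(b) countInROI(spots, b),
                           integer(1)))
        names(counts) <- c("whole", vapply(rois, function(b) b@name,
                                           character(1)))
        rows[[k]] <- data.frame(
            embryo_id = id, condition = as.character(r$condition),
            timepoint = as.character(r$timepoint), roi = names(counts),
            count = as.integer(counts), row.names = NULL)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a count table as CSV
#'
#' One row per embryo x timepoint x ROI, columns \code{embryo_id},
#' \code{condition}, \code{timepoint}, \code{roi}, \code{count}.
#'
#' @param counts the data.frame from [quantifyTimecourse()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeCountTable <- function(counts, path) {
    write.csv(counts, path, row.names = FALSE)
    invisible(path)
}
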