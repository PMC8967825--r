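#' Construct a VoxelVolume
#'
#' @param data numeric 3D array, non-negative, axis order (z, y, x).
#' @param spacing numeric(3) voxel spacing in um (z, y, x).
#' @param timepoint optional label.
#' @return A [VoxelVolume-class].
#' @examples
#' v <- VoxelVolume(array(0, c(4, 4, 4)), spacing = c(2, 1, 1))
#' spacing(v)
#' @export
VoxelVolume <- function(data, spacing, timepoint = NA_character_) {
    new("VoxelVolume", data = data, spacing = as.numeric(spacing),
        timepoint = as.character(timepoint))
}

#' Construct an axis-aligned ROI box
#'
#' Bounds are in um, ordered (z, y, x), inclusive at \code{lo} and exclusive
#' at \code{hi} so that boxes that tile space count each spot exactly once.
#'
#' @param name ROI name.
#' @param lo,hi numeric(3) um bounds, \code{lo < hi} per axis.
#' @return An [ROIBox-class].
#' @examples
#' ROIBox("trunk", lo = c(0, 50, 50), hi = c(100, 150, 150))
#' @export
ROIBox <- function(name, lo, hi) {
    new("ROIBox", name = as.character(name), lo = as.numeric(lo),
        hi = as.numeric(hi))
}

#' Construct spot-detection parameters
#'
#' Defaults suit nucleus-sized fluorescent cells (blob sigma ~3 um) over a
#' dim background: the baseline scale is several cell diameters so that the
#' baseline tracks slow background but not the spots themselves.
#'
#' @param backgroundSigma baseline Gaussian scale, um.
#' @param detectionThreshold minimum baseline-subtracted peak intensity.
#' @param minSeparation minimum physical distance between accepted spots, um.
#' @param expectedSpotSigma expected blob width, um (centroid refinement
#'   window is +/- 2 sigma).
#' @return A [SpotParams-class].
#' @export
SpotParams <- function(backgroundSigma = 15, detectionThreshold = 25,
                       minSeparation = 8, expectedSpotSigma = 3) {
    new("SpotParams", backgroundSigma = backgroundSigma,
        detectionThreshold = detectionThreshold,
        minSeparation = minSeparation,
        expectedSpotSigma = expectedSpotSigma)
}

## deterministic 32-bit stream seed from a base seed and labels;
## simple polynomial rolling hash modulo the Mersenne prime 2^31 - 1
.derive_seed <- function(base_seed, ...) {
    m <- 2147483647
    h <- as.numeric(base_seed) %% m
    for (tok in c(...)) {
        for (code in utf8ToInt(paste0("/", as.character(tok)))) {
            h <- (h * 31 + code) %% m
        }
    }
    as.integer(max(1, h))
}

## running mean along the first axis of a matrix with edge replication
.runmean_first <- function(M, w) {
    n <- nrow(M)
    r <- (w - 1L) %/% 2L
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    P <- M[idx, , drop = FALSE]
    cs <- apply(P, 2L, cumsum)
    cs <- rbind(0, cs)
    (cs[(w + 1L):(w + n), , drop = FALSE] - cs[seq_len(n), , drop = FALSE]) / w
}

## separable local box mean of a 3D array with edge replication
.box_mean3 <- function(a, window) {
    d <- dim(a)
    for (ax in 1:3) {
        w <- as.integer(window[ax])
        if (w <= 1L) next
        perm <- c(ax, setdiff(1:3, ax))
        ap <- aperm(a, perm)
        dp <- dim(ap)
        M <- .runmean_first(matrix(ap, nrow = dp[1]), w)
        ap <- array(M, dim = dp)
        a <- aperm(ap, order(perm))
    }
    a
}

## physical coordinates (um, columns z,y,x) of 1-based voxel indices
.voxel_to_um <- function(idx, spacing) {
    sweep(idx - 1, 2L, spacing, `*`)
}

## convert a linear 1-based index into 1-based (i1, i2, i3) triples
.linear_to_triple <- function(lin, d) {
    lin0 <- lin - 1L
    i1 <- lin0 %% d[1]
    i2 <- (lin0 %/% d[1]) %% d[2]
    i3 <- lin0 %/% (d[1] * d[2])
    cbind(i1, i2, i3) + 1L
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
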