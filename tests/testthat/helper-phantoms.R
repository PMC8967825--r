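# shared helpers: ideal sphere models, map-blob moments, spot matching

sphereModel <- function(center, radius) {
    new("SphereModel", center = as.numeric(center), radius = as.numeric(radius),
        rmsResidual = 0, nPoints = 6L)
}

# intensity-weighted centroid + principal second moments of a map image;
# returns list(aspect, size) with size = (l1 * l2)^(1/4) in pixels
blobMoments <- function(m) {
    w <- m / sum(m)
    ri <- row(m); ci <- col(m)
    mu_r <- sum(w * ri); mu_c <- sum(w * ci)
    vrr <- sum(w * (ri - mu_r)^2)
    vcc <- sum(w * (ci - mu_c)^2)
    vrc <- sum(w * (ri - mu_r) * (ci - mu_c))
    ev <- eigen(matrix(c(vrr, vrc, vrc, vcc), 2L), symmetric = TRUE)$values
    list(aspect = sqrt(ev[1] / ev[2]), size = (ev[1] * ev[2])^0.25,
         center = c(mu_r, mu_c))
}

# recall/precision of detected centroids vs ground-truth positions
matchSpots <- function(detected, truth, radius) {
    if (!nrow(detected) || !nrow(truth))
        return(list(recall = 0, precision = 0))
    d2 <- outer(rowSums(detected^2), rowSums(truth^2), `+`) -
        2 * detected %*% t(truth)
    list(recall = mean(apply(d2, 2L, min) <= radius^2),
         precision = mean(apply(d2, 1L, min) <= radius^2))
}

# brute-force local box mean with edge replication (oracle for binarization)
bruteLocalMean <- function(a, window) {
    d <- dim(a)
    r <- (window - 1L) %/% 2L
    out <- array(0, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        ii <- pmin(pmax(i + (-r[1]):r[1], 1L), d[1])
        jj <- pmin(pmax(j + (-r[2]):r[2], 1L), d[2])
        kk <- pmin(pmax(k + (-r[3]):r[3], 1L), d[3])
        out[i, j, k] <- mean(a[ii, jj, kk])
    }
    out
}
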