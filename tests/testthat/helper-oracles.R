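# Independent brute-force references used across the tests. These
# deliberately re-derive quantities from first principles (dense sweeps,
# exhaustive enumeration) rather than calling the package's production
# code paths.

# dense angle-sweep minimum/maximum projection width of a point cloud
sweepWidthPoints <- function(pts, stepDeg = 0.1) {
    th <- seq(0, 180 - stepDeg, by = stepDeg) * pi / 180
    w <- vapply(th, function(a) {
        pr <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
        max(pr) - min(pr)
    }, numeric(1))
    c(min = min(w), max = max(w))
}

# exact brute-force minimum width: the minimum width of a point set is
# attained with a supporting line flush with a hull edge, i.e. parallel to
# some pair of input points, so enumerating every pairwise direction and
# measuring the perpendicular projection width is exhaustive and exact
exactMinWidthPairs <- function(pts) {
    hp <- pts[grDevices::chull(pts), , drop = FALSE]
    n <- nrow(hp)
    best <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        e <- hp[j, ] - hp[i, ]
        len <- sqrt(sum(e^2))
        if (len == 0) next
        nrm <- c(-e[2], e[1]) / len
        pr <- hp[, 1] * nrm[1] + hp[, 2] * nrm[2]
        best <- min(best, max(pr) - min(pr))
    }
    best
}

# pixel-corner cloud of a 0/1 matrix at given spacing
cornerCloud <- function(m, spacing = c(1, 1)) {
    idx <- which(m == 1L, arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    pts <- unique(cbind(c(i - 1, i, i - 1, i), c(j - 1, j - 1, j, j)))
    cbind(pts[, 1] * spacing[1], pts[, 2] * spacing[2])
}

# exhaustive Otsu: try every histogram cut, recompute class stats directly
otsuExhaustive <- function(v, nbins = 256L) {
    breaks <- seq(min(v), max(v), length.out = nbins + 1L)
    bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    centers <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
    best <- -Inf; bestT <- NA
    for (t in seq_len(nbins - 1L)) {
        lo <- bin <= t
        n0 <- sum(lo); n1 <- length(v) - n0
        if (n0 == 0L || n1 == 0L) sb <- 0
        else {
            mu0 <- mean(centers[bin[lo]])
            mu1 <- mean(centers[bin[!lo]])
            sb <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
        }
        if (sb > best + 1e-15) { best <- sb; bestT <- t }
    }
    breaks[bestT + 1L]
}

# random convex polygon: convex hull of random points
randomConvexPolygon <- function(n = 12, scale = 10) {
    pts <- matrix(stats::runif(2 * n, -scale, scale), ncol = 2)
    pts[grDevices::chull(pts), , drop = FALSE]
}

# rasterise a rectangle of size a x b rotated by angle (degrees), centred
# in an n x n grid; pixel centre inside the rectangle -> foreground
rasterRotRect <- function(a, b, angleDeg, n = 64) {
    th <- angleDeg * pi / 180
    cx <- n / 2; cy <- n / 2
    xs <- (seq_len(n) - 0.5) - cx
    ys <- (seq_len(n) - 0.5) - cy
    X <- matrix(xs, n, n)
    Y <- matrix(rep(ys, each = n), n, n)
    u <- X * cos(th) + Y * sin(th)
    v <- -X * sin(th) + Y * cos(th)
    (abs(u) <= a / 2 & abs(v) <= b / 2) * 1L
}

# soft Dice on probabilities, the algebraic reference for the Tversky
# identity check
softDice <- function(p, g) {
    2 * sum(p * g) / (sum(p) + sum(g))
}
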