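#' @importFrom grDevices chull
NULL

# corner cloud of a 2D mask: each foreground pixel contributes the 4
# corners of its unit square, scaled to mm (pixel-as-area model, so a
# w-pixel-wide bar measures w mm at 1 mm spacing).
maskCornerPoints <- function(maskData, spacingMM) {
    idx <- which(maskData == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
    i <- idx[, 1]; j <- idx[, 2]
    pts <- cbind(c(i - 1, i, i - 1, i), c(j - 1, j - 1, j, j))
    pts <- unique(pts)
    cbind(pts[, 1] * spacingMM[1], pts[, 2] * spacingMM[2])
}

.asMask2d <- function(mask) {
    if (is(mask, "VoxelMask")) {
        if (length(dim(mask@data)) != 2L)
            stop("expected a 2D mask", call. = FALSE)
        list(data = mask@data, spacing = mask@spacing)
    } else if (is.matrix(mask)) {
        list(data = mask, spacing = NULL)
    } else stop("mask must be a VoxelMask or a matrix", call. = FALSE)
}

# label 2D connected components (8-connectivity), small and dependency-free;
# segmentation-scale labelling goes through EBImage::bwlabel instead.
labelComponents8 <- function(m) {
    lab <- matrix(0L, nrow(m), ncol(m))
    cur <- 0L
    todo <- which(m == 1L & lab == 0L)
    nr <- nrow(m); nc <- ncol(m)
    while (length(todo)) {
        cur <- cur + 1L
        stack <- todo[1L]
        lab[stack] <- cur
        while (length(stack)) {
            p <- stack[length(stack)]; stack <- stack[-length(stack)]
            i <- ((p - 1L) %% nr) + 1L; j <- ((p - 1L) %/% nr) + 1L
            for (di in -1:1) for (dj in -1:1) {
                ii <- i + di; jj <- j + dj
                if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
                    q <- (jj - 1L) * nr + ii
                    if (m[q] == 1L && lab[q] == 0L) {
                        lab[q] <- cur
                        stack <- c(stack, q)
                    }
                }
            }
        }
        todo <- which(m == 1L & lab == 0L)
    }
    lab
}

#' Minimum Feret diameter of a 2D mask (rotating calipers)
#'
#' The minimum over directions of the distance between two parallel
#' supporting lines of the shape. Pixels are treated as unit squares (the
#' four corners of every foreground pixel form the point cloud), the convex
#' hull is taken, and the minimum width is found flush with a hull edge
#' (rotating-calipers property), so the result is exact for the corner
#' cloud.
#'
#' @param mask a 2D \linkS4class{VoxelMask}, or a 0/1 matrix with
#'   \code{spacingMM} supplied.
#' @param spacingMM numeric(2) mm per pixel (taken from the VoxelMask when
#'   omitted).
#' @return thickness in mm.
#' @export
minFeretDiameter <- function(mask, spacingMM = NULL) {
    m <- .asMask2d(mask)
    sp <- if (is.null(spacingMM)) m$spacing else rep(spacingMM, length.out = 2)
    if (is.null(sp)) stop("spacingMM required for matrix input", call. = FALSE)
    if (sum(m$data) == 0L) stop("empty mask", call. = FALSE)
    if (max(labelComponents8(m$data)) > 1L)
        stop("mask has multiple connected components; clean it first",
             call. = FALSE)
    pts <- maskCornerPoints(m$data, sp)
    minWidthHull(pts)
}

# exact minimum width of a point set: min over hull edges of the maximum
# distance of hull vertices from the edge's supporting line.
minWidthHull <- function(pts) {
    h <- chull(pts)
    hp <- pts[h, , drop = FALSE]
    n <- nrow(hp)
    if (n < 3L) return(0)
    best <- Inf
    for (k in seq_len(n)) {
        a <- hp[k, ]; b <- hp[if (k == n) 1L else k + 1L, ]
        e <- b - a
        len <- sqrt(sum(e^2))
        if (len == 0) next
        nrm <- c(-e[2], e[1]) / len
        d <- abs((hp[, 1] - a[1]) * nrm[1] + (hp[, 2] - a[2]) * nrm[2])
        best <- min(best, max(d))
    }
    best
}

#' Maximum Feret diameter of a 2D mask
#'
#' Maximum over directions of the projection width; equals the hull
#' diameter (largest pairwise vertex distance) of the pixel corner cloud.
#'
#' @inheritParams minFeretDiameter
#' @return diameter in mm.
#' @export
maxFeretDiameter <- function(mask, spacingMM = NULL) {
    m <- .asMask2d(mask)
    sp <- if (is.null(spacingMM)) m$spacing else rep(spacingMM, length.out = 2)
    if (sum(m$data) == 0L) stop("empty mask", call. = FALSE)
    pts <- maskCornerPoints(m$data, sp)
    hp <- pts[chull(pts), , drop = FALSE]
    sqrt(max(as.vector(stats::dist(hp))^2))
}

#' Dense angle-sweep Feret widths
#'
#' Brute-force reference: sweeps directions in [0, 180) degrees at the
#' given step, projecting the pixel corner cloud onto each direction, and
#' reports the minimum and maximum width over the sweep. Used to verify
#' phantom construction; the rotating-calipers path is the production
#' implementation.
#'
#' @inheritParams minFeretDiameter
#' @param stepDeg angular step in degrees (default 0.1).
#' @return named numeric: \code{min}, \code{max} (mm).
#' @export
feretDiameterSweep <- function(mask, spacingMM = NULL, stepDeg = 0.1) {
    m <- .asMask2d(mask)
    sp <- if (is.null(spacingMM)) m$spacing else rep(spacingMM, length.out = 2)
    if (sum(m$data) == 0L) stop("empty mask", call. = FALSE)
    pts <- maskCornerPoints(m$data, sp)
    hp <- pts[chull(pts), , drop = FALSE]   # hull only, same widths
    th <- seq(0, pi, by = stepDeg * pi / 180)
    th <- th[th < pi]
    widths <- vapply(th, function(a) {
        pr <- hp[, 1] * cos(a) + hp[, 2] * sin(a)
        max(pr) - min(pr)
    }, numeric(1))
    c(min = min(widths), max = max(widths))
}

#' Cross-sectional area of a 2D mask
#'
#' @inheritParams minFeretDiameter
#' @return area in mm^2 (foreground pixel count times pixel area).
#' @export
crossSectionalArea <- function(mask, spacingMM = NULL) {
    m <- .asMask2d(mask)
    sp <- if (is.null(spacingMM)) m$spacing else rep(spacingMM, length.out = 2)
    if (is.null(sp)) stop("spacingMM required for matrix input", call. = FALSE)
    sum(m$data == 1L) * prod(sp[1:2])
}

#' Measure a left/right muscle pair at the selected slice
#'
#' Computes per-side minimum Feret thickness (TMT) and cross-sectional
#' area, and the bilateral mean: the two sides are averaged when both are
#' present; a single present side is reported as the mean with a flag.
#'
#' @param left,right 2D \linkS4class{VoxelMask} per side (may be empty).
#' @param spacingMM numeric(2) mm per pixel.
#' @param sliceIndex axial index the masks come from.
#' @return a \linkS4class{MusclePairMeasurement}.
#' @export
measureMusclePair <- function(left, right, spacingMM, sliceIndex = NA_integer_) {
    sideMeasure <- function(mask, name) {
        dat <- .asMask2d(mask)$data
        if (sum(dat) == 0L)
            return(list(tmt = NA_real_, csa = NA_real_,
                        flag = paste0(name, "_missing")))
        list(tmt = minFeretDiameter(mask, spacingMM),
             csa = crossSectionalArea(mask, spacingMM), flag = NULL)
    }
    l <- sideMeasure(left, "left")
    r <- sideMeasure(right, "right")
    present <- c(l$tmt, r$tmt)
    present <- present[!is.na(present)]
    if (length(present) == 0L)
        stop("both sides empty: nothing to measure", call. = FALSE)
    new("MusclePairMeasurement",
        tmtLeftMM = l$tmt, tmtRightMM = r$tmt,
        tmtMeanMM = mean(present),
        csaLeftMM2 = l$csa, csaRightMM2 = r$csa,
        sliceIndex = as.integer(sliceIndex),
        flags = as.character(c(l$flag, r$flag)))
}
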