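#' Focal Tversky loss on soft predictions
#'
#' Tversky index TI = (TP + s) / (TP + alpha*FN + beta*FP + s) with soft
#' counts TP = sum(p*g), FN = sum((1-p)*g), FP = sum(p*(1-g)) and a small
#' smoothing term s; the loss is (1 - TI)^(1/gamma). With
#' alpha = beta = 0.5 and gamma = 1 it reduces to 1 minus the soft Dice
#' coefficient. alpha > beta penalises missed muscle (false negatives)
#' harder, which suits thin structures.
#'
#' @param predProbs numeric array of probabilities in [0, 1].
#' @param truthMask 0/1 array of the same shape.
#' @param params list(alpha, beta, gamma); defaults 0.7 / 0.3 / 4/3.
#' @param smooth smoothing term (default 1e-7).
#' @return scalar loss in [0, 1].
#' @export
focalTverskyLoss <- function(predProbs, truthMask,
                             params = list(alpha = 0.7, beta = 0.3,
                                           gamma = 4 / 3),
                             smooth = 1e-7) {
    if (!all(dim(predProbs) == dim(truthMask)) ||
        length(predProbs) != length(truthMask))
        stop("shape mismatch between prediction and truth", call. = FALSE)
    if (any(predProbs < -1e-12) || any(predProbs > 1 + 1e-12))
        stop("predictions must lie in [0, 1]", call. = FALSE)
    stopifnot(params$alpha >= 0, params$beta >= 0, params$gamma > 0)
    p <- as.numeric(predProbs); g <- as.numeric(truthMask)
    tp <- sum(p * g)
    fn <- sum((1 - p) * g)
    fp <- sum(p * (1 - g))
    ti <- (tp + smooth) / (tp + params$alpha * fn + params$beta * fp + smooth)
    (1 - ti)^(1 / params$gamma)
}

#' Construct an overlapping-tile layout with verified vote coverage
#'
#' Places four square tiles shifted symmetrically by (+/-d, +/-d) around
#' the region of interest. The tile side must be at least the ROI side plus
#' 2d so that every ROI pixel falls inside at least three tiles; coverage
#' is counted exhaustively, never assumed, and a layout that leaves any ROI
#' pixel under-covered is rejected with the uncovered pixel count.
#'
#' @param roi integer c(x, y, width, height): region that must be covered
#'   (1-based top-left).
#' @param tileSize side length of each square tile.
#' @param nTiles number of tiles (the implemented layout uses 4).
#' @param shift half-offset d between tiles; default
#'   \code{min(floor(tileSize/8), floor((tileSize - max(w, h)) / 2))}.
#' @return object of class \code{TileLayout}: list with \code{windows}
#'   (list of c(x, y, w, h)), \code{shift}, \code{roi} and the exhaustive
#'   \code{coverage} count matrix.
#' @export
makeVoteTiles <- function(roi, tileSize, nTiles = 4L, shift = NULL) {
    stopifnot(length(roi) == 4L, roi[3] >= 1, roi[4] >= 1)
    if (nTiles != 4L)
        stop("the vote layout uses 4 tiles", call. = FALSE)
    if (is.null(shift))
        shift <- max(0L, min(tileSize %/% 8L,
                             (tileSize - max(roi[3], roi[4])) %/% 2L))
    shift <- as.integer(shift)
    # base window centred on the ROI
    bx <- roi[1] + (roi[3] - tileSize) %/% 2L
    by <- roi[2] + (roi[4] - tileSize) %/% 2L
    offs <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)) * shift
    windows <- lapply(seq_len(4L), function(k)
        c(x = bx + offs[k, 1], y = by + offs[k, 2],
          w = tileSize, h = tileSize))
    xs <- roi[1]:(roi[1] + roi[3] - 1L)
    ys <- roi[2]:(roi[2] + roi[4] - 1L)
    coverage <- matrix(0L, roi[3], roi[4])
    for (wn in windows) {
        inX <- xs >= wn["x"] & xs <= wn["x"] + wn["w"] - 1L
        inY <- ys >= wn["y"] & ys <= wn["y"] + wn["h"] - 1L
        coverage <- coverage + outer(inX, inY) * 1L
    }
    bad <- sum(coverage < 3L)
    if (bad > 0L)
        stop("tile layout leaves ", bad,
             " ROI pixel(s) with fewer than 3 votes; reduce the shift or ",
             "enlarge the tiles", call. = FALSE)
    structure(list(windows = windows, shift = shift, roi = roi,
                   coverage = coverage),
              class = "TileLayout")
}

#' Majority vote over a VoteGrid
#'
#' A pixel is positive iff strictly more than half of its cast votes are
#' positive (ties are negative, the conservative choice for thin muscles).
#' Every pixel of the region of interest must have received at least three
#' votes.
#'
#' @param grid a \linkS4class{VoteGrid}.
#' @param roi optional c(x, y, w, h) restricting the coverage requirement
#'   (default: the full grid).
#' @param spacingMM pixel spacing for the output mask.
#' @return a 2D \linkS4class{VoxelMask}.
#' @export
majorityVote <- function(grid, roi = NULL, spacingMM = c(1, 1)) {
    stopifnot(is(grid, "VoteGrid"))
    tot <- grid@totalVotes
    if (is.null(roi)) roi <- c(1L, 1L, nrow(tot), ncol(tot))
    sub <- tot[roi[1]:(roi[1] + roi[3] - 1L), roi[2]:(roi[2] + roi[4] - 1L)]
    if (any(sub < 3L))
        stop("vote coverage below 3 inside the region of interest",
             call. = FALSE)
    m <- (grid@posVotes > tot / 2) * 1L
    VoxelMask(matrix(as.integer(m), nrow(tot), ncol(tot)),
              spacing = spacingMM)
}

#' Split a bilateral mask into left and right sides
#'
#' Connected components are assigned by centroid relative to the image
#' midline along x. Data in canonical RAS orientation store the subject's
#' right at high x (\code{rightIsHighX = TRUE}, the default, which fixes
#' the radiological labelling); a component straddling the midline by more
#' than 25\% of its area triggers a warning and is assigned by centroid.
#'
#' @param mask a 2D \linkS4class{VoxelMask}.
#' @param rightIsHighX side labelling convention flag.
#' @return list(left, right) of 2D \linkS4class{VoxelMask}.
#' @export
splitLeftRight <- function(mask, rightIsHighX = TRUE) {
    stopifnot(is(mask, "VoxelMask"), length(dim(mask@data)) == 2L)
    m <- mask@data
    nx <- nrow(m)
    mid <- (nx + 1) / 2    # midline in pixel-centre coordinates
    lab <- labelComponents8(m)
    left <- matrix(0L, nrow(m), ncol(m))
    right <- matrix(0L, nrow(m), ncol(m))
    for (k in seq_len(max(lab))) {
        sel <- lab == k
        xs <- ((which(sel) - 1L) %% nx) + 1L
        cx <- mean(xs)
        fracHigh <- mean(xs > mid)
        if (min(fracHigh, 1 - fracHigh) > 0.25)
            warning("component ", k, " straddles the midline (",
                    round(100 * min(fracHigh, 1 - fracHigh)),
                    "% across); assigned by centroid", call. = FALSE)
        isHigh <- cx > mid
        isRight <- xor(isHigh, !rightIsHighX)
        if (isRight) right[sel] <- 1L else left[sel] <- 1L
    }
    list(left = VoxelMask(left, spacing = mask@spacing),
         right = VoxelMask(right, spacing = mask@spacing))
}

#' @describeIn predictProbs function-wrapped (oracle) segmenter.
#' @export
setMethod("predictProbs", "FunctionSegmenter", function(model, tile) {
    p <- model@fn(tile)
    if (!all(dim(p) == dim(tile)))
        stop("segmenter returned wrong shape", call. = FALSE)
    p
})

#' Oracle segmenter backed by a known probability map
#'
#' Builds a \linkS4class{FunctionSegmenter} that looks up a fixed
#' probability image using the tile window attached by
#' \code{\link{segmentMuscles}} (pixels outside the map are 0). Optional
#' salt-and-pepper corruption flips each pixel's probability with rate
#' \code{noiseRate} independently per tile prediction, for studying how
#' majority voting denoises.
#'
#' @param probs probability matrix in the segmentation working resolution.
#' @param noiseRate per-pixel corruption probability (default 0).
#' @return a \linkS4class{FunctionSegmenter}.
#' @export
oracleSegmenter <- function(probs, noiseRate = 0) {
    force(probs); force(noiseRate)
    new("FunctionSegmenter", fn = function(tile) {
        wn <- attr(tile, "window")
        out <- matrix(0, nrow(tile), ncol(tile))
        if (is.null(wn)) wn <- c(1L, 1L)
        tx <- seq_len(nrow(tile)) + wn[1] - 1L
        ty <- seq_len(ncol(tile)) + wn[2] - 1L
        okx <- which(tx >= 1L & tx <= nrow(probs))
        oky <- which(ty >= 1L & ty <= ncol(probs))
        out[okx, oky] <- probs[tx[okx], ty[oky]]
        if (noiseRate > 0) {
            flip <- matrix(stats::runif(length(out)) < noiseRate,
                           nrow(out), ncol(out))
            out[flip] <- 1 - out[flip]
        }
        out
    })
}

.resizeMaskNearest <- function(m, nxOut, nyOut) {
    ix <- pmin(pmax(round((seq_len(nxOut) - 0.5) * nrow(m) / nxOut + 0.5), 1),
               nrow(m))
    iy <- pmin(pmax(round((seq_len(nyOut) - 0.5) * ncol(m) / nyOut + 0.5), 1),
               ncol(m))
    m[ix, iy, drop = FALSE]
}

.largestComponent <- function(m) {
    lab <- labelComponents8(m)
    if (max(lab) <= 1L) return(m)
    sizes <- tabulate(lab[lab > 0L])
    (lab == which.max(sizes)) * 1L
}

#' Segment the left and right temporalis muscles on the selected slice
#'
#' The slice is upscaled to the working resolution (512 x 512 by default),
#' predicted four times on overlapping tiles, the binarised predictions
#' (threshold 0.5) are accumulated into a \linkS4class{VoteGrid}, majority
#' voting is applied, the result is split by the midline, the largest
#' connected component is kept per side (8-connectivity), and the masks are
#' mapped back to the native slice resolution. An empty side is flagged,
#' not an error.
#'
#' @param slice numeric matrix: the selected axial slice (preprocessed).
#' @param model a \linkS4class{Segmenter}.
#' @param config list: \code{input_size} (512), \code{shift} (16),
#'   \code{right_is_high_x} (TRUE). See
#'   \code{\link{defaultPipelineConfig}}.
#' @param spacingMM numeric(2) native pixel spacing in mm.
#' @return list with \code{left}, \code{right} (native-resolution
#'   \linkS4class{VoxelMask}), \code{flags} (character), and \code{voteGrid}.
#' @export
segmentMuscles <- function(slice, model,
                           config = defaultPipelineConfig()$segmentation,
                           spacingMM = c(1, 1)) {
    stopifnot(is.matrix(slice))
    Tn <- as.integer(config$input_size)
    d <- as.integer(config$shift)
    up <- EBImage::resize(slice, w = Tn, h = Tn)
    tileSize <- Tn + 2L * d
    layout <- makeVoteTiles(c(1L, 1L, Tn, Tn), tileSize, shift = d)
    pad <- 2L * d
    canvas <- matrix(0, Tn + 2L * pad, Tn + 2L * pad)
    canvas[pad + seq_len(Tn), pad + seq_len(Tn)] <- up
    pos <- matrix(0L, nrow(canvas), ncol(canvas))
    totv <- matrix(0L, nrow(canvas), ncol(canvas))
    for (wn in layout$windows) {
        cx <- wn["x"] + pad; cy <- wn["y"] + pad   # window in canvas coords
        rx <- cx:(cx + wn["w"] - 1L); ry <- cy:(cy + wn["h"] - 1L)
        tile <- canvas[rx, ry]
        attr(tile, "window") <- c(wn[["x"]], wn[["y"]])  # upscaled-slice frame
        pr <- predictProbs(model, tile)
        pos[rx, ry] <- pos[rx, ry] + (pr > 0.5) * 1L
        totv[rx, ry] <- totv[rx, ry] + 1L
    }
    sel <- pad + seq_len(Tn)
    grid <- new("VoteGrid", posVotes = pos[sel, sel],
                totalVotes = totv[sel, sel])
    voted <- majorityVote(grid, spacingMM = spacingMM)
    sides <- splitLeftRight(voted,
        rightIsHighX = !isFALSE(config$right_is_high_x))
    flags <- character()
    out <- list()
    for (sd in c("left", "right")) {
        m <- .largestComponent(sides[[sd]]@data)
        native <- .resizeMaskNearest(m, nrow(slice), ncol(slice))
        if (sum(native) == 0L) flags <- c(flags, paste0(sd, "_missing"))
        out[[sd]] <- VoxelMask(native, spacing = spacingMM)
    }
    list(left = out$left, right = out$right, flags = flags, voteGrid = grid)
}
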