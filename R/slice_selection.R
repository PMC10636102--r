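#' Compute a maximum-intensity-projection slab
#'
#' Pixelwise maximum over an axial slab of the stated physical thickness
#' centred on \code{centerIndex}, resized to the slice-selection model
#' input size. A thickness equal to the slice spacing degenerates to the
#' single resized slice.
#'
#' @param vol an \linkS4class{MRIVolume} (canonical orientation; axial = 3rd
#'   axis).
#' @param centerIndex axial voxel index of the slab centre (1-based).
#' @param thicknessMM slab thickness in mm (default 5, the model input slab).
#' @param inputSize side length of the resized model input (default 256).
#' @return a \linkS4class{MIPSlice}.
#' @export
computeMIP <- function(vol, centerIndex, thicknessMM = 5, inputSize = 256L) {
    stopifnot(is(vol, "MRIVolume"), thicknessMM > 0)
    d <- dim(vol@data)
    sz <- vol@spacing[3]
    nSlices <- max(1L, as.integer(round(thicknessMM / sz)))
    lo <- centerIndex - (nSlices - 1L) %/% 2L
    hi <- lo + nSlices - 1L
    if (lo < 1L || hi > d[3])
        stop("MIP slab [", lo, ", ", hi, "] outside volume (nz = ", d[3], ")",
             call. = FALSE)
    mip <- vol@data[, , lo]
    if (hi > lo) for (k in (lo + 1L):hi) mip <- pmax(mip, vol@data[, , k])
    img <- EBImage::resize(mip, w = inputSize, h = inputSize)
    new("MIPSlice", image = img, centerIndex = as.integer(centerIndex),
        centerZ = (centerIndex - 0.5) * sz, thicknessMM = thicknessMM)
}

#' Build a labelled offset dataset for slice-regressor training
#'
#' One MIP slab per requested offset; the label encodes the signed world-z
#' distance from the slab centre to the target slice
#' (\code{offsetLabelMM = target z - candidate z}), so labels are
#' antisymmetric about the target and zero at it. Optional augmentation
#' adds rotated/shifted copies (small rotations and width/height shifts).
#'
#' @param vol an \linkS4class{MRIVolume}.
#' @param targetIndex axial index of the landmark slice.
#' @param offsetsMM numeric vector of candidate offsets from the target (mm).
#' @param thicknessMM,inputSize passed to \code{\link{computeMIP}}.
#' @param augment optional list(n, max_rot_deg = 10, max_shift_frac = 0.05,
#'   seed): adds n augmented copies per base slab.
#' @return list of \linkS4class{MIPSlice} with labels set.
#' @export
buildOffsetDataset <- function(vol, targetIndex, offsetsMM, thicknessMM = 5,
                               inputSize = 256L, augment = NULL) {
    if (length(offsetsMM) == 0L)
        stop("offsetsMM must be non-empty", call. = FALSE)
    sz <- vol@spacing[3]
    out <- lapply(offsetsMM, function(o) {
        ci <- targetIndex - as.integer(round(o / sz))
        mip <- computeMIP(vol, ci, thicknessMM, inputSize)
        mip@offsetLabelMM <- (targetIndex - ci) * sz
        mip
    })
    if (!is.null(augment) && isTRUE(augment$n > 0)) {
        rot <- if (is.null(augment$max_rot_deg)) 10 else augment$max_rot_deg
        shf <- if (is.null(augment$max_shift_frac)) 0.05 else augment$max_shift_frac
        oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        if (!is.null(augment$seed)) set.seed(augment$seed)
        extra <- list()
        for (m in out) {
            for (k in seq_len(augment$n)) {
                ang <- stats::runif(1, -rot, rot)
                dxy <- round(stats::runif(2, -shf, shf) * inputSize)
                img <- EBImage::rotate(m@image, ang, output.dim = c(inputSize, inputSize))
                img <- EBImage::translate(img, dxy)
                m2 <- m; m2@image <- img
                extra <- c(extra, list(m2))
            }
        }
        if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv())
        out <- c(out, extra)
    }
    out
}

#' @describeIn predictOffset oracle / perturbation regressor.
#' @export
setMethod("predictOffset", "FunctionSliceRegressor", function(model, mip) {
    as.numeric(model@fn(mip))
})

#' Oracle slice regressor knowing the true target position
#'
#' Returns the exact signed offset from any slab centre to \code{targetZ}
#' (world mm). Used to validate the aggregation arithmetic independently of
#' any learned model.
#'
#' @param targetZ world-z position (mm) of the true landmark slice centre.
#' @return a \linkS4class{FunctionSliceRegressor}.
#' @export
oracleSliceRegressor <- function(targetZ) {
    force(targetZ)
    new("FunctionSliceRegressor", fn = function(mip) targetZ - mip@centerZ)
}

.mipFeatures <- function(mip, side) {
    img <- EBImage::resize(mip@image, w = side, h = side)
    as.vector(img)
}

#' @describeIn fitSliceRegressor no-op for fixed-function regressors.
#' @export
setMethod("fitSliceRegressor", "FunctionSliceRegressor",
    function(model, dataset, config = list()) model)

# forward pass of the perceptron on a standardised feature matrix
.mlpForward <- function(w, Xs, hidden) {
    if (hidden == 0L)
        return(list(pred = as.vector(Xs %*% w$W2) + w$b2))
    H <- Xs %*% w$W1
    H <- sweep(H, 2, w$b1, "+")
    A <- tanh(H)
    list(pred = as.vector(A %*% w$W2) + w$b2, A = A)
}

#' @describeIn fitSliceRegressor Adam / mean-squared-error training of the
#'   reference perceptron regressor. Config: \code{epochs} (30),
#'   \code{batch_size} (64), \code{lr} (5e-3), \code{seed}.
#' @export
setMethod("fitSliceRegressor", "MLPSliceRegressor",
    function(model, dataset, config = list()) {
    if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
    cfg <- utils::modifyList(
        list(epochs = 30L, batch_size = 64L, lr = 5e-3, seed = 1L), config)
    set.seed(cfg$seed)
    side <- model@inputSide
    h <- model@hidden
    X <- t(vapply(dataset, .mipFeatures, numeric(side * side), side = side))
    y <- vapply(dataset, function(m) m@offsetLabelMM, numeric(1))
    if (any(is.na(y))) stop("dataset has unlabelled slabs", call. = FALSE)
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    p <- ncol(Xs)
    w <- if (h == 0L)
        list(W2 = matrix(0, p, 1L), b2 = 0)
    else
        list(W1 = matrix(stats::rnorm(p * h, sd = 1 / sqrt(p)), p, h),
             b1 = numeric(h),
             W2 = matrix(stats::rnorm(h, sd = 1 / sqrt(h)), h, 1L), b2 = 0)
    vecW <- function(w) unlist(w, use.names = FALSE)
    unvecW <- function(v) {
        out <- w; pos <- 0L
        for (nm in names(w)) {
            nn <- length(w[[nm]])
            val <- v[pos + seq_len(nn)]; pos <- pos + nn
            out[[nm]] <- if (is.matrix(w[[nm]]))
                matrix(val, nrow(w[[nm]]), ncol(w[[nm]])) else val
        }
        out
    }
    theta <- vecW(w)
    mAd <- numeric(length(theta)); vAd <- numeric(length(theta))
    b1c <- 0.9; b2c <- 0.999; eps <- 1e-8; t <- 0L
    n <- nrow(Xs)
    loss <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = cfg$batch_size)) {
            idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
            Xb <- Xs[idx, , drop = FALSE]
            fw <- .mlpForward(w, Xb, h)
            res <- fw$pred - y[idx]
            dPred <- 2 * res / length(idx)
            if (h == 0L) {
                g <- list(W2 = crossprod(Xb, dPred), b2 = sum(dPred))
            } else {
                dA <- dPred %o% as.vector(w$W2)
                dH <- dA * (1 - fw$A^2)
                g <- list(W1 = crossprod(Xb, dH), b1 = colSums(dH),
                          W2 = crossprod(fw$A, dPred), b2 = sum(dPred))
            }
            gv <- vecW(g)
            t <- t + 1L
            mAd <- b1c * mAd + (1 - b1c) * gv
            vAd <- b2c * vAd + (1 - b2c) * gv^2
            theta <- theta - cfg$lr * (mAd / (1 - b1c^t)) /
                (sqrt(vAd / (1 - b2c^t)) + eps)
            w <- unvecW(theta)
        }
        loss[ep] <- mean((.mlpForward(w, Xs, h)$pred - y)^2)
        if (!is.finite(loss[ep]))
            stop("slice-regressor training diverged (non-finite MSE) at epoch ",
                 ep, call. = FALSE)
    }
    model@weights <- w
    model@featMean <- mu
    model@featSd <- sdv
    model@lossTrace <- loss
    model
})

#' @describeIn predictOffset reference perceptron regressor.
#' @export
setMethod("predictOffset", "MLPSliceRegressor", function(model, mip) {
    if (length(model@weights) == 0L)
        stop("regressor is not trained", call. = FALSE)
    x <- .mipFeatures(mip, model@inputSide)
    xs <- matrix((x - model@featMean) / model@featSd, 1L)
    as.numeric(.mlpForward(model@weights, xs, model@hidden)$pred)
})

#' Predict the target (superior-orbital-roof) slice index
#'
#' Sweeps candidate slab centres over \code{searchBand}, converts each
#' predicted offset into an implied target index
#' (candidate + offset / slice spacing), and aggregates by the median,
#' which tolerates up to half the candidates being corrupted. The robust
#' spread (MAD, mm) of implied targets is reported; a spread above
#' \code{warnMM} logs a warning but measurement proceeds (craniocaudal
#' shifts within about 4 mm have negligible impact on the thickness
#' measurement).
#'
#' @param vol an \linkS4class{MRIVolume} (preprocessed).
#' @param model a \linkS4class{SliceRegressor}.
#' @param searchBand integer range of candidate axial indices (default: the
#'   central third of the volume, clipped to valid slab positions).
#' @param stride candidate step in slices (default 1).
#' @param thicknessMM,inputSize passed to \code{\link{computeMIP}}.
#' @param warnMM dispersion warning threshold in mm (default 4).
#' @return a \linkS4class{SlicePrediction}.
#' @export
predictTargetSlice <- function(vol, model, searchBand = NULL, stride = 1L,
                               thicknessMM = 5, inputSize = 256L,
                               warnMM = 4) {
    d <- dim(vol@data)
    sz <- vol@spacing[3]
    halfVox <- (max(1L, as.integer(round(thicknessMM / sz))) - 1L) %/% 2L + 1L
    if (is.null(searchBand)) {
        lo <- max(halfVox + 1L, as.integer(floor(d[3] / 3)))
        hi <- min(d[3] - halfVox, as.integer(ceiling(2 * d[3] / 3)))
        searchBand <- lo:hi
    }
    if (length(searchBand) == 0L) stop("empty search band", call. = FALSE)
    searchBand <- searchBand[seq(1L, length(searchBand), by = stride)]
    offs <- vapply(searchBand, function(i) {
        predictOffset(model, computeMIP(vol, i, thicknessMM, inputSize))
    }, numeric(1))
    implied <- searchBand + offs / sz
    tgt <- as.integer(round(stats::median(implied)))
    tgt <- min(max(tgt, 1L), d[3])
    disp <- stats::mad(implied) * sz
    if (is.finite(disp) && disp > warnMM)
        warning(sprintf("slice-prediction dispersion %.2f mm exceeds %.1f mm",
                        disp, warnMM), call. = FALSE)
    new("SlicePrediction", targetIndex = tgt,
        perCandidate = data.frame(candidate = searchBand, offset_mm = offs,
                                  implied_target = implied),
        dispersionMM = disp)
}

#' Median absolute slice-selection error in mm
#'
#' @param predIndices,trueIndices paired axial indices.
#' @param spacingZ slice spacing in mm.
#' @return median of |pred - true| * spacingZ.
#' @export
sliceMAE <- function(predIndices, trueIndices, spacingZ) {
    if (length(predIndices) != length(trueIndices))
        stop("paired lists must have equal length", call. = FALSE)
    if (length(predIndices) == 0L) stop("empty input", call. = FALSE)
    stats::median(abs(predIndices - trueIndices)) * spacingZ
}
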