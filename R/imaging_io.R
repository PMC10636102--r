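#' Construct an MRIVolume
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3) mm per voxel.
#' @param orientation axis code, default "RAS".
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return an \linkS4class{MRIVolume}.
#' @export
MRIVolume <- function(data, spacing = c(1, 1, 1), orientation = "RAS",
                      affine = NULL) {
    new("MRIVolume", data = data, spacing = as.numeric(spacing),
        orientation = orientation, affine = affine)
}

#' Construct a VoxelMask
#'
#' @param data 2D or 3D array of 0/1 (logical accepted).
#' @param spacing numeric mm per voxel, length matching dimensionality.
#' @return a \linkS4class{VoxelMask}.
#' @export
VoxelMask <- function(data, spacing = rep(1, length(dim(data)))) {
    storage.mode(data) <- "integer"
    new("VoxelMask", data = data, spacing = as.numeric(spacing))
}

#' Load a NIfTI volume in canonical RAS orientation
#'
#' Reads a NIfTI-1/2 file, reorients the stored data to RAS using the
#' file's qform/sform (files without any transform are assumed to already
#' be RAS), and extracts the voxel spacing from the header. Non-3D images
#' and non-finite voxel values are rejected.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return an \linkS4class{MRIVolume}.
#' @export
loadVolume <- function(path) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
        error = function(e) stop("failed to read NIfTI file '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (length(dim(img)) != 3L)
        stop("expected a 3D volume, got ", length(dim(img)), "D data",
             call. = FALSE)
    hasXform <- tryCatch(!is.na(RNifti::orientation(img)),
                         error = function(e) FALSE, warning = function(w) FALSE)
    if (isTRUE(hasXform))
        suppressWarnings(RNifti::orientation(img) <- "RAS")
    dat <- array(as.vector(img), dim(img))
    storage.mode(dat) <- "double"
    if (any(!is.finite(dat)))
        stop("volume contains non-finite voxel values", call. = FALSE)
    sp <- abs(RNifti::pixdim(img)[1:3])
    aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
    MRIVolume(dat, spacing = sp, orientation = "RAS", affine = aff)
}

#' Save an MRIVolume as NIfTI
#'
#' Data and spacing round-trip bit-for-bit for canonical-orientation
#' volumes (voxels are written as float64).
#'
#' @param vol an \linkS4class{MRIVolume}.
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
saveVolume <- function(vol, path) {
    stopifnot(is(vol, "MRIVolume"))
    img <- RNifti::asNifti(vol@data)
    RNifti::pixdim(img) <- vol@spacing
    aff <- vol@affine
    if (is.null(aff)) aff <- diag(c(vol@spacing, 1))
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation at voxel centres; output grid dimensions are
#' the input dimensions scaled by spacing ratio and rounded. Resampling at
#' the input spacing is the identity.
#'
#' @param vol an \linkS4class{MRIVolume}.
#' @param targetMM target isotropic spacing in mm (default 1).
#' @return an \linkS4class{MRIVolume} with spacing \code{rep(targetMM, 3)}.
#' @export
resampleIsotropic <- function(vol, targetMM = 1.0) {
    stopifnot(is(vol, "MRIVolume"), targetMM > 0)
    d <- dim(vol@data)
    if (any(d < 2L))
        stop("degenerate volume: need >= 2 voxels per axis", call. = FALSE)
    sp <- vol@spacing
    dOut <- pmax(2L, as.integer(round(d * sp / targetMM)))
    # continuous input coordinate (1-based voxel centres) of each output centre
    coords <- lapply(1:3, function(ax) {
        x <- ((seq_len(dOut[ax]) - 0.5) * targetMM) / sp[ax] + 0.5
        pmin(pmax(x, 1), d[ax])
    })
    lo <- lapply(1:3, function(ax) pmin(pmax(floor(coords[[ax]]), 1), d[ax] - 1))
    w <- lapply(1:3, function(ax) coords[[ax]] - lo[[ax]])
    lo <- lapply(lo, as.integer)
    out <- array(0, dOut)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        corner <- vol@data[lo[[1]] + cx, lo[[2]] + cy, lo[[3]] + cz,
                           drop = FALSE]
        wx <- if (cx) w[[1]] else 1 - w[[1]]
        wy <- if (cy) w[[2]] else 1 - w[[2]]
        wz <- if (cz) w[[3]] else 1 - w[[3]]
        wt <- array(outer(outer(wx, wy), wz), dOut)
        out <- out + corner * wt
    }
    MRIVolume(out, spacing = rep(targetMM, 3), orientation = vol@orientation)
}

#' Z-score normalise a volume
#'
#' Centres and scales intensities so the normalising region has mean 0 and
#' (population) standard deviation 1; voxels outside the mask are
#' transformed by the same affine map.
#'
#' @param vol an \linkS4class{MRIVolume}.
#' @param mask optional \linkS4class{VoxelMask} selecting the region whose
#'   statistics define the transform (default: whole volume).
#' @return an \linkS4class{MRIVolume}.
#' @export
zscoreNormalize <- function(vol, mask = NULL) {
    stopifnot(is(vol, "MRIVolume"))
    vals <- if (is.null(mask)) as.vector(vol@data) else {
        stopifnot(is(mask, "VoxelMask"),
                  all(dim(mask@data) == dim(vol@data)))
        vol@data[mask@data == 1L]
    }
    if (length(vals) < 2L)
        stop("normalising region must contain >= 2 voxels", call. = FALSE)
    mu <- mean(vals)
    sigma <- sqrt(mean((vals - mu)^2))
    if (sigma == 0)
        stop("constant image: zero variance in normalising region",
             call. = FALSE)
    MRIVolume((vol@data - mu) / sigma, spacing = vol@spacing,
              orientation = vol@orientation, affine = vol@affine)
}

#' 3D median filter with nearest-border padding
#'
#' Each voxel is replaced by the median of its (2r+1)^3 neighbourhood;
#' voxels beyond the border are replicated from the nearest edge.
#'
#' @param vol an \linkS4class{MRIVolume}.
#' @param radiusVox integer radius in voxels (>= 1).
#' @return an \linkS4class{MRIVolume}.
#' @export
medianFilter3D <- function(vol, radiusVox = 1L) {
    stopifnot(is(vol, "MRIVolume"), radiusVox >= 1L)
    d <- dim(vol@data)
    out <- median_filter3d_cpp(as.vector(vol@data), as.integer(d),
                               as.integer(radiusVox))
    MRIVolume(array(out, d), spacing = vol@spacing,
              orientation = vol@orientation, affine = vol@affine)
}

#' Otsu threshold and foreground mask
#'
#' Maximises the between-class variance over histogram bin cuts (the bins
#' partition [min, max] into \code{nbins} equal-width intervals). Ties are
#' broken toward the lower threshold. Foreground is strictly above the
#' threshold.
#'
#' @param vol an \linkS4class{MRIVolume}.
#' @param nbins number of histogram bins (default 256).
#' @return list with \code{threshold} (scalar) and \code{foreground}
#'   (\linkS4class{VoxelMask}).
#' @export
otsuThreshold <- function(vol, nbins = 256L) {
    stopifnot(is(vol, "MRIVolume"), nbins >= 2L)
    v <- as.vector(vol@data)
    lo <- min(v); hi <- max(v)
    if (lo == hi)
        stop("constant image: Otsu threshold undefined", call. = FALSE)
    breaks <- seq(lo, hi, length.out = nbins + 1L)
    bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(bin, nbins)
    centers <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
    w0 <- cumsum(counts)
    m0 <- cumsum(counts * centers)
    n <- w0[nbins]; mTot <- m0[nbins]
    # cut after bin t: classes {1..t} vs {t+1..nbins}
    t <- seq_len(nbins - 1L)
    p0 <- w0[t] / n
    p1 <- 1 - p0
    mu0 <- ifelse(w0[t] > 0, m0[t] / w0[t], 0)
    mu1 <- ifelse(n - w0[t] > 0, (mTot - m0[t]) / (n - w0[t]), 0)
    sigmaB <- p0 * p1 * (mu0 - mu1)^2
    tBest <- which.max(sigmaB)   # first max: tie toward lower threshold
    thr <- breaks[tBest + 1L]
    fg <- array(as.integer(vol@data > thr), dim(vol@data))
    list(threshold = thr,
         foreground = VoxelMask(fg, spacing = vol@spacing))
}

#' Robust linear intensity standardisation
#'
#' Linearly maps the \code{pLo}/\code{pHi} percentiles (of the mask region
#' if given, else the whole volume) to 0/1 and clips to [0, 1].
#'
#' @param vol an \linkS4class{MRIVolume}.
#' @param pLo,pHi percentiles in [0, 100], \code{pLo < pHi}.
#' @param mask optional \linkS4class{VoxelMask} defining the region whose
#'   percentiles anchor the map.
#' @return an \linkS4class{MRIVolume} with intensities in [0, 1].
#' @export
rescaleIntensity <- function(vol, pLo = 0.5, pHi = 99.5, mask = NULL) {
    stopifnot(is(vol, "MRIVolume"), pLo < pHi)
    vals <- if (is.null(mask)) as.vector(vol@data)
            else vol@data[mask@data == 1L]
    q <- stats::quantile(vals, c(pLo, pHi) / 100, names = FALSE)
    if (q[1] == q[2])
        stop("percentile anchors coincide: cannot rescale", call. = FALSE)
    out <- (vol@data - q[1]) / (q[2] - q[1])
    out[out < 0] <- 0
    out[out > 1] <- 1
    MRIVolume(out, spacing = vol@spacing, orientation = vol@orientation,
              affine = vol@affine)
}

#' Full preprocessing chain
#'
#' Applies, in order: isotropic resampling, 3D median filtering, Otsu
#' background removal, z-score normalisation over the Otsu foreground, and
#' percentile rescaling to [0, 1]. The rescale anchors are whole-volume
#' percentiles: they leave the background/tissue intensity gap intact, so
#' running the chain twice is nearly a no-op (anchoring on foreground
#' percentiles would stretch the dark tissue tail onto the background and
#' shift the second-pass Otsu split).
#'
#' @param vol an \linkS4class{MRIVolume}.
#' @param config list with elements \code{target_mm}, \code{median_radius},
#'   \code{nbins}, \code{p_lo}, \code{p_hi} (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param verbose log each stage via \code{message()}.
#' @return an \linkS4class{MRIVolume}, 1 mm isotropic by default, values in
#'   [0, 1].
#' @export
preprocessVolume <- function(vol, config = defaultPipelineConfig()$preprocess,
                             verbose = FALSE) {
    say <- function(...) if (verbose) message("[preprocess] ", sprintf(...))
    say("resampling to %.3g mm isotropic", config$target_mm)
    v <- resampleIsotropic(vol, config$target_mm)
    say("median filter, radius %d voxels", config$median_radius)
    v <- medianFilter3D(v, config$median_radius)
    say("Otsu background removal (%d bins)", config$nbins)
    ot <- otsuThreshold(v, config$nbins)
    say("threshold %.4g, %d foreground voxels", ot$threshold,
        sum(ot$foreground@data))
    v <- zscoreNormalize(v, ot$foreground)
    say("z-scored over foreground")
    v <- rescaleIntensity(v, config$p_lo, config$p_hi)
    say("rescaled to [0, 1] (p%.3g/p%.3g)", config$p_lo, config$p_hi)
    v
}
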