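#' Predict the signed offset (mm) from a MIP slab centre to the target slice
#'
#' @param model a \linkS4class{SliceRegressor}.
#' @param mip a \linkS4class{MIPSlice}.
#' @return numeric(1), signed offset in mm (target minus slab centre).
#' @export
setGeneric("predictOffset", function(model, mip) standardGeneric("predictOffset"))

#' Train a slice regressor on labelled MIP slabs
#'
#' @param model a \linkS4class{SliceRegressor}.
#' @param dataset list of \linkS4class{MIPSlice} with offset labels.
#' @param config list: \code{epochs}, \code{batch_size}, \code{lr}, \code{seed}.
#' @return the trained model.
#' @export
setGeneric("fitSliceRegressor",
    function(model, dataset, config = list()) standardGeneric("fitSliceRegressor"))

#' Predict per-pixel probabilities for an image tile
#'
#' @param model a \linkS4class{Segmenter}.
#' @param tile numeric matrix; callers may attach \code{attr(tile, "window")}.
#' @return numeric matrix of probabilities in [0, 1], same shape as tile.
#' @export
setGeneric("predictProbs", function(model, tile) standardGeneric("predictProbs"))

#' Accessors
#'
#' @param x an object of the corresponding class.
#' @name accessors
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("volOrientation", function(x) standardGeneric("volOrientation"))

#' @rdname accessors
#' @export
setGeneric("targetIndex", function(x) standardGeneric("targetIndex"))

#' @rdname accessors
#' @export
setGeneric("dispersionMM", function(x) standardGeneric("dispersionMM"))

#' @rdname accessors
#' @export
setGeneric("tmtMean", function(x) standardGeneric("tmtMean"))

#' @rdname accessors
#' @export
setGeneric("measurementFlags", function(x) standardGeneric("measurementFlags"))

setMethod("voxelData", "MRIVolume", function(x) x@data)
setMethod("voxelData", "VoxelMask", function(x) x@data)
setMethod("voxelSpacing", "MRIVolume", function(x) x@spacing)
setMethod("voxelSpacing", "VoxelMask", function(x) x@spacing)
setMethod("volOrientation", "MRIVolume", function(x) x@orientation)
setMethod("targetIndex", "SlicePrediction", function(x) x@targetIndex)
setMethod("dispersionMM", "SlicePrediction", function(x) x@dispersionMM)
setMethod("tmtMean", "MusclePairMeasurement", function(x) x@tmtMeanMM)
setMethod("measurementFlags", "MusclePairMeasurement", function(x) x@flags)

setMethod("show", "MRIVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("MRIVolume %dx%dx%d, spacing %.3g x %.3g x %.3g mm, %s\n",
        d[1], d[2], d[3], object@spacing[1], object@spacing[2],
        object@spacing[3], object@orientation))
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
        min(object@data), max(object@data)))
})

setMethod("show", "VoxelMask", function(object) {
    cat(sprintf("VoxelMask %s, %d foreground voxels\n",
        paste(dim(object@data), collapse = "x"), sum(object@data)))
})

setMethod("show", "SlicePrediction", function(object) {
    cat(sprintf("SlicePrediction: target slice %d (%d candidates, dispersion %.2f mm)\n",
        object@targetIndex, nrow(object@perCandidate), object@dispersionMM))
})

setMethod("show", "MusclePairMeasurement", function(object) {
    cat(sprintf("MusclePairMeasurement @ slice %d\n", object@sliceIndex))
    cat(sprintf("  TMT  left %.2f mm | right %.2f mm | mean %.2f mm\n",
        object@tmtLeftMM, object@tmtRightMM, object@tmtMeanMM))
    cat(sprintf("  CSA  left %.1f mm2 | right %.1f mm2\n",
        object@csaLeftMM2, object@csaRightMM2))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CentileModel", function(object) {
    cat(sprintf("CentileModel (sex %s): n = %d, ages %.1f-%.1f years\n",
        object@sex, object@n, object@ageDomain[1], object@ageDomain[2]))
    cat(sprintf("  df: L = %g, M = %g, S = %g; logLik = %.2f, BIC = %.2f\n",
        object@df["L"], object@df["M"], object@df["S"],
        object@loglik, object@bic))
})

setMethod("show", "AgreementResult", function(object) {
    cat(sprintf("Gwet AC1 = %.4f (pa = %.4f, pe = %.4f; %d items, %d categories)\n",
        object@ac1, object@pa, object@pe, object@nItems,
        length(object@categories)))
})
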