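#' @import methods
NULL

#' MRIVolume: a 3D scalar image with physical spacing
#'
#' Container for a T1-weighted (or synthetic) volume. Voxel data are stored
#' as an R array indexed \code{[x, y, z]}; \code{spacing} gives mm per voxel
#' along each axis; \code{orientation} is the three-letter axis code of the
#' stored data (canonical form is \code{"RAS"}: +x right, +y anterior,
#' +z superior); \code{affine} optionally carries the 4x4 voxel-to-world map.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), mm per voxel, all > 0.
#' @slot orientation character(1), e.g. \code{"RAS"}.
#' @slot affine 4x4 matrix or NULL.
#' @exportClass MRIVolume
setClass("MRIVolume",
    representation(data = "array", spacing = "numeric",
                   orientation = "character", affine = "ANY"),
    prototype(orientation = "RAS", affine = NULL))

setValidity("MRIVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three positive finite values")
    if (any(!is.finite(object@data)))
        msg <- c(msg, "data must be finite everywhere (NaN/Inf rejected)")
    if (!is.null(object@affine)) {
        if (!is.matrix(object@affine) || !all(dim(object@affine) == c(4L, 4L)))
            msg <- c(msg, "affine must be a 4x4 matrix when present")
    }
    if (length(msg)) msg else TRUE
})

#' VoxelMask: a binary mask on a 2D or 3D grid
#'
#' Values are strictly 0/1. Carries the mm spacing of its parent grid so
#' that downstream morphometry can report physical units.
#'
#' @slot data integer/numeric array (2D or 3D) of 0/1.
#' @slot spacing numeric, mm per voxel (length matches dimensionality).
#' @exportClass VoxelMask
setClass("VoxelMask",
    representation(data = "array", spacing = "numeric"))

setValidity("VoxelMask", function(object) {
    msg <- character()
    nd <- length(dim(object@data))
    if (!nd %in% c(2L, 3L))
        msg <- c(msg, "mask must be 2D or 3D")
    if (length(object@spacing) != nd || any(object@spacing <= 0))
        msg <- c(msg, "spacing length must match mask dimensionality, all > 0")
    if (!all(object@data %in% c(0, 1)))
        msg <- c(msg, "mask values must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' MIPSlice: a maximum-intensity-projection slab
#'
#' One axial MIP computed over a slab of given physical thickness, resized
#' to the slice-selection model's input size. \code{offsetLabelMM} is the
#' signed training label (target world z minus slab-centre world z); it is
#' \code{NA} at inference time. \code{centerZ} is the slab centre in world
#' mm along the axial axis.
#'
#' @slot image 2D numeric matrix (model input size).
#' @slot centerIndex integer axial voxel index of the slab centre (1-based).
#' @slot centerZ numeric, slab centre in world mm.
#' @slot thicknessMM numeric slab thickness in mm.
#' @slot offsetLabelMM numeric signed offset label in mm (NA at inference).
#' @exportClass MIPSlice
setClass("MIPSlice",
    representation(image = "matrix", centerIndex = "integer",
                   centerZ = "numeric", thicknessMM = "numeric",
                   offsetLabelMM = "numeric"),
    prototype(offsetLabelMM = NA_real_))

setValidity("MIPSlice", function(object) {
    if (object@thicknessMM <= 0) return("thicknessMM must be > 0")
    TRUE
})

#' SlicePrediction: aggregated slice-selection result
#'
#' @slot targetIndex integer, predicted axial index of the landmark slice.
#' @slot perCandidate data.frame with columns \code{candidate},
#'   \code{offset_mm}, \code{implied_target}.
#' @slot dispersionMM numeric, robust spread (MAD, mm) of implied targets.
#' @exportClass SlicePrediction
setClass("SlicePrediction",
    representation(targetIndex = "integer", perCandidate = "data.frame",
                   dispersionMM = "numeric"))

#' VoteGrid: per-pixel vote counts from overlapping-tile inference
#'
#' @slot posVotes integer matrix, positive votes per pixel.
#' @slot totalVotes integer matrix, votes cast per pixel.
#' @exportClass VoteGrid
setClass("VoteGrid",
    representation(posVotes = "matrix", totalVotes = "matrix"))

setValidity("VoteGrid", function(object) {
    if (!all(dim(object@posVotes) == dim(object@totalVotes)))
        return("posVotes and totalVotes must have the same shape")
    if (any(object@posVotes < 0) || any(object@posVotes > object@totalVotes))
        return("need 0 <= posVotes <= totalVotes everywhere")
    TRUE
})

#' MusclePairMeasurement: bilateral thickness and area at the selected slice
#'
#' Thickness (TMT) is the minimum Feret diameter in mm; CSA is the
#' cross-sectional area in mm^2. \code{tmtMeanMM} is the mean of the sides
#' that are present (both sides / 2; a single present side with a flag).
#'
#' @slot tmtLeftMM,tmtRightMM,tmtMeanMM numeric mm (NA when side missing).
#' @slot csaLeftMM2,csaRightMM2 numeric mm^2 (NA when side missing).
#' @slot sliceIndex integer axial index where measured.
#' @slot flags character vector of warnings ("left_missing", ...).
#' @exportClass MusclePairMeasurement
setClass("MusclePairMeasurement",
    representation(tmtLeftMM = "numeric", tmtRightMM = "numeric",
                   tmtMeanMM = "numeric", csaLeftMM2 = "numeric",
                   csaRightMM2 = "numeric", sliceIndex = "integer",
                   flags = "character"))

setValidity("MusclePairMeasurement", function(object) {
    vals <- c(object@tmtLeftMM, object@tmtRightMM, object@tmtMeanMM,
              object@csaLeftMM2, object@csaRightMM2)
    if (any(vals < 0, na.rm = TRUE)) return("measurements must be >= 0")
    TRUE
})

#' CentileModel: sex-specific LMS (Box-Cox Cole-Green) age curves
#'
#' Holds fitted L(t) (Box-Cox power), M(t) (median, mm) and S(t)
#' (coefficient of variation) as natural-cubic-spline bases with
#' coefficients, plus fit metadata. M and S are modelled on the log scale so
#' positivity holds on the whole age domain; L is constant or linear in age.
#' Evaluating outside \code{ageDomain} is an error.
#'
#' @slot sex character, "M" or "F".
#' @slot curves list with components \code{L}, \code{M}, \code{S}; each is a
#'   list(df, knots, boundary, coef) describing a spline on the age axis
#'   (df = 1 means a constant).
#' @slot df named numeric, degrees of freedom per curve.
#' @slot n integer, number of observations fitted.
#' @slot loglik,bic numeric fit statistics.
#' @slot ageDomain numeric(2), [min, max] age in years.
#' @exportClass CentileModel
setClass("CentileModel",
    representation(sex = "character", curves = "list", df = "numeric",
                   n = "integer", loglik = "numeric", bic = "numeric",
                   ageDomain = "numeric"))

setValidity("CentileModel", function(object) {
    msg <- character()
    if (!all(c("L", "M", "S") %in% names(object@curves)))
        msg <- c(msg, "curves must contain L, M and S")
    if (length(object@ageDomain) != 2L || diff(object@ageDomain) <= 0)
        msg <- c(msg, "ageDomain must be an increasing [min, max]")
    if (length(msg)) msg else TRUE
})

#' AgreementResult: chance-corrected agreement (Gwet AC1)
#'
#' @slot pa numeric observed agreement in [0, 1].
#' @slot pe numeric chance agreement in [0, 1].
#' @slot ac1 numeric coefficient, (pa - pe) / (1 - pe).
#' @slot nItems integer number of rated items.
#' @slot categories character category labels.
#' @exportClass AgreementResult
setClass("AgreementResult",
    representation(pa = "numeric", pe = "numeric", ac1 = "numeric",
                   nItems = "integer", categories = "character"))

setValidity("AgreementResult", function(object) {
    vals <- c(object@pa, object@pe)
    vals <- vals[is.finite(vals)]   # pe is undefined for one category
    if (any(vals < -1e-12 | vals > 1 + 1e-12))
        return("pa and pe must lie in [0, 1]")
    TRUE
})

# ---- model contracts ----

#' SliceRegressor: contract for slice-offset regression models
#'
#' A slice regressor maps a \linkS4class{MIPSlice} to a signed offset in mm
#' from the slab centre to the target (superior-orbital-roof) slice.
#' Implementations must be deterministic given a fixed trained state.
#'
#' @exportClass SliceRegressor
setClass("SliceRegressor", representation("VIRTUAL"))

#' FunctionSliceRegressor: a slice regressor wrapping an arbitrary function
#'
#' Used for oracle and perturbation studies: \code{fn} receives the
#' \linkS4class{MIPSlice} and returns the predicted offset in mm.
#'
#' @slot fn function(MIPSlice) -> numeric offset mm.
#' @exportClass FunctionSliceRegressor
setClass("FunctionSliceRegressor", contains = "SliceRegressor",
    representation(fn = "function"))

#' MLPSliceRegressor: reference trainable slice regressor
#'
#' A deliberately small model: the MIP is downsampled to
#' \code{inputSide x inputSide}, flattened, standardised with stored
#' statistics, and mapped to an offset by a one-hidden-layer perceptron
#' (\code{hidden = 0} gives a pure linear readout). Trained with Adam on
#' mean squared error.
#'
#' @slot inputSide integer, downsampled side length.
#' @slot hidden integer, hidden units (0 = linear model).
#' @slot weights list of weight arrays; empty until fit.
#' @slot featMean,featSd numeric feature standardisation statistics.
#' @slot lossTrace numeric per-epoch training MSE.
#' @exportClass MLPSliceRegressor
setClass("MLPSliceRegressor", contains = "SliceRegressor",
    representation(inputSide = "integer", hidden = "integer",
                   weights = "list", featMean = "numeric",
                   featSd = "numeric", lossTrace = "numeric"),
    prototype(inputSide = 16L, hidden = 32L, weights = list(),
              featMean = numeric(), featSd = numeric(),
              lossTrace = numeric()))

#' Segmenter: contract for per-pixel probability segmenters
#'
#' A segmenter maps a 2D image tile to a per-pixel probability map in
#' [0, 1] of the same shape, deterministically given a fixed trained state.
#'
#' @exportClass Segmenter
setClass("Segmenter", representation("VIRTUAL"))

#' FunctionSegmenter: a segmenter wrapping an arbitrary function
#'
#' \code{fn} receives the tile (a matrix; tile window coordinates are
#' attached as \code{attr(tile, "window") = c(x0, y0)} by
#' \code{\link{segmentMuscles}}) and returns a probability matrix of the
#' same shape. Used for oracle segmenters in validation.
#'
#' @slot fn function(matrix) -> matrix of probabilities.
#' @exportClass FunctionSegmenter
setClass("FunctionSegmenter", contains = "Segmenter",
    representation(fn = "function"))

#' UNetSegmenter: reference two-level U-Net segmenter
#'
#' A small encoder-decoder with one pooling level and a skip connection
#' (conv3x3 -> maxpool -> conv3x3 -> nearest upsample + concat -> conv3x3
#' -> conv1x1 -> sigmoid), trained with Adam on the focal Tversky loss.
#' Fully convolutional, so it accepts any tile whose sides are even.
#'
#' @slot params list of weight arrays (empty until initialised).
#' @slot channels integer base channel count.
#' @slot lossTrace numeric per-step training loss.
#' @exportClass UNetSegmenter
setClass("UNetSegmenter", contains = "Segmenter",
    representation(params = "list", channels = "integer",
                   lossTrace = "numeric"),
    prototype(params = list(), channels = 8L, lossTrace = numeric()))
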