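# Synthetic head phantoms and synthetic cohorts. The phantom is the
# package's ground-truth test bed: an ellipsoidal "head" with two lateral
# crescent-shaped "temporalis" muscles of analytically controlled
# thickness, plus an axial intensity structure that makes the landmark
# slice learnable by a regression model.

#' Specify a synthetic head phantom
#'
#' The muscles are built as annular sectors (differences of co-centred
#' circles) with a large arc radius, so the crescent is shallow and its
#' minimum Feret diameter equals the radial thickness up to the arc
#' sagitta (kept below half a voxel); construction is verified numerically
#' against the angle-sweep Feret reference at build time, never assumed.
#'
#' @param shape grid dimensions (default c(128, 128, 96)).
#' @param spacing voxel size in mm (default 1 mm isotropic).
#' @param thicknessLeftMM,thicknessRightMM muscle thickness per side (mm).
#' @param targetSlice axial index of the superior-orbital-roof landmark.
#' @param intensities list(background, brain, muscle, ridge).
#' @param noiseSigma additive Gaussian noise SD (applied after truth
#'   extraction).
#' @param blurSigma Gaussian blur SD in voxels (0 = none; also post-truth).
#' @param arcRadiusMM arc radius of the crescents (default 180).
#' @param muscleLengthMM chord length of the crescents (default 24).
#' @param muscleZExtentMM cranio-caudal extent of the muscles (default 16).
#' @param seed RNG seed: a fixed seed gives bit-identical phantoms.
#' @return a list of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(128L, 128L, 96L), spacing = c(1, 1, 1),
                        thicknessLeftMM = 8, thicknessRightMM = 12,
                        targetSlice = 48L,
                        intensities = list(background = 0, brain = 0.55,
                                           muscle = 0.85, ridge = 1.0),
                        noiseSigma = 0, blurSigma = 0,
                        arcRadiusMM = 180, muscleLengthMM = 24,
                        muscleZExtentMM = 16, seed = 1L) {
    spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 thicknessLeftMM = thicknessLeftMM,
                 thicknessRightMM = thicknessRightMM,
                 targetSlice = as.integer(targetSlice),
                 intensities = intensities, noiseSigma = noiseSigma,
                 blurSigma = blurSigma, arcRadiusMM = arcRadiusMM,
                 muscleLengthMM = muscleLengthMM,
                 muscleZExtentMM = muscleZExtentMM, seed = as.integer(seed))
    class(spec) <- "PhantomSpec"
    stopifnot(spec$thicknessLeftMM > 0, spec$thicknessRightMM > 0,
              spec$targetSlice > 1L, spec$targetSlice < spec$shape[3])
    spec
}

# annular-sector cross-section mask on one axial slice.
# side: +1 right (high x), -1 left. Returns logical matrix (nx, ny).
.crescentSection <- function(spec, side) {
    nx <- spec$shape[1]; ny <- spec$shape[2]
    sx <- spec$spacing[1]; sy <- spec$spacing[2]
    t <- if (side > 0) spec$thicknessRightMM else spec$thicknessLeftMM
    R <- spec$arcRadiusMM
    halfAngle <- asin(spec$muscleLengthMM / 2 / R)
    cxMM <- (nx / 2) * sx    # midline, mm
    cyMM <- (ny / 2) * sy
    # inner edge of the muscle sits at a fixed lateral offset from midline;
    # the arc centre is snapped onto the pixel lattice so that the radial
    # band [R, R + t) rasterises to the intended number of pixel rows
    # regardless of grid size (pixel centres sit at half-integer mm)
    lateral <- round(0.36 * nx) * sx
    centerX <- cxMM + side * (lateral - R)   # arc centre, far medial
    xs <- (seq_len(nx) - 0.5) * sx
    ys <- (seq_len(ny) - 0.5) * sy
    dx <- matrix(xs - centerX, nx, ny)
    dy <- matrix(rep(ys - cyMM, each = nx), nx, ny)
    r <- sqrt(dx^2 + dy^2)
    ang <- abs(atan2(dy, side * dx))   # angle from the lateral direction
    r >= R & r < R + t & ang <= halfAngle
}

.gaussianBlur3d <- function(a, sigma) {
    if (sigma <= 0) return(a)
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-half:half, sd = sigma)
    k <- k / sum(k)
    convAxis <- function(x, axis) {
        d <- dim(x)
        out <- array(0, d)
        for (o in -half:half) {
            idx <- pmin(pmax(seq_len(d[axis]) + o, 1L), d[axis])
            sl <- switch(axis,
                         x[idx, , , drop = FALSE],
                         x[, idx, , drop = FALSE],
                         x[, , idx, drop = FALSE])
            out <- out + k[o + half + 1L] * sl
        }
        out
    }
    convAxis(convAxis(convAxis(a, 1L), 2L), 3L)
}

#' Generate a synthetic head phantom with known muscle thickness
#'
#' Builds the head, the two crescents and an axial intensity structure
#' (a linear intensity ramp along z inside the head plus a bright planar
#' ridge at the landmark slice, so slab position and the landmark are both
#' learnable), extracts the ground-truth masks, verifies the minimum Feret
#' diameter of each truth section at the target slice against the
#' angle-sweep reference (error if off by more than half a voxel), and
#' only then applies blur and noise.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list(volume, leftTruth, rightTruth, targetSlice, spec); truth
#'   masks are 3D \linkS4class{VoxelMask}.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
    stopifnot(inherits(spec, "PhantomSpec"))
    nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
    sx <- spec$spacing[1]; sy <- spec$spacing[2]; sz <- spec$spacing[3]
    ints <- spec$intensities
    xs <- (seq_len(nx) - 0.5) * sx
    ys <- (seq_len(ny) - 0.5) * sy
    zs <- (seq_len(nz) - 0.5) * sz
    cx <- nx / 2 * sx; cy <- ny / 2 * sy; cz <- nz / 2 * sz
    rx <- 0.33 * nx * sx; ry <- 0.42 * ny * sy; rz <- 0.40 * nz * sz
    ex <- ((xs - cx) / rx)^2
    ey <- ((ys - cy) / ry)^2
    ez <- ((zs - cz) / rz)^2
    head <- outer(outer(ex, ey, "+"), ez, "+") <= 1
    vol <- array(ints$background, spec$shape)
    # brain with a gentle axial intensity ramp (slab position is learnable)
    ramp <- 0.3 * (rep(zs, each = nx * ny) / max(zs) - 0.5)
    vol[head] <- ints$brain + array(ramp, spec$shape)[head]
    # muscles: constant cross-section over their z-extent
    zHalf <- spec$muscleZExtentMM / 2
    zRange <- which(abs(zs - (spec$targetSlice - 0.5) * sz) <= zHalf)
    secL <- .crescentSection(spec, -1)
    secR <- .crescentSection(spec, +1)
    leftT <- array(0L, spec$shape)
    rightT <- array(0L, spec$shape)
    for (k in zRange) {
        leftT[, , k] <- secL * 1L
        rightT[, , k] <- secR * 1L
        sl <- vol[, , k]
        sl[secL | secR] <- ints$muscle
        vol[, , k] <- sl
    }
    # bright planar ridge inside the head at the landmark slice
    kt <- spec$targetSlice
    ridgeSel <- head[, , kt] & abs(matrix(rep(ys, each = nx), nx, ny) - cy) < 0.12 * ny * sy
    sl <- vol[, , kt]
    sl[ridgeSel] <- ints$ridge
    vol[, , kt] <- sl
    # verify construction before corrupting the image
    for (side in c("left", "right")) {
        sec <- if (side == "left") secL else secR
        want <- if (side == "left") spec$thicknessLeftMM else spec$thicknessRightMM
        if (sum(sec) == 0L)
            stop("phantom ", side, " thickness not representable at this ",
                 "spacing: crescent rasterised to an empty mask",
                 call. = FALSE)
        got <- feretDiameterSweep(VoxelMask(sec * 1L,
                                            spacing = c(sx, sy)))["min"]
        if (abs(got - want) > 0.5 * max(sx, sy))
            stop("phantom ", side, " thickness not representable at this ",
                 "spacing: built ", round(got, 3), " mm, wanted ", want,
                 " mm", call. = FALSE)
    }
    vol <- .gaussianBlur3d(vol, spec$blurSigma)
    if (spec$noiseSigma > 0) {
        set.seed(spec$seed)
        vol <- vol + array(stats::rnorm(length(vol), sd = spec$noiseSigma),
                           spec$shape)
    }
    list(volume = MRIVolume(vol, spacing = spec$spacing),
         leftTruth = VoxelMask(leftT, spacing = spec$spacing),
         rightTruth = VoxelMask(rightT, spacing = spec$spacing),
         targetSlice = spec$targetSlice,
         spec = spec)
}

#' Generate a synthetic cohort from known LMS curves
#'
#' Ages are uniform on the range; measurements are drawn from
#' BCCG(L(age), M(age), S(age)). Optional study blocks add per-study
#' multiplicative offsets to M, giving structure for leave-one-study-out
#' checks.
#'
#' @param n number of subjects.
#' @param sexRatio proportion of males (1 = all male).
#' @param ageRange c(min, max) in years.
#' @param trueLMS list of functions \code{L(age)}, \code{M(age)},
#'   \code{S(age)} (applied to both sexes unless \code{trueLMSFemale}
#'   given).
#' @param trueLMSFemale optional separate curves for females.
#' @param studies optional named numeric vector of per-study
#'   multiplicative M offsets (e.g. c(A = 1, B = 1, C = 1.1)); subjects
#'   are assigned to studies uniformly.
#' @param seed RNG seed.
#' @return a cohort data.frame (id, study, age, sex, tmt_mm).
#' @export
generateCohort <- function(n, sexRatio = 0.5, ageRange = c(4, 30),
                           trueLMS = list(L = function(a) rep(1, length(a)),
                                          M = function(a) 6 + 0.3 * a,
                                          S = function(a) rep(0.12, length(a))),
                           trueLMSFemale = NULL, studies = NULL, seed = 1L) {
    stopifnot(n >= 1)
    set.seed(seed)
    age <- stats::runif(n, ageRange[1], ageRange[2])
    sex <- ifelse(stats::runif(n) < sexRatio, "M", "F")
    study <- if (is.null(studies)) rep("S1", n)
             else sample(names(studies), n, replace = TRUE)
    tmt <- numeric(n)
    for (sx in c("M", "F")) {
        idx <- which(sex == sx)
        if (!length(idx)) next
        curves <- if (sx == "F" && !is.null(trueLMSFemale)) trueLMSFemale
                  else trueLMS
        L <- curves$L(age[idx]); M <- curves$M(age[idx]); S <- curves$S(age[idx])
        if (any(!is.finite(M)) || any(M <= 0) || any(S <= 0))
            stop("invalid true LMS curves on the requested age range",
                 call. = FALSE)
        tmt[idx] <- rBCCG(length(idx), L, M, S)
    }
    if (!is.null(studies))
        tmt <- tmt * unname(studies[study])
    data.frame(id = sprintf("P%05d", seq_len(n)), study = study,
               age = age, sex = sex, tmt_mm = tmt,
               stringsAsFactors = FALSE)
}
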