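# Shared fixtures, built once per test run (generation is cheap and
# deterministic). Small phantoms keep per-file runtime low; the full-size
# default phantom is exercised in the acceptance tests.

smallPhantomSpec <- function(...) {
    phantomSpec(shape = c(96L, 96L, 64L), spacing = c(1, 1, 1),
                targetSlice = 32L, muscleLengthMM = 20, ...)
}

.fixtureCache <- new.env(parent = emptyenv())

cachedPhantom <- function(key = "default", builder = generatePhantom,
                          spec = phantomSpec()) {
    got <- .fixtureCache[[key]]
    if (is.null(got)) {
        got <- builder(spec)
        .fixtureCache[[key]] <- got
    }
    got
}

# constant-parameter centile model for closed-form checks
constLMSModel <- function(L = 1, M = 10, S = 0.1, ageDomain = c(0, 20)) {
    cv <- function(v) list(df = 1L, knots = numeric(0),
                           boundary = ageDomain, coef = v)
    new("CentileModel", sex = "M",
        curves = list(L = cv(L), M = cv(log(M)), S = cv(log(S))),
        df = c(L = 1, M = 1, S = 1), n = 1L, loglik = 0, bic = 0,
        ageDomain = ageDomain)
}

# the reference parameter-recovery fit: n = 2000 cohort from known curves
# (L = 1, M(t) = 6 + 0.3 t, S = 0.12), BIC-selected df; built once
cachedRecoveryFit <- function() {
    got <- .fixtureCache[["recovery"]]
    if (is.null(got)) {
        coh <- generateCohort(2000, sexRatio = 1, seed = 7)
        got <- list(cohort = coh, fit = fitLMS(coh, "M", seed = 1))
        .fixtureCache[["recovery"]] <- got
    }
    got
}

# full-size study conditions: toy models trained on default phantoms
# (noise levels 0 / 0.02 / 0.05, offsets every 2 mm within +/-16 mm for
# the regressor; 32 slices spanning the muscle extent for the U-Net).
# Built once and shared by the acceptance checks.
trainedToyModels <- function() {
    got <- .fixtureCache[["toys"]]
    if (!is.null(got)) return(got)
    offs <- seq(-16, 16, by = 2)
    ds <- list(); slices <- list(); masks <- list()
    for (s in 1:6) {
        sg <- c(0, 0.02, 0.05)[((s - 1) %% 3) + 1]
        ph <- generatePhantom(phantomSpec(noiseSigma = sg, seed = s))
        pre <- preprocessVolume(ph$volume)
        ds <- c(ds, buildOffsetDataset(pre, ph$targetSlice, offs))
        if (s <= 4) {
            for (k in seq(ph$targetSlice - 6, ph$targetSlice + 8, by = 2)) {
                slices[[length(slices) + 1L]] <- pre@data[, , k]
                masks[[length(masks) + 1L]] <-
                    (ph$leftTruth@data[, , k] |
                     ph$rightTruth@data[, , k]) * 1
            }
        }
    }
    reg <- fitSliceRegressor(new("MLPSliceRegressor"), ds,
                             list(epochs = 30L, seed = 1L))
    un <- fitToySegmenter(new("UNetSegmenter", channels = 8L),
                          slices, masks, list(epochs = 30L, seed = 1L))
    got <- list(slice = reg, seg = un, segSlices = slices,
                segMasks = masks, regMSE = reg@lossTrace)
    .fixtureCache[["toys"]] <- got
    got
}

# a tiny two-blob slice mask for split/vote tests
twoBlobMask <- function(nx = 256, ny = 256) {
    m <- matrix(0L, nx, ny)
    m[40:60, 120:140] <- 1L
    m[200:220, 120:140] <- 1L
    m
}
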