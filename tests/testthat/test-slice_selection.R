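test_that("MIP slab takes the pixelwise maximum and respects bounds", {
    a <- array(0, c(8, 8, 5))
    for (k in 1:5) a[, , k] <- c(1, 3, 2, 5, 4)[k]
    v <- MRIVolume(a, spacing = c(1, 1, 1))
    mip <- computeMIP(v, 3, thicknessMM = 5, inputSize = 8L)
    expect_true(all(abs(mip@image - 5) < 1e-12))

    # MIP dominates every contributing slice pixelwise
    set.seed(3)
    a2 <- array(rnorm(8 * 8 * 7), c(8, 8, 7))
    v2 <- MRIVolume(a2, spacing = c(1, 1, 1))
    m2 <- computeMIP(v2, 4, thicknessMM = 5, inputSize = 8L)
    for (k in 2:6)
        expect_true(all(m2@image >= a2[, , k] - 1e-12))
    # monotone: widening the slab never decreases any pixel
    m3 <- computeMIP(v2, 4, thicknessMM = 7, inputSize = 8L)
    expect_true(all(m3@image >= m2@image - 1e-12))

    # thickness of one slice spacing = that slice, resized only
    m1 <- computeMIP(v2, 4, thicknessMM = 1, inputSize = 8L)
    expect_equal(m1@image, a2[, , 4])

    expect_error(computeMIP(v2, 1, thicknessMM = 5, inputSize = 8L),
                 "outside")
})

test_that("offset dataset carries antisymmetric mm labels", {
    set.seed(6)
    v <- MRIVolume(array(rnorm(16 * 16 * 40), c(16, 16, 40)),
                   spacing = c(1, 1, 1))
    offs <- seq(-10, 10, by = 2)
    ds <- buildOffsetDataset(v, 20L, offs, inputSize = 16L)
    expect_length(ds, 11L)
    labels <- vapply(ds, function(m) m@offsetLabelMM, numeric(1))
    expect_equal(sort(labels), sort(offs))           # labels realise offsets
    expect_equal(labels[offs == 0], 0)               # zero at the target
    expect_equal(sort(labels + rev(labels)), rep(0, 11))  # antisymmetric
    # label convention: target z minus slab-centre z
    for (m in ds)
        expect_equal(m@offsetLabelMM, (20L - m@centerIndex) * 1)
    expect_error(buildOffsetDataset(v, 20L, numeric(0)), "non-empty")
})

test_that("an oracle regressor recovers the target slice exactly", {
    set.seed(9)
    v <- MRIVolume(array(rnorm(16 * 16 * 60), c(16, 16, 60)),
                   spacing = c(1, 1, 1))
    orc <- oracleSliceRegressor(targetZ = (37 - 0.5) * 1)
    for (band in list(20:50, 30:31, 37L)) {
        sp <- predictTargetSlice(v, orc, searchBand = band, inputSize = 16L)
        expect_identical(targetIndex(sp), 37L)
        expect_lt(dispersionMM(sp), 1e-9)
    }
    # a constant +1 mm bias at 1 mm spacing shifts the answer by one slice
    biased <- new("FunctionSliceRegressor",
                  fn = function(mip) (37 - 0.5) - mip@centerZ + 1)
    sp <- predictTargetSlice(v, biased, searchBand = 20:50, inputSize = 16L)
    expect_identical(targetIndex(sp), 38L)
    expect_error(predictTargetSlice(v, orc, searchBand = integer(0)), "empty")
})

test_that("median aggregation survives under-half corruption of candidates", {
    set.seed(10)
    v <- MRIVolume(array(rnorm(16 * 16 * 60), c(16, 16, 60)),
                   spacing = c(1, 1, 1))
    corrupted <- new("FunctionSliceRegressor", fn = function(mip) {
        true <- (37 - 0.5) - mip@centerZ
        # corrupt 40% of candidates with a huge error, keyed off the index
        if (mip@centerIndex %% 5 < 2) true + 40 else true
    })
    sp <- suppressWarnings(
        predictTargetSlice(v, corrupted, searchBand = 20:50, inputSize = 16L))
    expect_identical(targetIndex(sp), 37L)
})

test_that("slice MAE is a median in millimetres", {
    expect_equal(sliceMAE(c(10, 11, 12), c(10, 10, 10), 1), 1.0)
    expect_equal(sliceMAE(1:5, 1:5, 2), 0)
    expect_equal(sliceMAE(c(10, 10, 20), c(10, 10, 10), 1), 0)  # robust
    expect_equal(sliceMAE(c(12, 14), c(10, 10), 2.5), 7.5)
    expect_error(sliceMAE(1:3, 1:2, 1), "equal length")
    expect_error(sliceMAE(numeric(0), numeric(0), 1), "empty")
})

test_that("perceptron regressor trains: constant fit and cluster means", {
    img <- matrix(0.5, 16, 16)
    mk <- function(lab) new("MIPSlice", image = img, centerIndex = 1L,
                            centerZ = 0, thicknessMM = 5, offsetLabelMM = lab)
    # identical images, identical labels -> predicts that label
    ds <- replicate(20, mk(3.5))
    reg <- fitSliceRegressor(new("MLPSliceRegressor", inputSide = 8L,
                                 hidden = 0L),
                             ds, list(epochs = 300L, lr = 0.05, seed = 2L))
    expect_lt(abs(predictOffset(reg, mk(NA_real_)) - 3.5), 0.05)

    # identical images, two label clusters, linear model -> midpoint
    ds2 <- c(replicate(10, mk(-4)), replicate(10, mk(8)))
    reg2 <- fitSliceRegressor(new("MLPSliceRegressor", inputSide = 8L,
                                  hidden = 0L),
                              ds2, list(epochs = 300L, lr = 0.05, seed = 2L))
    expect_lt(abs(predictOffset(reg2, mk(NA_real_)) - 2), 0.2)
})

test_that("regressor training reduces the MSE on phantom slabs", {
    ph <- cachedPhantom("small", spec = smallPhantomSpec())
    pre <- preprocessVolume(ph$volume)
    ds <- buildOffsetDataset(pre, ph$targetSlice, seq(-10, 10, by = 2))
    reg <- new("MLPSliceRegressor", inputSide = 8L, hidden = 8L)
    reg <- fitSliceRegressor(reg, ds, list(epochs = 15L, seed = 3L))
    expect_lt(tail(reg@lossTrace, 1), reg@lossTrace[1])
    expect_true(all(is.finite(reg@lossTrace)))
    # deterministic prediction given the trained state
    p1 <- predictOffset(reg, ds[[1]])
    expect_identical(p1, predictOffset(reg, ds[[1]]))
})
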