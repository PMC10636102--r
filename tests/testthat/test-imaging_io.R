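test_that("NIfTI round trip preserves data, spacing and orientation handling", {
    set.seed(11)
    a <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
    f <- tempfile(fileext = ".nii.gz")
    saveVolume(MRIVolume(a, spacing = c(2, 2, 2)), f)
    v <- loadVolume(f)
    expect_identical(dim(v@data), dim(a))
    expect_equal(v@spacing, c(2, 2, 2))
    expect_identical(v@data, a)          # bit-for-bit for canonical files
    expect_equal(v@orientation, "RAS")

    # LPS-stored file comes back RAS with axes flipped accordingly
    f2 <- tempfile(fileext = ".nii.gz")
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- c(2, 2, 2)
    RNifti::sform(img) <- structure(diag(c(-2, -2, 2, 1)), code = 2L)
    RNifti::writeNifti(img, f2)
    v2 <- loadVolume(f2)
    expect_identical(v2@data, a[16:1, 16:1, ])
    # and saving the RAS volume re-reads identically
    f3 <- tempfile(fileext = ".nii.gz")
    saveVolume(v2, f3)
    expect_identical(loadVolume(f3)@data, v2@data)

    # 4D data are rejected with a shape error
    f4 <- tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 3))), f4)
    expect_error(loadVolume(f4), "3D")
    # unreadable file is an I/O error
    expect_error(loadVolume(tempfile(fileext = ".nii")), "read")
})

test_that("isotropic resampling: dimensions, constants, ramps, identity", {
    v <- MRIVolume(array(7, c(64, 64, 64)), spacing = c(2, 2, 2))
    r <- resampleIsotropic(v, 1)
    expect_identical(dim(r@data), c(128L, 128L, 128L))
    expect_equal(r@spacing, c(1, 1, 1))
    expect_true(all(abs(r@data - 7) < 1e-12))   # constant preserved

    # linear ramp preserved at interior voxels
    nx <- 32L
    ramp <- array(rep(seq_len(nx), times = nx * nx), c(nx, nx, nx))
    vr <- MRIVolume(ramp, spacing = c(2, 2, 2))
    rr <- resampleIsotropic(vr, 1)
    # world x of output voxel i is (i - 0.5); input value at world x is
    # x / 2 + 0.5 (input voxel i has value i at world (i - 0.5) * 2)
    interior <- 3:(dim(rr@data)[1] - 3)
    want <- ((interior - 0.5) / 2) + 0.5
    got <- rr@data[interior, 16, 16]
    expect_lt(max(abs(got - want)), 1e-6)

    # identity at the input spacing
    set.seed(4)
    v3 <- MRIVolume(array(rnorm(10^3), c(10, 10, 10)), spacing = c(1, 1, 1))
    expect_lt(max(abs(resampleIsotropic(v3, 1)@data - v3@data)), 1e-6)

    expect_error(resampleIsotropic(
        MRIVolume(array(0, c(1, 8, 8)), spacing = c(1, 1, 1))), "degenerate")
})

test_that("z-score normalisation is exact on the normalising region", {
    # two-point volume standardises to -1 / +1
    a <- array(c(0, 10), c(2, 2, 2))
    z <- zscoreNormalize(MRIVolume(a, spacing = c(1, 1, 1)))
    expect_equal(sort(unique(as.vector(z@data))), c(-1, 1))

    # masked normalisation: stats exact on mask, same affine map outside
    set.seed(21)
    a <- array(runif(8^3, 0, 100), c(8, 8, 8))
    mdat <- array(0L, c(8, 8, 8)); mdat[1:4, , ] <- 1L
    mask <- VoxelMask(mdat, spacing = c(1, 1, 1))
    v <- MRIVolume(a, spacing = c(1, 1, 1))
    z <- zscoreNormalize(v, mask)
    inside <- z@data[mdat == 1L]
    expect_lt(abs(mean(inside)), 1e-9)
    expect_lt(abs(sqrt(mean((inside - mean(inside))^2)) - 1), 1e-9)
    mu <- mean(a[mdat == 1L]); sg <- sqrt(mean((a[mdat == 1L] - mu)^2))
    expect_equal(z@data[mdat == 0L], (a[mdat == 0L] - mu) / sg)

    # idempotence (same normalising region) and the constant-image guard
    z2 <- zscoreNormalize(z, mask)
    expect_lt(max(abs(z2@data - z@data)), 1e-9)
    expect_error(zscoreNormalize(MRIVolume(array(3, c(4, 4, 4)),
                                           spacing = c(1, 1, 1))),
                 "constant")
})

test_that("median filter matches brute-force neighbourhood medians", {
    v <- MRIVolume(array(5, c(6, 6, 6)), spacing = c(1, 1, 1))
    expect_equal(medianFilter3D(v, 1)@data, v@data)   # constant unchanged

    imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 100
    f <- medianFilter3D(MRIVolume(imp, spacing = c(1, 1, 1)), 1)
    expect_true(all(f@data == 0))                     # impulse removed

    set.seed(33)
    a <- array(rnorm(10^3), c(10, 10, 10))
    f <- medianFilter3D(MRIVolume(a, spacing = c(1, 1, 1)), 1)@data
    idx <- cbind(sample(10, 100, TRUE), sample(10, 100, TRUE),
                 sample(10, 100, TRUE))
    for (r in seq_len(100)) {
        i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
        nb <- a[pmin(pmax(i + (-1:1), 1), 10),
                pmin(pmax(j + (-1:1), 1), 10),
                pmin(pmax(k + (-1:1), 1), 10)]
        expect_equal(f[i, j, k], median(nb))
    }
})

test_that("Otsu threshold equals exhaustive between-class maximisation", {
    # bimodal spikes: threshold strictly separates the modes
    set.seed(5)
    v <- MRIVolume(array(sample(c(10, 200), 4^3, TRUE), c(4, 4, 4)),
                   spacing = c(1, 1, 1))
    ot <- otsuThreshold(v)
    expect_gt(ot$threshold, 10)
    expect_lt(ot$threshold, 200)
    expect_true(all(ot$foreground@data[v@data > ot$threshold] == 1L))

    # exhaustive oracle equality on random volumes
    for (s in 1:10) {
        set.seed(100 + s)
        vals <- c(rnorm(300, 10, 3), rnorm(200, 60, 8))
        a <- array(vals[1:500], c(5, 10, 10))
        got <- otsuThreshold(MRIVolume(a, spacing = c(1, 1, 1)), 64L)$threshold
        expect_equal(got, otsuExhaustive(as.vector(a), 64L))
    }
    expect_error(otsuThreshold(MRIVolume(array(1, c(4, 4, 4)),
                                         spacing = c(1, 1, 1))), "constant")
})

test_that("Otsu foreground of a head phantom contains the head voxels", {
    ph <- cachedPhantom("small", spec = smallPhantomSpec())
    ot <- otsuThreshold(ph$volume)
    # all muscle voxels (known bright structure) are foreground
    expect_true(all(ot$foreground@data[ph$leftTruth@data == 1L] == 1L))
    expect_true(all(ot$foreground@data[ph$rightTruth@data == 1L] == 1L))
})

test_that("intensity rescaling maps anchors to [0, 1] and clips", {
    a <- array(seq(0, 100, length.out = 4^3), c(4, 4, 4))
    r <- rescaleIntensity(MRIVolume(a, spacing = c(1, 1, 1)), 0, 100)
    expect_equal(range(r@data), c(0, 1))
    expect_lt(max(abs(r@data - a / 100)), 1e-12)

    # outlier above p_hi is clipped to 1
    a2 <- a; a2[1] <- 1e6
    r2 <- rescaleIntensity(MRIVolume(a2, spacing = c(1, 1, 1)), 0.5, 99.5)
    expect_equal(max(r2@data), 1)

    set.seed(8)
    rnd <- rescaleIntensity(MRIVolume(array(rnorm(6^3), c(6, 6, 6)),
                                      spacing = c(1, 1, 1)))
    expect_gte(min(rnd@data), 0)
    expect_lte(max(rnd@data), 1)
    expect_error(rescaleIntensity(MRIVolume(array(1, c(4, 4, 4)),
                                            spacing = c(1, 1, 1))), "rescale")
})

test_that("preprocessing chain composes the stages in order", {
    ph <- cachedPhantom("small", spec = smallPhantomSpec())
    cfg <- defaultPipelineConfig()$preprocess
    pre <- preprocessVolume(ph$volume, cfg)
    expect_equal(pre@spacing, c(1, 1, 1))
    expect_equal(range(pre@data), c(0, 1))

    # stage-wise recheck: before the final rescale the foreground is
    # mean-0 / sd-1
    v <- resampleIsotropic(ph$volume, cfg$target_mm)
    v <- medianFilter3D(v, cfg$median_radius)
    ot <- otsuThreshold(v, cfg$nbins)
    z <- zscoreNormalize(v, ot$foreground)
    fgv <- z@data[ot$foreground@data == 1L]
    expect_lt(abs(mean(fgv)), 1e-9)
    expect_lt(abs(sqrt(mean((fgv - mean(fgv))^2)) - 1), 1e-9)
    # and the exported chain equals the hand-composed chain
    byHand <- rescaleIntensity(z, cfg$p_lo, cfg$p_hi)
    expect_equal(pre@data, byHand@data)

    # quasi-idempotence: a second pass moves voxels by < 5% RMS
    pre2 <- preprocessVolume(pre, cfg)
    relRMS <- sqrt(mean((pre2@data - pre@data)^2)) / sqrt(mean(pre@data^2))
    expect_lt(relRMS, 0.05)

    expect_error(preprocessVolume(MRIVolume(array(0, c(8, 8, 8)),
                                            spacing = c(1, 1, 1))),
                 "constant")
})
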