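test_that("focal Tversky loss: perfect, empty, soft-Dice identity", {
    set.seed(41)
    g <- (matrix(runif(64 * 64), 64, 64) > 0.7) * 1
    expect_lt(focalTverskyLoss(g, g), 1e-6)                 # perfect
    expect_gt(focalTverskyLoss(matrix(0, 64, 64), g), 0.999)  # all-miss

    # alpha = beta = 0.5, gamma = 1  <=>  1 - soft Dice
    for (i in 1:50) {
        p <- matrix(runif(32 * 32), 32, 32)
        g <- (matrix(runif(32 * 32), 32, 32) > 0.6) * 1
        got <- focalTverskyLoss(p, g, list(alpha = 0.5, beta = 0.5,
                                           gamma = 1))
        expect_lt(abs(got - (1 - softDice(p, g))), 1e-9)
    }
    expect_error(focalTverskyLoss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("focal Tversky loss decreases as predictions approach truth", {
    set.seed(42)
    g <- (matrix(runif(48 * 48), 48, 48) > 0.5) * 1
    p0 <- matrix(runif(48 * 48), 48, 48)
    lossAt <- function(t) focalTverskyLoss(p0 + t * (g - p0), g)
    path <- vapply(seq(0, 1, by = 0.1), lossAt, numeric(1))
    expect_true(all(diff(path) <= 1e-12))
})

test_that("vote tile layout guarantees >= 3-fold coverage, exhaustively", {
    # zero shift: every ROI pixel covered exactly 4 times
    lay <- makeVoteTiles(c(1, 1, 64, 64), 64L, shift = 0L)
    expect_true(all(lay$coverage == 4L))

    # maximal admissible shift for this tile size: coverage verified >= 3
    lay2 <- makeVoteTiles(c(1, 1, 64, 64), 80L, shift = 8L)
    expect_true(all(lay2$coverage >= 3L))
    expect_length(lay2$windows, 4L)
    # windows are pairwise shifted by (+/-d, +/-d)
    xs <- vapply(lay2$windows, `[`, numeric(1), "x")
    ys <- vapply(lay2$windows, `[`, numeric(1), "y")
    expect_equal(max(xs) - min(xs), 16)
    expect_equal(max(ys) - min(ys), 16)

    # an oversized shift cannot satisfy coverage and is rejected
    expect_error(makeVoteTiles(c(1, 1, 64, 64), 64L, shift = 10L),
                 "fewer than 3")
})

test_that("majority vote is strict with ties negative", {
    pos <- matrix(c(3L, 2L, 4L, 0L), 2, 2)
    tot <- matrix(4L, 2, 2)
    out <- majorityVote(new("VoteGrid", posVotes = pos, totalVotes = tot))
    expect_identical(out@data, matrix(c(1L, 0L, 1L, 0L), 2, 2))
    # under-covered pixels are rejected
    expect_error(majorityVote(new("VoteGrid", posVotes = pos * 0L,
                                  totalVotes = matrix(2L, 2, 2))),
                 "coverage")
    # unanimous grids reproduce any single prediction
    una <- new("VoteGrid", posVotes = matrix(c(4L, 0L), 2, 1),
               totalVotes = matrix(4L, 2, 1))
    expect_identical(majorityVote(una)@data, matrix(c(1L, 0L), 2, 1))
})

test_that("left/right split follows centroids and mirrors exactly", {
    m <- VoxelMask(twoBlobMask(), spacing = c(1, 1))
    sides <- splitLeftRight(m)
    # high-x blob is the subject's right in RAS storage
    expect_true(all(which(sides$right@data == 1L, arr.ind = TRUE)[, 1] > 128))
    expect_true(all(which(sides$left@data == 1L, arr.ind = TRUE)[, 1] < 128))
    expect_equal(sum(sides$left@data) + sum(sides$right@data),
                 sum(m@data))

    # single blob left of midline: (blob, empty)
    one <- matrix(0L, 256, 256); one[30:50, 100:120] <- 1L
    s1 <- splitLeftRight(VoxelMask(one, c(1, 1)))
    expect_equal(sum(s1$left@data), sum(one))
    expect_equal(sum(s1$right@data), 0L)

    # mirroring the mask swaps the sides exactly
    mm <- m@data[256:1, ]
    s2 <- splitLeftRight(VoxelMask(mm, c(1, 1)))
    expect_identical(s2$left@data, sides$right@data[256:1, ])
    expect_identical(s2$right@data, sides$left@data[256:1, ])

    # a component straddling the midline warns and goes by centroid
    str <- matrix(0L, 256, 256); str[120:140, 100:120] <- 1L
    expect_warning(splitLeftRight(VoxelMask(str, c(1, 1))), "straddles")
})

test_that("oracle segmentation recovers phantom truth through voting", {
    ph <- cachedPhantom("small", spec = smallPhantomSpec())
    pre <- preprocessVolume(ph$volume)
    k <- ph$targetSlice
    truth <- (ph$leftTruth@data[, , k] | ph$rightTruth@data[, , k]) * 1
    cfg <- defaultPipelineConfig()$segmentation
    up <- (EBImage::resize(truth, w = cfg$input_size, h = cfg$input_size)
           > 0.5) * 1

    seg <- segmentMuscles(pre@data[, , k], oracleSegmenter(up), cfg,
                          spacingMM = c(1, 1))
    expect_length(seg$flags, 0)
    expect_equal(diceCoefficient(seg$left@data, ph$leftTruth@data[, , k]), 1)
    expect_equal(diceCoefficient(seg$right@data, ph$rightTruth@data[, , k]), 1)

    # voting denoises 10% salt-and-pepper corruption to Dice >= 0.95
    set.seed(77)
    segN <- segmentMuscles(pre@data[, , k], oracleSegmenter(up, 0.10), cfg,
                           spacingMM = c(1, 1))
    expect_gte(diceCoefficient(segN$left@data, ph$leftTruth@data[, , k]),
               0.95)
    expect_gte(diceCoefficient(segN$right@data, ph$rightTruth@data[, , k]),
               0.95)

    # muscles erased: both sides flagged missing, no exception
    blank <- segmentMuscles(pre@data[, , k] * 0,
                            oracleSegmenter(up * 0), cfg, c(1, 1))
    expect_setequal(blank$flags, c("left_missing", "right_missing"))
})

test_that("voting is invariant to tile enumeration order and mirrors", {
    ph <- cachedPhantom("small", spec = smallPhantomSpec())
    pre <- preprocessVolume(ph$volume)
    k <- ph$targetSlice
    truth <- (ph$leftTruth@data[, , k] | ph$rightTruth@data[, , k]) * 1
    nx <- dim(pre@data)[1]
    cfg <- defaultPipelineConfig()$segmentation
    cfg$input_size <- nx; cfg$shift <- 4L   # work at native resolution

    # with a mirror-equivariant (oracle) segmenter, mirroring the slice
    # mirror-swaps the segmentation exactly
    seg <- segmentMuscles(pre@data[, , k], oracleSegmenter(truth), cfg,
                          c(1, 1))
    segM <- segmentMuscles(pre@data[nx:1, , k],
                           oracleSegmenter(truth[nx:1, ]), cfg, c(1, 1))
    expect_identical(segM$left@data, seg$right@data[nx:1, ])
    expect_identical(segM$right@data, seg$left@data[nx:1, ])
})
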