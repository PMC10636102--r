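test_that("BCCG density integrates to one for representative parameters", {
    for (par in list(c(1, 10, 0.1), c(0, 8, 0.15), c(-0.5, 6, 0.12),
                     c(2, 15, 0.2))) {
        tot <- stats::integrate(function(y)
            dBCCG(y, par[1], par[2], par[3]),
            lower = 1e-6, upper = par[2] * 6,
            rel.tol = 1e-9)$value
        expect_lt(abs(tot - 1), 1e-6)
    }
})

test_that("value/centile conversions match closed forms and invert", {
    m <- constLMSModel(L = 1, M = 10, S = 0.1)
    expect_equal(valueToCentile(m, 5, 10), 50.0)
    # z = 1 -> Phi(1) = 84.134%
    expect_equal(valueToCentile(m, 5, 11), 100 * pnorm(1), tolerance = 1e-9)
    expect_equal(round(valueToCentile(m, 5, 11), 3), 84.134)
    expect_equal(centileToValue(m, 5, 50), 10.0)

    # log-branch closed form: L = 0, S = 0.1, alpha = 95
    m0 <- constLMSModel(L = 0, M = 10, S = 0.1)
    expect_equal(centileToValue(m0, 5, 95), 10 * exp(0.1 * qnorm(0.95)),
                 tolerance = 1e-12)

    # continuity across L -> 0
    mPlus <- constLMSModel(L = 1e-6, M = 10, S = 0.1)
    mMinus <- constLMSModel(L = -1e-6, M = 10, S = 0.1)
    for (v in c(8, 10, 12.5))
        expect_lt(max(abs(c(valueToCentile(mPlus, 5, v),
                            valueToCentile(mMinus, 5, v))
                          - valueToCentile(m0, 5, v))), 1e-3)

    # round trip across the centile range
    alphas <- 1:99
    vals <- centileToValue(m, rep(5, 99), alphas)
    expect_lt(max(abs(valueToCentile(m, rep(5, 99), vals) - alphas)), 1e-8)

    # strict monotonicity in value and centile
    expect_true(all(diff(valueToCentile(m, rep(5, 50),
                                        seq(7, 14, length.out = 50))) > 0))
    expect_true(all(diff(vals) > 0))
    # out-of-domain age errors; out-of-support centile errors
    expect_error(valueToCentile(m, 25, 10), "domain")
    mNeg <- constLMSModel(L = -2, M = 10, S = 0.3)
    expect_error(centileToValue(mNeg, 5, 99.999), "support")
})

test_that("BIC penalises parameters and favours the true model", {
    expect_equal(bicFromLogLik(-100, 0, 50), 200)
    expect_lt(bicFromLogLik(-100, 6, 2000), bicFromLogLik(-100, 9, 2000))

    # true (df M = 2, S = 1) vs saturated (df 5/4/2) on simulated data
    wins <- 0L
    for (r in 1:10) {
        coh <- generateCohort(800, sexRatio = 1, seed = 100 + r)
        fitT <- fitLMS(coh, "M", dfCandidates = 2, dfSCandidates = 1,
                       dfLCandidates = 1, seed = 1)
        fitS <- fitLMS(coh, "M", dfCandidates = 5, dfSCandidates = 4,
                       dfLCandidates = 2, seed = 1)
        if (fitT@bic < fitS@bic) wins <- wins + 1L
    }
    expect_gte(wins, 9L)
})

test_that("LMS fit recovers the generating curves at n = 2000", {
    rec <- cachedRecoveryFit()
    fit <- rec$fit
    grid <- seq(ceiling(fit@ageDomain[1]), floor(fit@ageDomain[2]))
    lms <- predictLMS(fit, grid)
    expect_lt(max(abs(lms$M - (6 + 0.3 * grid)) / (6 + 0.3 * grid)), 0.03)
    expect_lt(max(abs(lms$S - 0.12) / 0.12), 0.15)
    expect_true(all(lms$M > 0) && all(lms$S > 0))

    # PIT uniformity of fitted centiles
    pit <- valueToCentile(fit, rec$cohort$age, rec$cohort$tmt_mm) / 100
    expect_gt(stats::ks.test(pit, "punif")$p.value, 0.01)

    # fitted median curve tracks the running median of the data
    md <- vapply(seq(6, 28, by = 2), function(a) {
        sel <- abs(rec$cohort$age - a) <= 1
        stats::median(rec$cohort$tmt_mm[sel])
    }, numeric(1))
    expect_lt(max(abs(predictLMS(fit, seq(6, 28, by = 2))$M - md) /
                  md), 0.05)

    # guards
    expect_error(fitLMS(generateCohort(10, seed = 1), "M"), "insufficient")
    degenerate <- data.frame(id = as.character(1:60), study = "s",
                             age = rep(5:14, 6), sex = "M", tmt_mm = 7)
    expect_error(fitLMS(degenerate, "M"), "constant|degenerate")
})

test_that("recovery error of the median curve shrinks with sample size", {
    errAt <- function(n) {
        coh <- generateCohort(n, sexRatio = 1, seed = 31)
        # df 3 for M: the generating median is linear on the raw scale,
        # and M is modelled through a log link, so one interior knot is
        # needed to represent it without a bias floor
        fit <- fitLMS(coh, "M", dfCandidates = 3, dfSCandidates = 1,
                      dfLCandidates = 1, seed = 1)
        grid <- seq(ceiling(fit@ageDomain[1]), floor(fit@ageDomain[2]))
        max(abs(predictLMS(fit, grid)$M - (6 + 0.3 * grid)) /
            (6 + 0.3 * grid))
    }
    errs <- vapply(c(500, 2000, 8000), errAt, numeric(1))
    expect_lt(errs[3], errs[1])          # large n beats small n
    expect_lt(errs[3], 0.03)
})

test_that("chart curves are ordered, tabulated and serialisable", {
    rec <- cachedRecoveryFit()
    cc <- chartCurves(rec$fit)
    expect_true(all(c("p2.5", "p50", "p97.5") %in% names(cc)))
    # strict ordering of centile curves at every age
    expect_true(all(apply(cc[, -1], 1, function(r) all(diff(r) > 0))))
    # 50th centile curve equals M(t)
    expect_equal(cc$p50, predictLMS(rec$fit, cc$age)$M, tolerance = 1e-12)

    # model JSON round trip reproduces lookups exactly
    f <- tempfile(fileext = ".json")
    saveCentileModel(rec$fit, f)
    back <- loadCentileModel(f)
    ages <- c(6.5, 12, 20.25, 28)
    expect_equal(valueToCentile(back, ages, c(7, 9, 11, 13)),
                 valueToCentile(rec$fit, ages, c(7, 9, 11, 13)),
                 tolerance = 1e-12)
})

test_that("mm-per-centile matches its analytic value and scales", {
    m <- constLMSModel(L = 1, M = 10, S = 0.1)
    want <- 10 * 0.1 * mean(diff(qnorm((1:99) / 100)))
    expect_equal(mmPerCentile(m, ageGrid = c(2, 5, 9)), want,
                 tolerance = 1e-12)
    m2 <- constLMSModel(L = 1, M = 20, S = 0.1)   # doubling M doubles it
    expect_equal(mmPerCentile(m2, ageGrid = 5), 2 * want, tolerance = 1e-12)
    rec <- cachedRecoveryFit()
    expect_gt(mmPerCentile(rec$fit), 0)
})

test_that("centile precision has its closed form and grows with error", {
    m <- constLMSModel(L = 1, M = 10, S = 0.1)
    for (mae in c(0.3, 1.06)) {
        cp <- centilePrecision(m, mae, ageGrid = c(3, 8, 15), nBoot = 50)
        expect_equal(cp$precision, 100 * (pnorm(mae / (10 * 0.1)) - 0.5),
                     tolerance = 1e-9)
        expect_true(cp$ci[1] <= cp$precision && cp$precision <= cp$ci[2])
    }
    # monotone non-decreasing in the measurement error, vanishing at zero
    rec <- cachedRecoveryFit()
    vals <- vapply(c(0.01, 0.2, 0.5, 1, 2), function(e)
        centilePrecision(rec$fit, e, nBoot = 10)$precision, numeric(1))
    expect_true(all(diff(vals) >= 0))
    expect_lt(vals[1], 1)
})

test_that("leave-one-study-out flags the discordant study", {
    # three balanced studies, one with a +15% M offset
    coh <- generateCohort(1200, sexRatio = 1, seed = 41,
                          studies = c(A = 1, B = 1, C = 1.15))
    out <- losoCurves(coh, "M", df = c(L = 1, M = 2, S = 1), seed = 1)
    expect_setequal(out$study, c("A", "B", "C"))
    expect_equal(out$study[which.max(out$max_delta_mm)], "C")
    expect_true(all(is.finite(out$max_delta_mm)) &&
                all(out$max_delta_mm >= 0))

    # statistically identical studies: all deltas small
    coh2 <- generateCohort(1200, sexRatio = 1, seed = 42,
                           studies = c(A = 1, B = 1, C = 1))
    out2 <- losoCurves(coh2, "M", df = c(L = 1, M = 2, S = 1), seed = 1)
    expect_lt(max(out2$max_delta_mm), 0.25)

    expect_error(losoCurves(generateCohort(300, sexRatio = 1, seed = 2),
                            "M"), "3 distinct")
})
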