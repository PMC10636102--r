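# LMS / Box-Cox Cole-Green (BCCG) growth curves.
#
# The measurement y > 0 at age t follows a Box-Cox normal law with
# age-varying parameters: L(t) the Box-Cox power (skewness), M(t) the
# median (mm), S(t) the coefficient of variation. The z-score is
#   z = ((y/M)^L - 1) / (L*S)   for L != 0
#   z = log(y/M) / S            for L == 0
# and z is standard normal truncated to the region where y > 0 is
# attainable (normalising constant Phi(1/(S*|L|))). Centile = 100*Phi(z).

.LZERO <- 1e-8

#' BCCG (Box-Cox Cole-Green) density
#'
#' @param y positive measurement values.
#' @param L,M,S Box-Cox power, median (> 0) and coefficient of variation
#'   (> 0); scalars or vectors matching y.
#' @param log return log-density.
#' @return (log-)density values.
#' @export
dBCCG <- function(y, L, M, S, log = FALSE) {
    stopifnot(all(y > 0), all(M > 0), all(S > 0))
    n <- max(length(y), length(L), length(M), length(S))
    y <- rep_len(y, n); L <- rep_len(L, n)
    M <- rep_len(M, n); S <- rep_len(S, n)
    z <- bccgZ(y, L, M, S)
    trunc <- numeric(n)
    big <- abs(L) > .LZERO
    trunc[big] <- stats::pnorm(1 / (S[big] * abs(L[big])), log.p = TRUE)
    ll <- stats::dnorm(z, log = TRUE) + L * log(y / M) - log(y * S) - trunc
    if (log) ll else exp(ll)
}

#' BCCG z-score transform
#'
#' @inheritParams dBCCG
#' @return standard-normal z-scores (the LMS transform).
#' @export
bccgZ <- function(y, L, M, S) {
    n <- max(length(y), length(L), length(M), length(S))
    y <- rep_len(y, n); L <- rep_len(L, n)
    M <- rep_len(M, n); S <- rep_len(S, n)
    z <- numeric(n)
    small <- abs(L) <= .LZERO
    z[small] <- log(y[small] / M[small]) / S[small]
    ok <- !small
    z[ok] <- ((y[ok] / M[ok])^L[ok] - 1) / (L[ok] * S[ok])
    z
}

#' Inverse BCCG z-score transform
#'
#' @param z standard-normal quantiles.
#' @inheritParams dBCCG
#' @return measurement values; errors when 1 + L*S*z <= 0 (outside the
#'   Box-Cox support).
#' @export
bccgInvZ <- function(z, L, M, S) {
    n <- max(length(z), length(L), length(M), length(S))
    z <- rep_len(z, n); L <- rep_len(L, n)
    M <- rep_len(M, n); S <- rep_len(S, n)
    out <- numeric(n)
    small <- abs(L) <= .LZERO
    out[small] <- M[small] * exp(S[small] * z[small])
    if (any(!small)) {
        base <- 1 + L[!small] * S[!small] * z[!small]
        if (any(base <= 0))
            stop("requested centile lies outside the Box-Cox support ",
                 "(1 + L*S*z <= 0)", call. = FALSE)
        out[!small] <- M[!small] * base^(1 / L[!small])
    }
    out
}

#' Sample from the BCCG distribution
#'
#' Draws truncated-normal z (rejection; the truncated tail mass is
#' negligible for realistic S) and back-transforms.
#'
#' @param n sample size.
#' @inheritParams dBCCG
#' @return numeric vector of positive values.
#' @export
rBCCG <- function(n, L, M, S) {
    L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
    z <- stats::rnorm(n)
    bound <- ifelse(abs(L) > .LZERO, 1 / (S * abs(L)), Inf)
    bad <- which(abs(L) > .LZERO &
                 ifelse(L > 0, z <= -bound, z >= bound))
    while (length(bad)) {
        z[bad] <- stats::rnorm(length(bad))
        bad <- bad[ifelse(L[bad] > 0, z[bad] <= -bound[bad],
                          z[bad] >= bound[bad])]
    }
    bccgInvZ(z, L, M, S)
}

# ---- spline curve plumbing ----
# a curve with df coefficients: intercept plus (df - 1) natural-cubic-spline
# columns; df = 1 is a constant.

.makeCurveSpec <- function(age, df) {
    if (df == 1L)
        return(list(df = 1L, knots = numeric(0),
                    boundary = range(age), coef = NA_real_))
    basis <- splines::ns(age, df = df - 1L)
    list(df = as.integer(df),
         knots = as.numeric(attr(basis, "knots")),
         boundary = as.numeric(attr(basis, "Boundary.knots")),
         coef = rep(NA_real_, df))
}

.curveBasis <- function(spec, age) {
    if (spec$df == 1L) return(matrix(1, length(age), 1L))
    cbind(1, splines::ns(age, knots = spec$knots,
                         Boundary.knots = spec$boundary))
}

.evalCurve <- function(spec, age) {
    as.vector(.curveBasis(spec, age) %*% spec$coef)
}

#' Evaluate the fitted L, M and S curves
#'
#' @param model a \linkS4class{CentileModel}.
#' @param age ages in years (inside the model's age domain).
#' @return data.frame(age, L, M, S).
#' @export
predictLMS <- function(model, age) {
    stopifnot(is(model, "CentileModel"))
    if (any(age < model@ageDomain[1] - 1e-9 | age > model@ageDomain[2] + 1e-9))
        stop("age outside the fitted domain [",
             model@ageDomain[1], ", ", model@ageDomain[2], "]", call. = FALSE)
    data.frame(age = age,
               L = .evalCurve(model@curves$L, age),
               M = exp(.evalCurve(model@curves$M, age)),
               S = exp(.evalCurve(model@curves$S, age)))
}

#' Validate and normalise a cohort table
#'
#' Expects columns \code{id}, \code{study}, \code{age}, \code{sex} (M/F),
#' \code{tmt_mm}; ages above \code{collapseAge} are collapsed onto that
#' value (the top of the chart is a single 30+ category by default, for
#' curve stability in sparse old ages).
#'
#' @param cohort data.frame.
#' @param ageRange allowed age range in years (default c(4, 35)).
#' @param collapseAge ages above this are set to it (default 30).
#' @return the cleaned data.frame.
#' @export
validateCohort <- function(cohort, ageRange = c(4, 35), collapseAge = 30) {
    need <- c("id", "study", "age", "sex", "tmt_mm")
    if (!all(need %in% names(cohort)))
        stop("cohort needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (!all(cohort$sex %in% c("M", "F")))
        stop("sex must be coded M/F", call. = FALSE)
    if (any(cohort$tmt_mm <= 0)) stop("tmt_mm must be > 0", call. = FALSE)
    if (any(cohort$age < ageRange[1] | cohort$age > ageRange[2]))
        stop("ages outside the configured range [", ageRange[1], ", ",
             ageRange[2], "]", call. = FALSE)
    cohort$age <- pmin(cohort$age, collapseAge)
    cohort
}

# negative log-likelihood of theta = c(thetaM, thetaS, thetaL) given bases
.bccgNegLL <- function(theta, Bm, Bs, Bl, y) {
    pm <- ncol(Bm); ps <- ncol(Bs)
    M <- exp(as.vector(Bm %*% theta[seq_len(pm)]))
    S <- exp(as.vector(Bs %*% theta[pm + seq_len(ps)]))
    L <- as.vector(Bl %*% theta[pm + ps + seq_len(ncol(Bl))])
    if (any(!is.finite(M)) || any(!is.finite(S))) return(1e10)
    ll <- sum(dBCCG(y, L, M, S, log = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
}

.fitLMSOnce <- function(age, y, dfM, dfS, dfL, seed = 1L) {
    specM <- .makeCurveSpec(age, dfM)
    specS <- .makeCurveSpec(age, dfS)
    specL <- .makeCurveSpec(age, dfL)
    Bm <- .curveBasis(specM, age)
    Bs <- .curveBasis(specS, age)
    Bl <- .curveBasis(specL, age)
    # init: log-linear fit for M, pooled residual CV for S, L = 1
    thM <- stats::coef(stats::lm.fit(Bm, log(y)))
    res <- log(y) - as.vector(Bm %*% thM)
    thS <- c(log(max(stats::sd(res), 1e-3)), rep(0, ncol(Bs) - 1L))
    thL <- c(1, rep(0, ncol(Bl) - 1L))
    theta0 <- c(thM, thS, thL)
    fit <- tryCatch(
        stats::optim(theta0, .bccgNegLL, Bm = Bm, Bs = Bs, Bl = Bl, y = y,
                     method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) {
        # retry from a jittered start (seeded)
        set.seed(seed)
        fit <- stats::optim(theta0 + stats::rnorm(length(theta0), sd = 0.01),
                            .bccgNegLL, Bm = Bm, Bs = Bs, Bl = Bl, y = y,
                            method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12))
    }
    if (!is.finite(fit$value) || fit$value >= 1e10)
        stop("LMS fit did not converge (df = ", dfM, "/", dfS, "/", dfL, ")",
             call. = FALSE)
    pm <- ncol(Bm); ps <- ncol(Bs)
    specM$coef <- fit$par[seq_len(pm)]
    specS$coef <- fit$par[pm + seq_len(ps)]
    specL$coef <- fit$par[pm + ps + seq_len(ncol(Bl))]
    list(L = specL, M = specM, S = specS,
         loglik = -fit$value, k = pm + ps + ncol(Bl))
}

#' Fit sex-specific LMS centile curves by maximum likelihood
#'
#' Maximises the BCCG log-likelihood over natural-cubic-spline coefficients
#' for log M(t) and log S(t) and a constant-or-linear L(t), jointly
#' selecting the degrees of freedom by BIC over the candidate grid. L is
#' kept low-dimensional (constant by default) because the skewness power is
#' weakly identified at moderate n.
#'
#' @param cohort cohort data.frame (see \code{\link{validateCohort}}).
#' @param sex "M" or "F": the stratum to fit.
#' @param dfCandidates candidate df (coefficient counts) for the M curve;
#'   default 2:5.
#' @param dfSCandidates candidate df for the S curve (default: same grid).
#' @param dfLCandidates candidate df for L; default c(1, 2).
#' @param seed RNG seed (used only for jittered restarts).
#' @return a \linkS4class{CentileModel}.
#' @export
fitLMS <- function(cohort, sex, dfCandidates = 2:5,
                   dfSCandidates = dfCandidates,
                   dfLCandidates = c(1L, 2L), seed = 1L) {
    cohort <- validateCohort(cohort)
    sub <- cohort[cohort$sex == sex, ]
    n <- nrow(sub)
    if (n < 50L)
        stop("insufficient data: need >= 50 rows for sex ", sex,
             " (got ", n, ")", call. = FALSE)
    if (length(unique(round(sub$age))) < 5L)
        stop("ages must span >= 5 distinct years", call. = FALSE)
    if (stats::sd(sub$tmt_mm) == 0)
        stop("degenerate data: constant tmt_mm", call. = FALSE)
    best <- NULL
    for (dfM in dfCandidates) for (dfS in dfSCandidates)
        for (dfL in dfLCandidates) {
        fit <- tryCatch(
            .fitLMSOnce(sub$age, sub$tmt_mm, dfM, dfS, dfL, seed = seed),
            error = function(e) NULL)
        if (is.null(fit)) next
        bic <- bicFromLogLik(fit$loglik, fit$k, n)
        if (is.null(best) || bic < best$bic)
            best <- c(fit, list(bic = bic,
                                df = c(L = dfL, M = dfM, S = dfS)))
    }
    if (is.null(best))
        stop("no LMS fit converged for sex ", sex, call. = FALSE)
    new("CentileModel", sex = sex,
        curves = list(L = best$L, M = best$M, S = best$S),
        df = best$df, n = as.integer(n), loglik = best$loglik,
        bic = best$bic, ageDomain = range(sub$age))
}

#' BIC from a log-likelihood
#'
#' \code{-2 * loglik + k * log(n)}.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters (total effective df).
#' @param n number of observations.
#' @return scalar BIC.
#' @export
bicFromLogLik <- function(loglik, k, n) {
    -2 * loglik + k * log(n)
}

#' BIC of a fitted centile model on a cohort
#'
#' Recomputes the BCCG log-likelihood of the model on the given rows of its
#' own sex and applies the BIC penalty with the model's total df.
#'
#' @param model a \linkS4class{CentileModel}.
#' @param cohort cohort data.frame.
#' @return scalar BIC.
#' @export
bicScore <- function(model, cohort) {
    cohort <- validateCohort(cohort)
    sub <- cohort[cohort$sex == model@sex, ]
    lms <- predictLMS(model, sub$age)
    ll <- sum(dBCCG(sub$tmt_mm, lms$L, lms$M, lms$S, log = TRUE))
    bicFromLogLik(ll, sum(model@df), nrow(sub))
}

#' Convert a measurement to a centile
#'
#' @param model a \linkS4class{CentileModel}.
#' @param age age in years (inside the model domain).
#' @param valueMM measurement in mm (> 0).
#' @return centile in (0, 100).
#' @export
valueToCentile <- function(model, age, valueMM) {
    stopifnot(all(valueMM > 0))
    lms <- predictLMS(model, age)
    z <- bccgZ(valueMM, lms$L, lms$M, lms$S)
    100 * stats::pnorm(z)
}

#' Convert a centile to a measurement
#'
#' Inverse of \code{\link{valueToCentile}}; centile 50 returns M(age)
#' exactly.
#'
#' @param model a \linkS4class{CentileModel}.
#' @param age age in years.
#' @param centile centile in (0, 100).
#' @return measurement in mm.
#' @export
centileToValue <- function(model, age, centile) {
    stopifnot(all(centile > 0), all(centile < 100))
    lms <- predictLMS(model, age)
    bccgInvZ(stats::qnorm(centile / 100), lms$L, lms$M, lms$S)
}

#' Tabulate centile curves on an age grid
#'
#' @param model a \linkS4class{CentileModel}.
#' @param centiles centile lines to draw (default the classical 7).
#' @param band extra reference band limits (default c(2.5, 97.5)).
#' @param ageGrid evaluation ages (default: 0.25-year grid over the domain).
#' @return data.frame with column \code{age} and one column per centile
#'   (\code{p3}, \code{p10}, ...); curves are strictly ordered at every age.
#' @export
chartCurves <- function(model, centiles = c(3, 10, 25, 50, 75, 90, 97),
                        band = c(2.5, 97.5), ageGrid = NULL) {
    if (is.null(ageGrid))
        ageGrid <- seq(model@ageDomain[1], model@ageDomain[2], by = 0.25)
    all_c <- sort(unique(c(centiles, band)))
    out <- data.frame(age = ageGrid)
    for (a in all_c)
        out[[paste0("p", a)]] <- centileToValue(model, ageGrid, a)
    out
}

#' Average mm change per centile point
#'
#' Mean over the age grid and over adjacent centile pairs (a, a + 1),
#' a = 1..98, of the measurement difference. Summarises how many mm a
#' one-centile move represents on the chart.
#'
#' @param model a \linkS4class{CentileModel}.
#' @param ageGrid evaluation ages (default: integer ages over the domain).
#' @return mm per centile point (strictly positive).
#' @export
mmPerCentile <- function(model, ageGrid = NULL) {
    if (is.null(ageGrid))
        ageGrid <- seq(ceiling(model@ageDomain[1]),
                       floor(model@ageDomain[2]), by = 1)
    alphas <- 1:99
    gaps <- vapply(ageGrid, function(a) {
        v <- centileToValue(model, rep(a, length(alphas)), alphas)
        mean(diff(v))
    }, numeric(1))
    mean(gaps)
}

#' Centile precision implied by a measurement error
#'
#' Propagates a thickness error through the chart: the median over the age
#' grid of |centile(M(age) + maeMM) - 50|, i.e. how many centile points a
#' typical measurement error moves a median subject. A bootstrap 95\%
#' interval over ages is attached.
#'
#' @param model a \linkS4class{CentileModel}.
#' @param maeMM measurement error in mm (> 0).
#' @param ageGrid evaluation ages (default: integer ages over the domain).
#' @param nBoot bootstrap replicates (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return list(precision, ci, perAge).
#' @export
centilePrecision <- function(model, maeMM, ageGrid = NULL, nBoot = 500L,
                             seed = 1L) {
    stopifnot(maeMM > 0)
    if (is.null(ageGrid))
        ageGrid <- seq(ceiling(model@ageDomain[1]),
                       floor(model@ageDomain[2]), by = 1)
    lms <- predictLMS(model, ageGrid)
    perAge <- abs(valueToCentile(model, ageGrid, lms$M + maeMM) - 50)
    set.seed(seed)
    boots <- vapply(seq_len(nBoot), function(b)
        stats::median(sample(perAge, replace = TRUE)), numeric(1))
    list(precision = stats::median(perAge),
         ci = stats::quantile(boots, c(0.025, 0.975), names = FALSE),
         perAge = data.frame(age = ageGrid, centiles = perAge))
}

#' Leave-one-study-out stability of the median curve
#'
#' Refits the model excluding each study in turn (at the df of the full
#' fit) and reports the maximum absolute deviation of M(t) from the full
#' fit over the age grid.
#'
#' @param cohort cohort data.frame with a \code{study} column.
#' @param sex stratum to fit.
#' @param df named df to hold fixed, e.g. c(L = 1, M = 3, S = 2); default:
#'   selected by BIC on the full data.
#' @param ageGrid evaluation ages (default: integer ages over the domain).
#' @param seed passed to the fits.
#' @return data.frame(study, max_delta_mm) plus the full fit as attribute
#'   \code{"full"}.
#' @export
losoCurves <- function(cohort, sex, df = NULL, ageGrid = NULL, seed = 1L) {
    cohort <- validateCohort(cohort)
    studies <- unique(cohort$study[cohort$sex == sex])
    if (length(studies) < 3L)
        stop("need >= 3 distinct studies for LOSO", call. = FALSE)
    full <- if (is.null(df))
        fitLMS(cohort, sex, seed = seed)
    else
        fitLMS(cohort, sex, dfCandidates = df[["M"]],
               dfSCandidates = df[["S"]], dfLCandidates = df[["L"]],
               seed = seed)
    dfFix <- full@df
    if (is.null(ageGrid))
        ageGrid <- seq(ceiling(full@ageDomain[1]),
                       floor(full@ageDomain[2]), by = 1)
    mFull <- predictLMS(full, ageGrid)$M
    deltas <- vapply(studies, function(s) {
        keep <- cohort[cohort$study != s, ]
        fit <- fitLMS(keep, sex, dfCandidates = dfFix[["M"]],
                      dfSCandidates = dfFix[["S"]],
                      dfLCandidates = dfFix[["L"]], seed = seed)
        grid <- ageGrid[ageGrid >= fit@ageDomain[1] &
                        ageGrid <= fit@ageDomain[2]]
        max(abs(predictLMS(fit, grid)$M - mFull[match(grid, ageGrid)]))
    }, numeric(1))
    out <- data.frame(study = studies, max_delta_mm = deltas)
    attr(out, "full") <- full
    out
}

#' Serialise a centile model to JSON
#'
#' @param model a \linkS4class{CentileModel}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
saveCentileModel <- function(model, path) {
    obj <- list(sex = model@sex,
                curves = model@curves,
                df = as.list(model@df),
                n = model@n, loglik = model@loglik, bic = model@bic,
                ageDomain = model@ageDomain)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Load a centile model from JSON
#'
#' @param path JSON path written by \code{\link{saveCentileModel}}.
#' @return a \linkS4class{CentileModel}.
#' @export
loadCentileModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    fix <- function(cv) list(df = as.integer(cv$df),
                             knots = as.numeric(cv$knots),
                             boundary = as.numeric(cv$boundary),
                             coef = as.numeric(cv$coef))
    new("CentileModel", sex = obj$sex,
        curves = list(L = fix(obj$curves$L), M = fix(obj$curves$M),
                      S = fix(obj$curves$S)),
        df = unlist(obj$df), n = as.integer(obj$n),
        loglik = obj$loglik, bic = obj$bic,
        ageDomain = as.numeric(obj$ageDomain))
}
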