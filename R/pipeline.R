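#' Default pipeline configuration
#'
#' One nested list holding every module's tunable block: the preprocessing
#' chain, the slice-selection model input (5 mm MIP slabs at 256 x 256),
#' the segmentation working resolution (512 x 512) with tile shift and
#' Tversky parameters, and the chart-fitting block. Values round-trip
#' unchanged through YAML.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
    list(
        preprocess = list(target_mm = 1, median_radius = 1L, nbins = 256L,
                          p_lo = 0.5, p_hi = 99.5),
        slice_selection = list(thickness_mm = 5, input_size = 256L,
                               stride = 1L, epochs = 30L, batch_size = 64L,
                               lr = 5e-3, seed = 1L,
                               dispersion_warn_mm = 4),
        segmentation = list(input_size = 512L, n_tiles = 4L, shift = 16L,
                            alpha = 0.7, beta = 0.3, gamma = 4 / 3,
                            epochs = 30L, batch_size = 4L, lr = 5e-3,
                            seed = 1L, right_is_high_x = TRUE),
        charts = list(age_range = c(4, 35), collapse_age = 30,
                      df_candidates = 2:5,
                      centiles = c(3, 10, 25, 50, 75, 90, 97),
                      band = c(2.5, 97.5)),
        seed = 1L
    )
}

#' Read a pipeline configuration from YAML
#'
#' Missing blocks/fields fall back to \code{\link{defaultPipelineConfig}}.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
readPipelineConfig <- function(path) {
    user <- yaml::read_yaml(path)
    utils::modifyList(defaultPipelineConfig(), user)
}

#' Write a pipeline configuration to YAML
#'
#' Uses enough floating-point precision that the configuration round-trips
#' unchanged (same \code{\link{configHash}}).
#'
#' @param config nested configuration list.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
    writeLines(yaml::as.yaml(config, precision = 17), path)
    invisible(path)
}

#' Hash of a configuration (provenance)
#'
#' Changes iff any configuration value changes.
#'
#' @param config nested configuration list.
#' @return character md5 digest.
#' @export
configHash <- function(config) {
    # canonicalise numeric storage so a YAML round trip (which drops the
    # integer/double distinction) hashes identically
    canon <- rapply(config, function(x)
        if (is.numeric(x)) as.numeric(x) else x, how = "replace")
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(deparse(canon, control = "exact"), f)
    unname(tools::md5sum(f))
}

.objectHash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}

.measurementAsList <- function(m) {
    list(tmt_left_mm = m@tmtLeftMM, tmt_right_mm = m@tmtRightMM,
         tmt_mean_mm = m@tmtMeanMM, csa_left_mm2 = m@csaLeftMM2,
         csa_right_mm2 = m@csaRightMM2, slice_index = m@sliceIndex,
         flags = as.list(m@flags))
}

#' Run the full measurement pipeline on one subject
#'
#' preprocess -> slice selection -> segmentation -> morphometry ->
#' optional centile lookup. A failure at any stage yields a structured
#' failure record naming the stage (no exception); every stage is logged
#' with its timing to the message stream, never into the result, so
#' outputs are byte-identical across runs with fixed inputs.
#'
#' @param input path to a NIfTI file, or an \linkS4class{MRIVolume}.
#' @param sliceModel a \linkS4class{SliceRegressor}.
#' @param segModel a \linkS4class{Segmenter}.
#' @param config pipeline configuration (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param age,sex optional subject age (years) and sex ("M"/"F").
#' @param chart optional \linkS4class{CentileModel} (or path to one saved
#'   as JSON); a centile is reported only when chart, age and sex are all
#'   supplied.
#' @param subjectId identifier for the output record (default: file name).
#' @param outJSON optional path; when given the result is written as JSON.
#' @return list: either a result record (status "ok", with slice,
#'   measurement, optional centile, warnings, provenance) or a failure
#'   record (status "failed", stage, message).
#' @export
runMeasure <- function(input, sliceModel, segModel,
                       config = defaultPipelineConfig(),
                       age = NULL, sex = NULL, chart = NULL,
                       subjectId = NULL, outJSON = NULL) {
    t0 <- proc.time()[["elapsed"]]
    stageTimes <- c()
    tick <- function(stage) {
        t1 <- proc.time()[["elapsed"]]
        message(sprintf("[measure] %-10s %.2fs", stage,
                        t1 - t0 - sum(stageTimes)))
        stageTimes <<- c(stageTimes, t1 - t0 - sum(stageTimes))
    }
    fail <- function(stage, e) {
        rec <- list(status = "failed", subject = subjectId, stage = stage,
                    message = conditionMessage(e))
        if (!is.null(outJSON))
            jsonlite::write_json(rec, outJSON, auto_unbox = TRUE, digits = NA)
        rec
    }
    if (is.character(chart)) chart <- loadCentileModel(chart)
    if (is.null(subjectId))
        subjectId <- if (is.character(input)) basename(input) else "subject"
    warningsSeen <- character()
    withCallingHandlers({
        vol <- tryCatch(
            if (is.character(input)) loadVolume(input) else input,
            error = function(e) e)
        if (inherits(vol, "error")) return(fail("load", vol))
        tick("load")
        pre <- tryCatch(preprocessVolume(vol, config$preprocess),
                        error = function(e) e)
        if (inherits(pre, "error")) return(fail("preprocess", pre))
        tick("preprocess")
        sl <- tryCatch(predictTargetSlice(pre, sliceModel,
                 stride = config$slice_selection$stride,
                 thicknessMM = config$slice_selection$thickness_mm,
                 inputSize = config$slice_selection$input_size,
                 warnMM = config$slice_selection$dispersion_warn_mm),
                 error = function(e) e)
        if (inherits(sl, "error")) return(fail("slice_selection", sl))
        tick("slice")
        seg <- tryCatch(segmentMuscles(pre@data[, , sl@targetIndex],
                 segModel, config$segmentation,
                 spacingMM = pre@spacing[1:2]),
                 error = function(e) e)
        if (inherits(seg, "error")) return(fail("segmentation", seg))
        tick("segment")
        meas <- tryCatch(measureMusclePair(seg$left, seg$right,
                 spacingMM = pre@spacing[1:2], sliceIndex = sl@targetIndex),
                 error = function(e) e)
        if (inherits(meas, "error")) return(fail("morphometry", meas))
        tick("measure")
        centile <- NULL
        if (!is.null(chart) && !is.null(age) && !is.null(sex)) {
            if (chart@sex != sex)
                warningsSeen <- c(warningsSeen,
                                  "chart sex differs from subject sex")
            centile <- tryCatch(
                valueToCentile(chart, age, meas@tmtMeanMM),
                error = function(e) e)
            if (inherits(centile, "error"))
                return(fail("centile", centile))
            tick("centile")
        }
        res <- list(
            status = "ok",
            subject = subjectId,
            slice = list(target_index = sl@targetIndex,
                         dispersion_mm = sl@dispersionMM),
            measurement = .measurementAsList(meas),
            centile = centile,
            warnings = as.list(c(warningsSeen, seg$flags)),
            provenance = list(config_hash = configHash(config),
                              slice_model_hash = .objectHash(sliceModel),
                              seg_model_hash = .objectHash(segModel),
                              seed = config$seed)
        )
        if (!is.null(outJSON))
            jsonlite::write_json(res, outJSON, auto_unbox = TRUE, digits = NA)
        res
    }, warning = function(w) {
        warningsSeen <<- c(warningsSeen, conditionMessage(w))
        invokeRestart("muffleWarning")
    })
}

#' Run the pipeline over a batch manifest
#'
#' The manifest needs columns \code{path} and \code{id}; optional
#' \code{age}, \code{sex}, \code{study}. Per-row failures are isolated:
#' the run continues and failures are reported alongside the results. The
#' returned cohort table feeds \code{\link{fitLMS}} directly.
#'
#' @param manifest data.frame or path to a CSV manifest.
#' @inheritParams runMeasure
#' @return list: \code{results} (per-subject records), \code{cohort}
#'   (data.frame id, study, age, sex, tmt_mm for successful rows with age
#'   and sex), \code{summary} (counts).
#' @export
runBatch <- function(manifest, sliceModel, segModel,
                     config = defaultPipelineConfig(), chart = NULL) {
    if (is.character(manifest))
        manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
    if (!all(c("path", "id") %in% names(manifest)))
        stop("manifest needs columns path, id", call. = FALSE)
    results <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
        row <- manifest[i, ]
        results[[i]] <- runMeasure(row$path, sliceModel, segModel, config,
            age = if ("age" %in% names(row)) row$age else NULL,
            sex = if ("sex" %in% names(row)) row$sex else NULL,
            chart = chart, subjectId = row$id)
    }
    ok <- vapply(results, function(r) identical(r$status, "ok"), logical(1))
    cohort <- do.call(rbind, lapply(which(ok), function(i) {
        row <- manifest[i, ]
        data.frame(id = row$id,
                   study = if ("study" %in% names(row)) row$study else "batch",
                   age = if ("age" %in% names(row)) row$age else NA_real_,
                   sex = if ("sex" %in% names(row)) row$sex else NA_character_,
                   tmt_mm = results[[i]]$measurement$tmt_mean_mm,
                   stringsAsFactors = FALSE)
    }))
    list(results = results, cohort = cohort,
         summary = list(n = nrow(manifest), n_ok = sum(ok),
                        n_failed = sum(!ok)))
}
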