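#' Configuration of the full analysis pipeline
#'
#' Bundles everything the five-stage workflow needs: the data source
#' (synthetic generator config or a spectra CSV), preprocessing
#' parameters, the regions and wavelength modes to run, optimizer budgets
#' for wavelength selection and architecture search, classifier
#' parameters, the evaluation plan, and the master seed. The master seed
#' fans out to stage-specific seeds by fixed offsets so stages can be
#' rerun in isolation.
#'
#' @param generator a \code{\link{generatorConfig}} (used when
#'   \code{inputCSV} is NULL).
#' @param inputCSV optional path to a reflectance spectra CSV.
#' @param detrendOrder,medianWindow preprocessing parameters.
#' @param regions subset of \code{c("swir", "visnir")}.
#' @param wavelengthModes subset of \code{c("effective", "full")}.
#' @param k number of effective wavelengths per region.
#' @param selectionParams,selectionEpochs CA budget and inner-network
#'   epochs for wavelength selection.
#' @param archParams,archEpochs optimizer budget and per-candidate epochs
#'   for the ANN architecture searches.
#' @param knnK,ldaEntryAlpha,ldaExitAlpha classifier parameters.
#' @param nIterations repeated-split evaluation iterations.
#' @param memberEpochs per-iteration training epochs of the ANN members.
#' @param seed master seed (mandatory, integer).
#' @return A list of class \code{"runConfig"}.
#' @export
runConfig <- function(generator = generatorConfig(), inputCSV = NULL,
                      detrendOrder = 2L, medianWindow = 5L,
                      regions = c("swir", "visnir"),
                      wavelengthModes = c("effective", "full"),
                      k = 3L,
                      selectionParams = optimizerParams(
                          populationSize = 16L, maxIterations = 6L),
                      selectionEpochs = 100L,
                      archParams = optimizerParams(
                          populationSize = 10L, maxIterations = 3L,
                          nImperialists = 3L, harmonyMemorySize = 10L,
                          maxEvaluations = 30L),
                      archEpochs = 100L,
                      knnK = 5L, ldaEntryAlpha = 0.05, ldaExitAlpha = 0.10,
                      nIterations = 200L, memberEpochs = 120L,
                      seed = 1L) {
    regions <- match.arg(regions, c("swir", "visnir"), several.ok = TRUE)
    wavelengthModes <- match.arg(wavelengthModes, c("effective", "full"),
                                 several.ok = TRUE)
    if (is.null(seed)) stop("a seed is mandatory")
    structure(list(
        generator = generator, inputCSV = inputCSV,
        detrendOrder = as.integer(detrendOrder),
        medianWindow = as.integer(medianWindow),
        regions = regions, wavelengthModes = wavelengthModes,
        k = as.integer(k),
        selectionParams = selectionParams,
        selectionEpochs = as.integer(selectionEpochs),
        archParams = archParams, archEpochs = as.integer(archEpochs),
        knnK = as.integer(knnK),
        ldaEntryAlpha = ldaEntryAlpha, ldaExitAlpha = ldaExitAlpha,
        nIterations = as.integer(nIterations),
        memberEpochs = as.integer(memberEpochs),
        seed = as.integer(seed)
    ), class = "runConfig")
}

prepareOutDir <- function(outDir, overwrite) {
    if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite) {
        stop("output directory exists and is not empty; use overwrite = TRUE")
    }
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    invisible(outDir)
}

logLine <- function(logPath, ...) {
    cat(paste0(..., "\n"), file = logPath, append = TRUE)
}

configSnapshot <- function(config) {
    snap <- config
    snap$generator$plantedBands <- as.list(snap$generator$plantedBands)
    lapply(snap, function(el) if (is.list(el)) unclass(el) else el)
}

#' Pipeline stage commands
#'
#' Thin orchestration wrappers mirroring the command-line subcommands.
#' \code{cmdSimulate} writes the generator output (spectra CSV plus a
#' JSON file with the planted band centers); \code{cmdPreprocess} applies
#' the fixed preprocessing chain to a spectra CSV; \code{cmdSelect} runs
#' wavelength selection on a preprocessed CSV; \code{cmdMetrics} computes
#' the metric report of a stored 2x2 confusion matrix; \code{cmdRunAll}
#' executes the whole workflow (see \code{\link{runPipeline}}).
#'
#' @param config a \code{\link{runConfig}} (or \code{\link{generatorConfig}}
#'   for \code{cmdSimulate}).
#' @param outDir output directory.
#' @param overwrite allow writing into a non-empty directory / over an
#'   existing file.
#' @return See the individual descriptions; all return their main result
#'   invisibly and write files as a side effect.
#' @export
cmdSimulate <- function(config, outDir, overwrite = FALSE) {
    gen <- if (inherits(config, "runConfig")) config$generator else config
    prepareOutDir(outDir, overwrite)
    csv <- file.path(outDir, "spectra.csv")
    if (file.exists(csv) && !overwrite) stop("output exists: ", csv)
    ds <- generateDataset(gen)
    writeSpectraCSV(ds, csv)
    jsonlite::write_json(list(planted_centers_nm = plantedTruth(gen),
                              seed = gen$seed),
                         file.path(outDir, "planted_truth.json"),
                         digits = NA, auto_unbox = TRUE)
    invisible(ds)
}

#' @rdname cmdSimulate
#' @param inputCSV path to a reflectance spectra CSV.
#' @param outCSV output path for the preprocessed spectra.
#' @param detrendOrder,medianWindow preprocessing parameters.
#' @export
cmdPreprocess <- function(inputCSV, outCSV, detrendOrder = 2L,
                          medianWindow = 5L, overwrite = FALSE) {
    if (file.exists(outCSV) && !overwrite) stop("output exists: ", outCSV)
    pre <- preprocessSpectra(readSpectraCSV(inputCSV),
                             detrendOrder = detrendOrder,
                             medianWindow = medianWindow)
    writeSpectraCSV(pre, outCSV)
    invisible(pre)
}

#' @rdname cmdSimulate
#' @param preprocessedCSV path to a preprocessed (absorbance) spectra CSV.
#' @param region \code{"swir"} or \code{"visnir"}.
#' @param k,params,epochs,seed selection controls, see
#'   \code{\link{selectWavelengths}}.
#' @param outJSON output path for the selection result.
#' @export
cmdSelect <- function(preprocessedCSV, region, outJSON, k = 3L,
                      params = optimizerParams(populationSize = 16L,
                                               maxIterations = 6L),
                      epochs = 100L, seed = 1L, overwrite = FALSE) {
    if (file.exists(outJSON) && !overwrite) stop("output exists: ", outJSON)
    ds <- readSpectraCSV(preprocessedCSV, domain = "absorbance")
    regionSet <- splitRegions(ds)[[region]]
    sel <- selectWavelengths(regionSet, region, k = k, params = params,
                             seed = seed, epochs = epochs)
    selectionToJSON(sel, outJSON)
    invisible(sel)
}

#' @rdname cmdSimulate
#' @param cm path to a CSV holding a 2x2 confusion matrix (rows predicted
#'   healthy/defective, columns actual), or the matrix itself.
#' @export
cmdMetrics <- function(cm) {
    if (is.character(cm)) {
        cm <- as.matrix(utils::read.csv(cm, row.names = 1))
    }
    cm <- as.matrix(cm)
    computeMetrics(confusionMatrix2x2(cm[1, 1], cm[1, 2], cm[2, 1],
                                      cm[2, 2]))
}

buildMembers <- function(config, icaArch, hsArch) {
    list(
        memberANN("ANN-ICA", icaArch, epochs = config$memberEpochs),
        memberANN("ANN-HS", hsArch, epochs = config$memberEpochs),
        memberKNN(k = config$knnK),
        memberLDA(config$ldaEntryAlpha, config$ldaExitAlpha)
    )
}

#' Run the complete spectra-to-decision workflow
#'
#' Stages: (1) generate or ingest reflectance spectra; (2) preprocess
#' (absorbance, detrend, median smoothing); (3) per region, select the k
#' effective wavelengths with the ANN-CA wrapper; (4) search the hybrid
#' classifier architectures once per region (ANN-ICA and ANN-HS) on a
#' held-out split; (5) evaluate the four-member majority-voting ensemble
#' with repeated stratified splits, for the effective wavelengths and/or
#' the full spectrum; then compare mean ensemble CCRs of the two
#' wavelength modes across regions with a paired two-tailed t-test.
#' All results are written under \code{outDir}; \code{results.json} is
#' byte-identical across reruns with the same config and seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return The report structure written to \code{results.json},
#'   invisibly; the evaluation reports themselves are attached as
#'   \code{attr(, "reports")}.
#' @export
runPipeline <- function(config, outDir, overwrite = FALSE) {
    stopifnot(inherits(config, "runConfig"))
    if (!length(config$regions)) stop("stage config: no regions requested")
    prepareOutDir(outDir, overwrite)
    logPath <- file.path(outDir, "run.log")
    cat("", file = logPath)
    jsonlite::write_json(configSnapshot(config),
                         file.path(outDir, "config.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
    stage <- function(tag, expr) {
        tryCatch(expr, error = function(e) {
            stop(sprintf("[stage %s] %s", tag, conditionMessage(e)),
                 call. = FALSE)
        })
    }
    ds <- stage("ingest", {
        if (!is.null(config$inputCSV)) readSpectraCSV(config$inputCSV)
        else generateDataset(config$generator)
    })
    logLine(logPath, "ingest: ", ncol(ds), " samples")
    pre <- stage("preprocess", preprocessSpectra(
        ds, config$detrendOrder, config$medianWindow))
    logLine(logPath, "preprocess: ",
            paste(metadata(pre)$processing, collapse = " -> "))
    regions <- stage("regions", splitRegions(pre))

    results <- list(seed = config$seed, regions = list())
    reports <- list()
    for (rg in config$regions) {
        regionSet <- regions[[rg]]
        rgRes <- list()
        sel <- NULL
        arch <- NULL
        if ("effective" %in% config$wavelengthModes) {
            sel <- stage(paste0("select:", rg), selectWavelengths(
                regionSet, rg, k = config$k,
                params = config$selectionParams,
                seed = deriveSeed(config$seed, 41L, match(rg, c("swir", "visnir"))),
                epochs = config$selectionEpochs))
            logLine(logPath, "select ", rg, ": ",
                    paste(sel$wavelengths, collapse = ", "),
                    " nm (MSE ", signif(sel$fitness, 4), ")")
            rgRes$selection <- list(wavelengths = sel$wavelengths,
                                    fitness = sel$fitness,
                                    evaluations = sel$evaluations)
        }
        for (mode in config$wavelengthModes) {
            dsMode <- if (mode == "effective") {
                restrictWavelengths(regionSet, sel$wavelengths)
            } else regionSet
            if (is.null(arch)) {
                arch <- stage(paste0("architecture:", rg), {
                    sp <- stratifiedSplit(classLabels(dsMode),
                                          c(0.6, 0.3, 0.1),
                                          deriveSeed(config$seed, 43L))
                    xm <- spectraMatrix(dsMode); ym <- classLabels(dsMode)
                    list(
                        ica = annMetaheuristicFit(
                            xm[sp$train, , drop = FALSE], ym[sp$train],
                            xm[sp$test, , drop = FALSE], ym[sp$test],
                            xm[sp$validation, , drop = FALSE],
                            ym[sp$validation],
                            method = "ica", params = config$archParams,
                            seed = deriveSeed(config$seed, 47L),
                            epochs = config$archEpochs),
                        hs = annMetaheuristicFit(
                            xm[sp$train, , drop = FALSE], ym[sp$train],
                            xm[sp$test, , drop = FALSE], ym[sp$test],
                            xm[sp$validation, , drop = FALSE],
                            ym[sp$validation],
                            method = "hs", params = config$archParams,
                            seed = deriveSeed(config$seed, 53L),
                            epochs = config$archEpochs)
                    )
                })
                logLine(logPath, "architecture ", rg, ": ICA ",
                        paste(arch$ica$architecture@neurons, collapse = "x"),
                        ", HS ",
                        paste(arch$hs$architecture@neurons, collapse = "x"))
            }
            rep <- stage(paste0("evaluate:", rg, ":", mode),
                runRepeatedEvaluation(
                    dsMode,
                    buildMembers(config, arch$ica$architecture,
                                 arch$hs$architecture),
                    nIterations = config$nIterations,
                    seed = deriveSeed(config$seed, 59L,
                                      match(rg, c("swir", "visnir")),
                                      match(mode, c("effective", "full")))))
            reports[[paste(rg, mode, sep = "_")]] <- rep
            utils::write.csv(
                as.data.frame(rep$iterationCCR),
                file.path(outDir, sprintf("ccr_%s_%s.csv", rg, mode)),
                row.names = FALSE)
            for (nm in names(rep$pooled)) {
                utils::write.csv(
                    as.data.frame(unclass(rep$pooled[[nm]])),
                    file.path(outDir, sprintf("confusion_%s_%s_%s.csv",
                                              rg, mode, nm)))
            }
            rgRes[[mode]] <- list(
                pooledMV = if ("MV" %in% names(rep$pooled)) {
                    unclass(rep$pooled[["MV"]])
                } else NULL,
                ccr = vapply(rep$metrics, function(m) m$ccr, numeric(1)),
                auc = vapply(rep$roc, function(r) {
                    if (is.null(r)) NA_real_ else r$auc
                }, numeric(1)),
                meanIterationCCR = colMeans(rep$iterationCCR)
            )
            logLine(logPath, "evaluate ", rg, " ", mode, ": MV CCR ",
                    round(rgRes[[mode]]$ccr[["MV"]], 1), "%")
        }
        results$regions[[rg]] <- rgRes
    }

    if (all(c("effective", "full") %in% config$wavelengthModes) &&
        length(config$regions) >= 2L) {
        eff <- vapply(config$regions, function(rg) {
            results$regions[[rg]]$effective$ccr[["MV"]]
        }, numeric(1))
        full <- vapply(config$regions, function(rg) {
            results$regions[[rg]]$full$ccr[["MV"]]
        }, numeric(1))
        cmp <- stage("compare", pairedTTest(eff, full))
        results$comparison <- list(
            pairs = config$regions, effectiveCCR = eff, fullCCR = full,
            meanDiff = cmp$meanDiff, sdDiff = cmp$sdDiff,
            t = cmp$t, df = cmp$df, p = cmp$p)
        logLine(logPath, "compare effective vs full: t = ",
                round(cmp$t, 2), ", p = ", round(cmp$p, 3))
    }

    jsonlite::write_json(results, file.path(outDir, "results.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
    attr(results, "reports") <- reports
    invisible(results)
}

#' @rdname cmdSimulate
#' @export
cmdRunAll <- function(config, outDir, overwrite = FALSE) {
    runPipeline(config, outDir, overwrite)
}
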