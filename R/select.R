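#' Wrapper selection of effective wavelengths (ANN-CA)
#'
#' Searches for the k wavelengths of a spectral region whose columns give
#' the lowest test mean squared error of the fixed selection network
#' (\code{\link{fixedSelectionANN}}), using the cultural algorithm over k
#' integer index dimensions. For every candidate, the data are split
#' 60/30/10 (train/test/validation, stratified) with a split seed derived
#' deterministically from the candidate indices, the network is trained on
#' the candidate columns, and its test MSE is the candidate's fitness.
#' Duplicate indices within a candidate are repaired to the nearest unused
#' index so a candidate always carries k distinct wavelengths.
#'
#' @param dataset a preprocessed \linkS4class{SpectralSet} (one region).
#' @param region label stored in the result (\code{"visnir"},
#'   \code{"swir"}, or \code{"full"}).
#' @param k number of wavelengths to select (default 3).
#' @param params an \code{\link{optimizerParams}} controlling the CA
#'   budget.
#' @param seed master seed for the search and the per-candidate splits.
#' @param epochs training epoch budget of the inner network.
#' @param topM number of leading candidates entered in the refinement
#'   race.
#' @param restarts independent cultural-algorithm restarts; all share the
#'   candidate cache, and the race pools the candidates of every restart.
#' @param refineSplits number of splits averaged per candidate in the
#'   refinement race.
#' @return A list of class \code{"selectionResult"}: \code{region},
#'   \code{wavelengths} (sorted), \code{indices}, \code{fitness} (the
#'   winner's refined mean test MSE), \code{splitSeeds} and
#'   \code{annSeed} of the winning candidate, \code{trace} (optimizer
#'   history), \code{evaluations}, \code{seed}.
#' @export
selectWavelengths <- function(dataset, region = "swir", k = 3L,
                              params = optimizerParams(),
                              seed = 1L, epochs = 120L, topM = 8L,
                              refineSplits = 6L, restarts = 3L) {
    k <- as.integer(k)
    x <- spectraMatrix(dataset)
    y <- classLabels(dataset)
    p <- ncol(x)
    if (k < 1L || k > p) stop("k must be between 1 and the number of wavelengths")
    wl <- wavelengths(dataset)
    annSeed <- deriveSeed(seed, 7L)
    cache <- new.env(parent = emptyenv())

    # search fitness: one split, re-randomized per candidate (cheap, and
    # no single split can be overfitted by the whole search);
    # race fitness: a common panel of splits shared by all finalists, so
    # candidate comparisons are paired and free of split luck
    restartNo <- 1L
    searchSplitSeed <- function(idx) {
        deriveSeed(seed, 11L, restartNo, sum(idx * seq_along(idx)), sum(idx))
    }
    raceSplitSeeds <- function(rounds) {
        vapply(rounds, function(r) deriveSeed(seed, 13L, r), integer(1))
    }
    scoreCandidate <- function(idx, rounds) {
        mean(vapply(raceSplitSeeds(rounds), function(ss) {
            selectionObjective(x, y, idx, ss, annSeed, epochs)
        }, numeric(1)))
    }
    objective <- function(point) {
        idx <- repairIndices(sort(as.integer(unlist(point))), p)
        key <- paste(restartNo, paste(idx, collapse = ","))
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit$fitness)
        f <- selectionObjective(x, y, idx, searchSplitSeed(idx), annSeed,
                                epochs)
        cache[[key]] <- list(indices = idx, fitness = f)
        f
    }

    if (k == p) {
        # degenerate case: the selection is the full grid, evaluated once
        f <- objective(as.list(seq_len(p)))
        res <- list(history = f, evaluations = 1L)
    } else {
        space <- searchSpace(lapply(seq_len(k), function(i) intDim(1L, p)))
        res <- NULL
        for (r in seq_len(max(1L, restarts))) {
            restartNo <- r
            params$seed <- deriveSeed(seed, 3L, r)
            this <- caOptimize(objective, space, params)
            res <- if (is.null(res)) this else {
                this$history <- c(res$history, this$history)
                this$evaluations <- res$evaluations + this$evaluations
                this
            }
        }
    }

    # refinement race among the best candidates seen (deduplicated across
    # restarts, keeping each candidate's best search estimate), plus
    # recombined candidates assembled from the discovered bands
    seen <- lapply(ls(cache), function(key) cache[[key]])
    seen <- seen[order(vapply(seen, `[[`, numeric(1), "fitness"))]
    dedup <- !duplicated(vapply(seen, function(cand) {
        paste(cand$indices, collapse = ",")
    }, character(1)))
    seen <- seen[dedup]
    finalists <- seen[seq_len(min(topM, length(seen)))]
    recombined <- recombineElites(seen, k, p)
    have <- vapply(finalists, function(cand) {
        paste(cand$indices, collapse = ",")
    }, character(1))
    for (idx in recombined) {
        key <- paste(idx, collapse = ",")
        if (!(key %in% have)) {
            finalists <- c(finalists, list(list(indices = idx,
                                                fitness = NA_real_)))
            have <- c(have, key)
        }
    }
    # sequential-halving race: widen the split average only for the
    # leaders, so a lucky single-split estimate cannot win outright
    stageSizes <- c(2L, max(refineSplits - 2L, 4L), 6L)
    stageKeep <- c(8L, 3L, 1L)
    pool <- finalists
    score <- rep(0, length(pool))
    roundsUsed <- integer(0)
    nextRound <- 1L
    for (stg in seq_along(stageSizes)) {
        rounds <- nextRound + seq_len(stageSizes[stg]) - 1L
        nextRound <- nextRound + stageSizes[stg]
        newScores <- vapply(pool, function(cand) {
            scoreCandidate(cand$indices, rounds)
        }, numeric(1))
        nOld <- length(roundsUsed)
        score <- (score * nOld + newScores * length(rounds)) /
            (nOld + length(rounds))
        roundsUsed <- c(roundsUsed, rounds)
        keepIdx <- order(score)[seq_len(min(stageKeep[stg], length(pool)))]
        pool <- pool[keepIdx]; score <- score[keepIdx]
        if (length(pool) == 1L && stg >= 2L) break
    }
    winner <- pool[[1L]]
    winnerFitness <- score[[1L]]
    racedRounds <- roundsUsed

    # local polish: coordinate descent around the winner on a fresh
    # common panel, so near-miss picks settle onto the local MSE minimum
    polishRounds <- max(racedRounds) + seq_len(4L)
    offsets <- c(-24L, -16L, -8L, -4L, 4L, 8L, 16L, 24L)
    polishCache <- new.env(parent = emptyenv())
    polishScore <- function(idx) {
        key <- paste(idx, collapse = ",")
        hit <- polishCache[[key]]
        if (!is.null(hit)) return(hit)
        v <- scoreCandidate(idx, polishRounds)
        polishCache[[key]] <- v
        v
    }
    idx <- sort(winner$indices)
    if (k < p) {
        cur <- polishScore(idx)
        for (pass in 1:3) {
            moved <- FALSE
            for (dPos in seq_len(k)) {
                bestIdx <- idx; bestScore <- cur
                for (off in offsets) {
                    cand <- idx
                    cand[dPos] <- cand[dPos] + off
                    if (cand[dPos] < 1L || cand[dPos] > p ||
                        anyDuplicated(cand)) next
                    cand <- sort(cand)
                    v <- polishScore(cand)
                    if (v < bestScore - 1e-6) {
                        bestScore <- v; bestIdx <- cand
                    }
                }
                if (!identical(bestIdx, idx)) {
                    idx <- bestIdx; cur <- bestScore; moved <- TRUE
                }
            }
            if (!moved) break
        }
        winnerFitness <- cur
        racedRounds <- polishRounds
    }
    structure(list(
        region = region,
        wavelengths = wl[idx],
        indices = idx,
        fitness = winnerFitness,
        splitSeeds = raceSplitSeeds(racedRounds),
        annSeed = annSeed,
        trace = res$history,
        evaluations = res$evaluations,
        seed = as.integer(seed),
        epochs = as.integer(epochs)
    ), class = "selectionResult")
}

# Pick well-separated representative wavelengths from the best search
# candidates (greedy: best-scoring index first, suppressing a +/- radius
# neighbourhood around each pick), then enumerate all k-subsets.
# Returns a list of sorted index vectors.
recombineElites <- function(seen, k, p, topN = 60L, radius = 12L,
                            maxReps = 8L) {
    seen <- seen[seq_len(min(topN, length(seen)))]
    if (!length(seen)) return(list())
    pos <- unlist(lapply(seen, `[[`, "indices"))
    fit <- rep(vapply(seen, `[[`, numeric(1), "fitness"),
               vapply(seen, function(cand) length(cand$indices), integer(1)))
    reps <- integer(0)
    while (length(pos) && length(reps) < maxReps) {
        b <- which.min(fit)
        reps <- c(reps, pos[b])
        keep <- abs(pos - pos[b]) > radius
        pos <- pos[keep]; fit <- fit[keep]
    }
    if (length(reps) < k) return(list())
    combos <- utils::combn(sort(reps), k, simplify = FALSE)
    lapply(combos, function(idx) sort(as.integer(idx)))
}

# Replace duplicate column indices by the nearest unused index, keeping k
# distinct wavelengths per candidate.
repairIndices <- function(idx, p) {
    out <- integer(0)
    for (i in idx) {
        if (!(i %in% out)) {
            out <- c(out, i)
            next
        }
        found <- NA_integer_
        for (offset in seq_len(p)) {
            for (cand in c(i - offset, i + offset)) {
                if (cand >= 1L && cand <= p && !(cand %in% out)) {
                    found <- cand
                    break
                }
            }
            if (!is.na(found)) break
        }
        if (is.na(found)) stop("cannot repair duplicate indices")
        out <- c(out, found)
    }
    out
}

# Fitness of one candidate index set: test MSE of the fixed selection
# network under a deterministic stratified 60/30/10 split.
selectionObjective <- function(x, y, idx, splitSeed, annSeed, epochs) {
    sp <- stratifiedSplit(y, c(0.6, 0.3, 0.1), splitSeed)
    xs <- x[, idx, drop = FALSE]
    model <- trainANN(xs[sp$train, , drop = FALSE], y[sp$train],
                      xs[sp$test, , drop = FALSE], y[sp$test],
                      architecture = fixedSelectionANN(),
                      seed = annSeed, epochs = epochs,
                      xVal = xs[sp$validation, , drop = FALSE],
                      yVal = y[sp$validation], patience = 20L)
    model$testMSE
}

#' Re-evaluate a selection result
#'
#' Recomputes the objective for the wavelengths reported by
#' \code{\link{selectWavelengths}} using the recorded split and weight
#' seeds; by construction it reproduces the reported fitness exactly.
#'
#' @param dataset the same \linkS4class{SpectralSet} the selection ran on.
#' @param result a \code{"selectionResult"}.
#' @return The recomputed test MSE.
#' @export
reevaluateSelection <- function(dataset, result) {
    x <- spectraMatrix(dataset)
    y <- classLabels(dataset)
    mean(vapply(result$splitSeeds, function(ss) {
        selectionObjective(x, y, result$indices, ss, result$annSeed,
                           result$epochs)
    }, numeric(1)))
}

#' @export
print.selectionResult <- function(x, ...) {
    cat(sprintf("<selectionResult> region %s: %s nm (test MSE %.4g, %d evals)\n",
                x$region, paste(x$wavelengths, collapse = ", "),
                x$fitness, x$evaluations))
    invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param result a \code{"selectionResult"}.
#' @param path JSON file path.
#' @param tracePath optional CSV path the optimizer trace was written to;
#'   recorded in the document.
#' @export
selectionToJSON <- function(result, path, tracePath = NULL) {
    doc <- list(region = result$region,
                wavelengths = result$wavelengths,
                fitness = result$fitness,
                seed = result$seed,
                evaluations = result$evaluations,
                trace_file = tracePath)
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}
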