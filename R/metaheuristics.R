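#' Define a mixed discrete/continuous search space
#'
#' A search space is an ordered list of dimensions, each an integer range,
#' a real interval, or a categorical level set (all bounds inclusive).
#' Internally the optimizers work on a unit hypercube genotype; a decoded
#' point is a plain list with one element per dimension.
#'
#' @param ... dimensions built with \code{intDim}, \code{realDim},
#'   \code{catDim}, or a single list of such dimensions.
#' @return An object of class \code{"searchSpace"}.
#' @examples
#' searchSpace(realDim(-5, 5), intDim(1, 25), catDim(c("tanh", "relu")))
#' @export
searchSpace <- function(...) {
    dims <- list(...)
    if (length(dims) == 1L && is.list(dims[[1]]) &&
        !inherits(dims[[1]], "searchDim")) {
        dims <- dims[[1]]
    }
    if (!length(dims)) stop("search space must have at least one dimension")
    stopifnot(all(vapply(dims, inherits, logical(1), "searchDim")))
    structure(list(dims = dims), class = "searchSpace")
}

#' @rdname searchSpace
#' @export
intDim <- function(lower, upper) {
    stopifnot(upper >= lower)
    structure(list(kind = "integer", lower = as.integer(lower),
                   upper = as.integer(upper)), class = "searchDim")
}

#' @rdname searchSpace
#' @export
realDim <- function(lower, upper) {
    stopifnot(upper >= lower)
    structure(list(kind = "real", lower = lower, upper = upper),
              class = "searchDim")
}

#' @rdname searchSpace
#' @export
catDim <- function(levels) {
    stopifnot(length(levels) >= 1L)
    structure(list(kind = "categorical", levels = levels),
              class = "searchDim")
}

spaceSize <- function(space) length(space$dims)

isCatDim <- function(space) {
    vapply(space$dims, function(d) d$kind == "categorical", logical(1))
}

# Decode a unit-cube genotype to a domain point (list, one element per dim).
decodePoint <- function(space, z) {
    mapply(function(d, zj) {
        zj <- min(max(zj, 0), 1)
        switch(d$kind,
            real = d$lower + zj * (d$upper - d$lower),
            integer = {
                k <- d$upper - d$lower + 1L
                d$lower + min(as.integer(floor(zj * k)), k - 1L)
            },
            categorical = {
                k <- length(d$levels)
                d$levels[[1L + min(as.integer(floor(zj * k)), k - 1L)]]
            }
        )
    }, space$dims, z, SIMPLIFY = FALSE)
}

reflectUnit <- function(z) {
    z <- z %% 2
    ifelse(z > 1, 2 - z, z)
}

#' Optimizer parameters
#'
#' Shared and algorithm-specific knobs for the three population
#' metaheuristics. All rates lie in [0, 1]. The evaluation budget
#' (\code{maxEvaluations}) is a hard cap on objective calls; when
#' \code{NULL} it defaults to \code{populationSize * (maxIterations + 1)}
#' for the population algorithms and to
#' \code{harmonyMemorySize + maxIterations} for harmony search.
#'
#' @param populationSize population (countries) size.
#' @param maxIterations generation cap.
#' @param maxEvaluations hard objective-evaluation budget.
#' @param seed RNG seed; identical inputs give identical runs.
#' @param acceptanceFraction CA: fraction of the population whose positions
#'   update the normative belief bounds.
#' @param nImperialists ICA: number of elite countries taken as
#'   imperialists (must be < populationSize).
#' @param assimilationCoeff ICA: assimilation step coefficient (beta).
#' @param revolutionRate ICA: probability a colony is resampled uniformly.
#' @param coloniesMeanWeight ICA: weight (xi) of the mean colony cost in an
#'   empire's total power.
#' @param harmonyMemorySize HS: harmony memory size (>= 2).
#' @param memoryConsideringRate HS: probability a new value is drawn from
#'   memory (HMCR).
#' @param pitchAdjustingRate HS: probability a memory-drawn value is
#'   perturbed (PAR).
#' @param bandwidth HS: pitch-adjustment half-width on the unit-cube scale.
#' @return A list of class \code{"optimizerParams"}.
#' @export
optimizerParams <- function(populationSize = 30L, maxIterations = 100L,
                            maxEvaluations = NULL, seed = 1L,
                            acceptanceFraction = 0.3,
                            nImperialists = 8L, assimilationCoeff = 2,
                            revolutionRate = 0.1, coloniesMeanWeight = 0.1,
                            harmonyMemorySize = 30L,
                            memoryConsideringRate = 0.9,
                            pitchAdjustingRate = 0.3, bandwidth = 0.1) {
    p <- list(populationSize = as.integer(populationSize),
              maxIterations = as.integer(maxIterations),
              maxEvaluations = maxEvaluations, seed = as.integer(seed),
              acceptanceFraction = acceptanceFraction,
              nImperialists = as.integer(nImperialists),
              assimilationCoeff = assimilationCoeff,
              revolutionRate = revolutionRate,
              coloniesMeanWeight = coloniesMeanWeight,
              harmonyMemorySize = as.integer(harmonyMemorySize),
              memoryConsideringRate = memoryConsideringRate,
              pitchAdjustingRate = pitchAdjustingRate,
              bandwidth = bandwidth)
    rates <- c(p$acceptanceFraction, p$revolutionRate, p$coloniesMeanWeight,
               p$memoryConsideringRate, p$pitchAdjustingRate)
    if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
    if (p$populationSize < 2L) stop("populationSize must be >= 2")
    class(p) <- "optimizerParams"
    p
}

# Budget-capped evaluation bookkeeping shared by the optimizers.
makeEvaluator <- function(objective, space, budget) {
    count <- 0L
    evalZ <- function(z) {
        if (count >= budget) return(NA_real_)
        count <<- count + 1L
        as.numeric(objective(decodePoint(space, z)))
    }
    list(evalZ = evalZ,
         used = function() count,
         exhausted = function() count >= budget)
}

finishResult <- function(space, bestZ, bestFit, history, meanHistory,
                         evaluations, seed, algorithm) {
    structure(list(
        best = list(position = decodePoint(space, bestZ), z = bestZ,
                    fitness = bestFit),
        history = history, meanHistory = meanHistory,
        evaluations = evaluations, seed = seed, algorithm = algorithm
    ), class = "optimizerResult")
}

#' @export
print.optimizerResult <- function(x, ...) {
    cat(sprintf("<%s> best fitness %.6g after %d evaluations\n",
                x$algorithm, x$best$fitness, x$evaluations))
    invisible(x)
}

#' Write an optimizer trace as CSV
#'
#' Columns: iteration, best_fitness (best-so-far), mean_fitness.
#'
#' @param result an \code{"optimizerResult"}.
#' @param path output file path.
#' @export
writeOptimizerTrace <- function(result, path) {
    utils::write.csv(data.frame(
        iteration = seq_along(result$history),
        best_fitness = result$history,
        mean_fitness = result$meanHistory
    ), path, row.names = FALSE)
    invisible(path)
}

#' Cultural algorithm minimizer
#'
#' Population-plus-belief-space evolutionary minimizer. The belief space
#' holds situational knowledge (the best solution found) and normative
#' knowledge (per-dimension bounds spanned by the accepted elite, i.e. the
#' top \code{acceptanceFraction} of the population each generation).
#' Variation perturbs numeric dimensions with Gaussian steps scaled by the
#' normative range and directed back inside it, and categorical dimensions
#' by inheritance from the situational solution or uniform resampling.
#' Survivor selection is elitist (mu + lambda), so the best-so-far fitness
#' never increases.
#'
#' @param objective function taking a decoded point (list) and returning a
#'   scalar to minimize (lower is better).
#' @param space a \code{\link{searchSpace}}.
#' @param params an \code{\link{optimizerParams}}.
#' @return An \code{"optimizerResult"}: \code{best} (decoded position and
#'   fitness), \code{history} (best-so-far per generation),
#'   \code{meanHistory}, \code{evaluations}, \code{seed}.
#' @export
caOptimize <- function(objective, space, params = optimizerParams()) {
    stopifnot(inherits(space, "searchSpace"))
    d <- spaceSize(space)
    catMask <- isCatDim(space)
    N <- params$populationSize
    budget <- if (is.null(params$maxEvaluations)) {
        N * (params$maxIterations + 1L)
    } else params$maxEvaluations
    if (budget < 1L) stop("evaluation budget must be >= 1")
    ev <- makeEvaluator(objective, space, budget)
    iterCap <- if (is.null(params$maxEvaluations)) params$maxIterations
               else max(params$maxIterations, ceiling(budget / N))
    withLocalSeed(params$seed, {
        # Latin-hypercube start: per dimension, one point per stratum
        zs <- vapply(seq_len(d), function(j) {
            (sample.int(N) - stats::runif(N)) / N
        }, numeric(N))
        zs <- matrix(zs, N, d)
        fit <- apply(zs, 1, ev$evalZ)
        keep <- !is.na(fit)
        zs <- zs[keep, , drop = FALSE]; fit <- fit[keep]
        history <- min(fit); meanHistory <- mean(fit)
        nAccept <- max(1L, ceiling(params$acceptanceFraction * nrow(zs)))
        for (iter in seq_len(iterCap)) {
            if (ev$exhausted()) break
            ord <- order(fit)
            zs <- zs[ord, , drop = FALSE]; fit <- fit[ord]
            situational <- zs[1L, ]
            elite <- zs[seq_len(min(nAccept, nrow(zs))), , drop = FALSE]
            normLo <- apply(elite, 2, min)
            normHi <- apply(elite, 2, max)
            width <- pmax(normHi - normLo, 0.02)
            nOff <- nrow(zs)
            off <- matrix(0, nOff, d)
            for (i in seq_len(nOff)) {
                zi <- zs[i, ]
                for (j in seq_len(d)) {
                    if (catMask[j]) {
                        r <- stats::runif(1)
                        zi[j] <- if (r < 0.4) zi[j]
                                 else if (r < 0.7) situational[j]
                                 else stats::runif(1)
                    } else if (stats::runif(1) < 0.05) {
                        # rare uniform resampling keeps exploration alive
                        # after the normative bounds have contracted
                        zi[j] <- stats::runif(1)
                    } else if (stats::runif(1) < 0.25) {
                        # normative influence: recombine by drawing the
                        # value from the accepted elite's range
                        zi[j] <- stats::runif(1, normLo[j], normHi[j])
                    } else if (zi[j] < normLo[j]) {
                        zi[j] <- zi[j] + abs(stats::rnorm(1)) * width[j]
                    } else if (zi[j] > normHi[j]) {
                        zi[j] <- zi[j] - abs(stats::rnorm(1)) * width[j]
                    } else {
                        zi[j] <- zi[j] + stats::rnorm(1) * width[j]
                    }
                }
                off[i, ] <- reflectUnit(zi)
            }
            offFit <- apply(off, 1, ev$evalZ)
            okOff <- !is.na(offFit)
            zs <- rbind(zs, off[okOff, , drop = FALSE])
            fit <- c(fit, offFit[okOff])
            sel <- order(fit)[seq_len(min(N, length(fit)))]
            zs <- zs[sel, , drop = FALSE]; fit <- fit[sel]
            history <- c(history, min(fit))
            meanHistory <- c(meanHistory, mean(fit))
        }
        finishResult(space, zs[which.min(fit), ], min(fit), history,
                     meanHistory, ev$used(), params$seed, "CA")
    })
}

#' Imperialist competitive algorithm minimizer
#'
#' The initial countries are ranked; the best \code{nImperialists} become
#' imperialists and the remaining countries are distributed among them as
#' colonies, proportionally to normalized imperialist power. Each
#' iteration, colonies are assimilated (moved a random fraction of
#' \code{assimilationCoeff} towards their imperialist, per dimension),
#' occasionally undergo revolution (uniform resampling), swap roles with
#' their imperialist when they beat it, and the weakest colony of the
#' weakest empire (total cost = imperialist cost +
#' \code{coloniesMeanWeight} * mean colony cost) is handed to a
#' power-weighted competitor. Empires left without colonies collapse. The
#' global best country is tracked separately, so the best-so-far trace is
#' non-increasing.
#'
#' @inheritParams caOptimize
#' @return An \code{"optimizerResult"}; see \code{\link{caOptimize}}.
#' @export
icaOptimize <- function(objective, space, params = optimizerParams()) {
    stopifnot(inherits(space, "searchSpace"))
    d <- spaceSize(space)
    catMask <- isCatDim(space)
    N <- params$populationSize
    nImp <- params$nImperialists
    if (nImp >= N) stop("nImperialists must be smaller than populationSize")
    budget <- if (is.null(params$maxEvaluations)) {
        N * (params$maxIterations + 1L)
    } else params$maxEvaluations
    if (budget < 1L) stop("evaluation budget must be >= 1")
    ev <- makeEvaluator(objective, space, budget)
    iterCap <- if (is.null(params$maxEvaluations)) params$maxIterations
               else max(params$maxIterations, ceiling(budget / max(N - nImp, 1L)))
    withLocalSeed(params$seed, {
        zs <- matrix(stats::runif(N * d), N, d)
        fit <- apply(zs, 1, ev$evalZ)
        keep <- !is.na(fit)
        zs <- zs[keep, , drop = FALSE]; fit <- fit[keep]
        ord <- order(fit)
        zs <- zs[ord, , drop = FALSE]; fit <- fit[ord]
        bestZ <- zs[1L, ]; bestFit <- fit[1L]
        nImpEff <- min(nImp, max(1L, nrow(zs) - 1L))
        impCost <- fit[seq_len(nImpEff)]
        power <- max(impCost) - impCost
        power <- if (sum(power) > 0) power / sum(power)
                 else rep(1 / nImpEff, nImpEff)
        nColTotal <- nrow(zs) - nImpEff
        quota <- floor(power * nColTotal)
        while (sum(quota) < nColTotal) {
            quota[which.max(power)] <- quota[which.max(power)] + 1L
            power[which.max(power)] <- -1
        }
        colonyIdx <- nImpEff + seq_len(nColTotal)
        empires <- vector("list", nImpEff)
        pos <- 0L
        for (e in seq_len(nImpEff)) {
            take <- colonyIdx[pos + seq_len(quota[e])]
            pos <- pos + quota[e]
            empires[[e]] <- list(
                imp = zs[e, ], impFit = fit[e],
                col = zs[take, , drop = FALSE], colFit = fit[take]
            )
        }
        history <- bestFit
        meanHistory <- mean(fit)
        for (iter in seq_len(iterCap)) {
            if (ev$exhausted() || !length(empires)) break
            for (e in seq_along(empires)) {
                emp <- empires[[e]]
                nc <- nrow(emp$col)
                if (nc) {
                    for (ci in seq_len(nc)) {
                        z <- emp$col[ci, ]
                        if (stats::runif(1) < params$revolutionRate) {
                            z <- stats::runif(d)
                        } else {
                            step <- params$assimilationCoeff *
                                stats::runif(d) * (emp$imp - z)
                            z <- z + step
                            if (any(catMask)) {
                                take <- catMask & (stats::runif(d) < 0.5)
                                z[take] <- emp$imp[take]
                                z[catMask & !take] <- emp$col[ci, ][catMask & !take]
                            }
                        }
                        z <- reflectUnit(z)
                        f <- ev$evalZ(z)
                        if (!is.na(f)) {
                            emp$col[ci, ] <- z
                            emp$colFit[ci] <- f
                        }
                    }
                    wb <- which.min(emp$colFit)
                    if (emp$colFit[wb] < emp$impFit) {
                        tmpZ <- emp$imp; tmpF <- emp$impFit
                        emp$imp <- emp$col[wb, ]; emp$impFit <- emp$colFit[wb]
                        emp$col[wb, ] <- tmpZ; emp$colFit[wb] <- tmpF
                    }
                }
                empires[[e]] <- emp
                if (emp$impFit < bestFit) {
                    bestFit <- emp$impFit; bestZ <- emp$imp
                }
            }
            # imperialistic competition
            tc <- vapply(empires, function(emp) {
                emp$impFit + params$coloniesMeanWeight *
                    (if (nrow(emp$col)) mean(emp$colFit) else emp$impFit)
            }, numeric(1))
            if (length(empires) > 1L) {
                weakest <- which.max(tc)
                pw <- max(tc) - tc
                pw[weakest] <- 0
                winner <- if (sum(pw) > 0) {
                    sample(seq_along(empires), 1L, prob = pw / sum(pw))
                } else {
                    cands <- setdiff(seq_along(empires), weakest)
                    cands[sample.int(length(cands), 1L)]
                }
                wEmp <- empires[[weakest]]
                if (nrow(wEmp$col)) {
                    wc <- which.max(wEmp$colFit)
                    empires[[winner]]$col <-
                        rbind(empires[[winner]]$col, wEmp$col[wc, ])
                    empires[[winner]]$colFit <-
                        c(empires[[winner]]$colFit, wEmp$colFit[wc])
                    wEmp$col <- wEmp$col[-wc, , drop = FALSE]
                    wEmp$colFit <- wEmp$colFit[-wc]
                    empires[[weakest]] <- wEmp
                } else {
                    empires[[winner]]$col <-
                        rbind(empires[[winner]]$col, wEmp$imp)
                    empires[[winner]]$colFit <-
                        c(empires[[winner]]$colFit, wEmp$impFit)
                    empires[[weakest]] <- NULL
                }
            }
            allFit <- unlist(lapply(empires, function(emp) {
                c(emp$impFit, emp$colFit)
            }))
            history <- c(history, bestFit)
            meanHistory <- c(meanHistory, mean(allFit))
        }
        finishResult(space, bestZ, bestFit, history, meanHistory,
                     ev$used(), params$seed, "ICA")
    })
}

#' Harmony search minimizer
#'
#' Keeps a memory of \code{harmonyMemorySize} solutions. Each iteration
#' composes one new harmony dimension-wise: with probability
#' \code{memoryConsideringRate} the value is taken from a random memory
#' member (and, with probability \code{pitchAdjustingRate}, perturbed by up
#' to \code{bandwidth} for numeric dimensions or resampled for categorical
#' ones); otherwise it is drawn uniformly at random. The new harmony
#' replaces the worst memory member if it is better, which makes the
#' best-so-far trace non-increasing.
#'
#' @inheritParams caOptimize
#' @return An \code{"optimizerResult"}; see \code{\link{caOptimize}}.
#' @export
hsOptimize <- function(objective, space, params = optimizerParams()) {
    stopifnot(inherits(space, "searchSpace"))
    d <- spaceSize(space)
    catMask <- isCatDim(space)
    hms <- params$harmonyMemorySize
    if (hms < 2L) stop("harmony memory size must be >= 2")
    budget <- if (is.null(params$maxEvaluations)) {
        hms + params$maxIterations
    } else params$maxEvaluations
    if (budget < 1L) stop("evaluation budget must be >= 1")
    ev <- makeEvaluator(objective, space, budget)
    iterCap <- if (is.null(params$maxEvaluations)) params$maxIterations
               else max(params$maxIterations, budget - hms)
    withLocalSeed(params$seed, {
        zs <- matrix(stats::runif(hms * d), hms, d)
        fit <- apply(zs, 1, ev$evalZ)
        keep <- !is.na(fit)
        zs <- zs[keep, , drop = FALSE]; fit <- fit[keep]
        history <- min(fit); meanHistory <- mean(fit)
        for (iter in seq_len(iterCap)) {
            if (ev$exhausted()) break
            z <- numeric(d)
            for (j in seq_len(d)) {
                if (stats::runif(1) < params$memoryConsideringRate) {
                    z[j] <- zs[sample.int(nrow(zs), 1L), j]
                    if (stats::runif(1) < params$pitchAdjustingRate) {
                        z[j] <- if (catMask[j]) stats::runif(1)
                                else z[j] + stats::runif(1, -1, 1) *
                                     params$bandwidth
                    }
                } else {
                    z[j] <- stats::runif(1)
                }
            }
            z <- reflectUnit(z)
            f <- ev$evalZ(z)
            if (!is.na(f)) {
                worst <- which.max(fit)
                if (f < fit[worst]) {
                    zs[worst, ] <- z
                    fit[worst] <- f
                }
            }
            history <- c(history, min(fit))
            meanHistory <- c(meanHistory, mean(fit))
        }
        finishResult(space, zs[which.min(fit), ], min(fit), history,
                     meanHistory, ev$used(), params$seed, "HS")
    })
}
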