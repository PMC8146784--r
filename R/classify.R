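#' k-nearest-neighbour classification
#'
#' Brute-force Euclidean KNN with explicit, deterministic tie rules:
#' distance ties are broken by the lower training-sample index, and an
#' even class split among the k neighbours is broken in favour of the
#' class with the smaller summed neighbour distance.
#'
#' @param trainX training feature matrix.
#' @param trainY training 0/1 labels.
#' @param queries query feature matrix (same columns).
#' @param k number of neighbours (default 5; odd values avoid most ties).
#' @return A list with \code{labels} (0/1 per query) and \code{scores}
#'   (fraction of defective neighbours, the coarse KNN score used for
#'   ROC curves).
#' @export
knnClassify <- function(trainX, trainY, queries, k = 5L) {
    trainX <- as.matrix(trainX)
    queries <- as.matrix(queries)
    trainY <- as.integer(trainY)
    k <- as.integer(k)
    n <- nrow(trainX)
    if (k < 1L || k > n) stop("k must be between 1 and the training size")
    if (ncol(queries) != ncol(trainX)) stop("feature dimension mismatch")
    labels <- integer(nrow(queries))
    scores <- numeric(nrow(queries))
    for (q in seq_len(nrow(queries))) {
        d2 <- rowSums(sweep(trainX, 2, queries[q, ])^2)
        nb <- order(d2, seq_len(n))[seq_len(k)]   # distance ties: lower index
        votes1 <- sum(trainY[nb] == 1L)
        scores[q] <- votes1 / k
        labels[q] <- if (votes1 * 2L > k) 1L
            else if (votes1 * 2L < k) 0L
            else {
                # even split: the class closer in summed distance wins
                s1 <- sum(sqrt(d2[nb][trainY[nb] == 1L]))
                s0 <- sum(sqrt(d2[nb][trainY[nb] == 0L]))
                as.integer(s1 <= s0)
            }
    }
    list(labels = labels, scores = scores)
}

# Wilks' lambda of a feature subset for a two-class problem:
# det(W)/det(T) over the subset, with W the pooled within-class SSCP and
# T the total SSCP.
wilksLambda <- function(W, T, subset) {
    if (!length(subset)) return(1)
    dw <- det(W[subset, subset, drop = FALSE])
    dt <- det(T[subset, subset, drop = FALSE])
    if (!is.finite(dw) || !is.finite(dt) || dt <= 0) return(NA_real_)
    max(dw / dt, 0)
}

#' Stepwise linear discriminant analysis
#'
#' Classic forward-with-removal stepwise feature selection on the partial
#' F statistic derived from Wilks' lambda, followed by a two-class linear
#' discriminant on the selected features (pooled covariance with a small
#' ridge on the diagonal, midpoint threshold, equal priors). A feature
#' enters when its entry p-value is below \code{entryAlpha} (most
#' significant first) and is removed when its removal p-value exceeds
#' \code{exitAlpha}. If no feature passes entry, the model falls back to a
#' majority-class predictor.
#'
#' @param X feature matrix.
#' @param y 0/1 labels (at least two samples per class).
#' @param entryAlpha significance level to enter (default 0.05).
#' @param exitAlpha significance level to stay (default 0.10); must be >=
#'   \code{entryAlpha}.
#' @param ridge ridge factor applied as \code{ridge * mean(diag(S))} to the
#'   pooled covariance diagonal.
#' @return A list of class \code{"stepwiseLDA"}: \code{selected} (ordered
#'   feature indices), \code{w}, \code{threshold}, \code{entryOrder},
#'   \code{fallbackMajority}, \code{majorityLabel}.
#' @export
ldaStepwiseFit <- function(X, y, entryAlpha = 0.05, exitAlpha = 0.10,
                           ridge = 1e-6) {
    X <- as.matrix(X)
    y <- as.integer(y)
    if (min(table(factor(y, levels = c(0, 1)))) < 2L) {
        stop("at least two samples per class are required")
    }
    if (entryAlpha > exitAlpha) {
        stop("entryAlpha must not exceed exitAlpha (entry stricter than exit)")
    }
    n <- nrow(X); p <- ncol(X); g <- 2L
    mAll <- colMeans(X)
    m0 <- colMeans(X[y == 0L, , drop = FALSE])
    m1 <- colMeans(X[y == 1L, , drop = FALSE])
    X0 <- sweep(X[y == 0L, , drop = FALSE], 2, m0)
    X1 <- sweep(X[y == 1L, , drop = FALSE], 2, m1)
    W <- crossprod(X0) + crossprod(X1)
    T <- crossprod(sweep(X, 2, mAll))

    selected <- integer(0)
    entryOrder <- integer(0)
    steps <- 0L
    repeat {
        steps <- steps + 1L
        if (steps > 2L * p + 10L) break   # anti-cycling cap
        changed <- FALSE
        # forward entry
        pSel <- length(selected)
        df2 <- n - g - pSel
        if (df2 >= 1L && pSel < p) {
            lamCur <- wilksLambda(W, T, selected)
            cand <- setdiff(seq_len(p), selected)
            Fs <- vapply(cand, function(j) {
                lamNew <- wilksLambda(W, T, c(selected, j))
                if (is.na(lamNew) || lamNew <= 0) return(NA_real_)
                df2 * (lamCur / lamNew - 1) / (g - 1)
            }, numeric(1))
            if (any(is.finite(Fs))) {
                jBest <- cand[which.max(Fs)]
                pEnter <- stats::pf(max(Fs, na.rm = TRUE), g - 1, df2,
                                    lower.tail = FALSE)
                if (pEnter < entryAlpha) {
                    selected <- c(selected, jBest)
                    entryOrder <- c(entryOrder, jBest)
                    changed <- TRUE
                }
            }
        }
        # backward removal
        if (length(selected) > 1L) {
            pSel <- length(selected)
            df2r <- n - g - (pSel - 1L)
            lamCur <- wilksLambda(W, T, selected)
            pVals <- vapply(selected, function(j) {
                lamRed <- wilksLambda(W, T, setdiff(selected, j))
                Fr <- df2r * (lamRed / lamCur - 1) / (g - 1)
                stats::pf(Fr, g - 1, df2r, lower.tail = FALSE)
            }, numeric(1))
            worst <- which.max(pVals)
            if (pVals[worst] > exitAlpha &&
                selected[worst] != utils::tail(entryOrder, 1L)) {
                selected <- selected[-worst]
                changed <- TRUE
            }
        }
        if (!changed) break
    }

    model <- list(selected = selected, entryOrder = entryOrder,
                  entryAlpha = entryAlpha, exitAlpha = exitAlpha,
                  fallbackMajority = FALSE,
                  majorityLabel = as.integer(sum(y == 1L) * 2L >= n))
    if (!length(selected)) {
        model$fallbackMajority <- TRUE
        model$w <- numeric(0)
        model$threshold <- 0
        class(model) <- "stepwiseLDA"
        return(model)
    }
    S <- W[selected, selected, drop = FALSE] / (n - g)
    S <- S + diag(ridge * mean(diag(S)), nrow(S))
    w <- tryCatch(solve(S, (m1 - m0)[selected]), error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) {
        stop("pooled covariance is singular even after ridge regularization")
    }
    model$w <- as.numeric(w)
    model$threshold <- sum(w * (m1 + m0)[selected]) / 2
    class(model) <- "stepwiseLDA"
    model
}

#' Predict with a stepwise LDA model
#'
#' @param model a \code{"stepwiseLDA"}.
#' @param X feature matrix containing (at least) the selected features at
#'   their original column positions.
#' @return A list with \code{scores} (signed discriminant score; 0 at the
#'   class midpoint) and \code{labels} (1 when score >= 0, the midpoint
#'   going to the defective class).
#' @export
ldaPredict <- function(model, X) {
    X <- as.matrix(X)
    if (model$fallbackMajority) {
        n <- nrow(X)
        return(list(scores = rep(ifelse(model$majorityLabel == 1L, 0, -1e-9), n),
                    labels = rep(model$majorityLabel, n)))
    }
    if (max(model$selected) > ncol(X)) {
        stop("feature matrix is missing selected feature columns")
    }
    scores <- as.numeric(X[, model$selected, drop = FALSE] %*% model$w) -
        model$threshold
    list(scores = scores, labels = as.integer(scores >= 0))
}

#' @export
print.stepwiseLDA <- function(x, ...) {
    if (x$fallbackMajority) {
        cat("<stepwiseLDA> empty selection; majority-class fallback\n")
    } else {
        cat("<stepwiseLDA> selected features:",
            paste(x$selected, collapse = ", "), "\n")
    }
    invisible(x)
}

#' Hyperparameter search space of the hybrid ANN classifiers
#'
#' The space both metaheuristics explore: 1-3 hidden layers, 1-25 neurons
#' per layer, a transfer function per layer, a training algorithm and a
#' learning rule from the catalogs. Exported so tests can assert that
#' ANN-ICA and ANN-HS search identical bounds.
#'
#' @return A \code{\link{searchSpace}} of 9 dimensions: layers, three
#'   widths, three transfer ids, training id, learning id.
#' @export
annSearchSpace <- function() {
    searchSpace(list(
        intDim(1L, 3L),
        intDim(1L, 25L), intDim(1L, 25L), intDim(1L, 25L),
        catDim(annTransferCatalog()), catDim(annTransferCatalog()),
        catDim(annTransferCatalog()),
        catDim(annTrainingCatalog()),
        catDim(annLearnCatalog())
    ))
}

decodeAnnPoint <- function(point) {
    nLayers <- point[[1]]
    neurons <- unlist(point[2:4])[seq_len(nLayers)]
    transfer <- unlist(point[5:7])[seq_len(nLayers)]
    annArchitecture(neurons, transfer, trainingFn = point[[8]],
                    learnFn = point[[9]])
}

#' Metaheuristic architecture search for the hybrid ANN classifiers
#'
#' Wraps the network engine in the imperialist competitive algorithm
#' (ANN-ICA) or harmony search (ANN-HS): candidate architecture vectors
#' are proposed by the optimizer, each is trained on the training split
#' and scored by its test-split MSE, and the lowest-MSE architecture is
#' returned, retrained, together with the search trace. The validation
#' split is used inside training for early stopping.
#'
#' @param xTrain,yTrain,xTest,yTest,xVal,yVal the three disjoint splits.
#' @param method \code{"ica"} or \code{"hs"}.
#' @param params an \code{\link{optimizerParams}} (its \code{seed} is
#'   overridden from \code{seed}).
#' @param seed master seed.
#' @param epochs per-candidate training epoch budget.
#' @return A list of class \code{"hybridANNResult"}: \code{method},
#'   \code{architecture}, \code{model} (retrained \code{"trainedANN"}),
#'   \code{fitness} (best test MSE seen), \code{trace}, \code{seed}.
#' @export
annMetaheuristicFit <- function(xTrain, yTrain, xTest, yTest,
                                xVal = NULL, yVal = NULL,
                                method = c("ica", "hs"),
                                params = optimizerParams(
                                    populationSize = 12L,
                                    maxIterations = 4L),
                                seed = 1L, epochs = 120L) {
    method <- match.arg(method)
    space <- annSearchSpace()
    counter <- 0L
    best <- new.env(parent = emptyenv())
    best$fitness <- Inf
    objective <- function(point) {
        counter <<- counter + 1L
        arch <- decodeAnnPoint(point)
        model <- trainANN(xTrain, yTrain, xTest, yTest, arch,
                          seed = deriveSeed(seed, 31L, counter),
                          epochs = epochs, xVal = xVal, yVal = yVal)
        if (model$testMSE < best$fitness) {
            best$fitness <- model$testMSE
            best$arch <- arch
            best$model <- model
        }
        model$testMSE
    }
    params$seed <- deriveSeed(seed, 17L)
    res <- if (method == "ica") icaOptimize(objective, space, params)
           else hsOptimize(objective, space, params)
    structure(list(
        method = toupper(method),
        architecture = best$arch,
        model = best$model,
        fitness = best$fitness,
        trace = res$history,
        evaluations = res$evaluations,
        seed = as.integer(seed)
    ), class = "hybridANNResult")
}

#' @export
print.hybridANNResult <- function(x, ...) {
    cat(sprintf("<hybridANNResult> ANN-%s: %s hidden, test MSE %.4g\n",
                x$method, paste(x$architecture@neurons, collapse = "x"),
                x$fitness))
    invisible(x)
}
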