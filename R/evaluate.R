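#' Construct a 2x2 pooled confusion matrix
#'
#' The package-wide axis convention is rows = predicted class, columns =
#' actual class, class order (healthy, defective). All reported metrics
#' derive from this orientation.
#'
#' @param predHealthyActHealthy,predHealthyActDefective counts in the
#'   predicted-healthy row.
#' @param predDefectiveActHealthy,predDefectiveActDefective counts in the
#'   predicted-defective row.
#' @return An integer matrix of class \code{"confusionMatrix2x2"}.
#' @examples
#' confusionMatrix2x2(6877, 337, 515, 6671)
#' @export
confusionMatrix2x2 <- function(predHealthyActHealthy,
                               predHealthyActDefective,
                               predDefectiveActHealthy,
                               predDefectiveActDefective) {
    counts <- c(predHealthyActHealthy, predHealthyActDefective,
                predDefectiveActHealthy, predDefectiveActDefective)
    if (any(counts < 0) || any(counts != round(counts))) {
        stop("confusion counts must be nonnegative integers")
    }
    m <- matrix(as.integer(round(counts)), 2, 2, byrow = TRUE,
                dimnames = list(predicted = c("healthy", "defective"),
                                actual = c("healthy", "defective")))
    class(m) <- c("confusionMatrix2x2", class(m))
    m
}

# accumulate predictions into a confusion matrix (rows predicted, cols actual)
tallyConfusion <- function(cm, predicted, actual) {
    for (i in seq_along(predicted)) {
        cm[predicted[i] + 1L, actual[i] + 1L] <-
            cm[predicted[i] + 1L, actual[i] + 1L] + 1L
    }
    cm
}

emptyConfusion <- function() confusionMatrix2x2(0, 0, 0, 0)

#' Per-class metrics from a pooled confusion matrix
#'
#' Under the rows-predicted/columns-actual convention: recall of a class
#' is its correct count over its actual (column) total; precision is the
#' correct count over the predicted (row) total; specificity of a class is
#' the recall of the other class; accuracy is the overall correct
#' classification rate (CCR = trace/total); F-score is the harmonic mean
#' of precision and recall. The per-row misclassified share is the
#' off-diagonal count over the row total. All percentages are returned at
#' full precision; \code{print} displays them to 1 decimal. Zero
#' denominators yield \code{NA}, not 0.
#'
#' @param cm a \code{\link{confusionMatrix2x2}} (or plain 2x2 matrix in
#'   the same orientation).
#' @return A list of class \code{"metricsReport"}: \code{ccr} (percent),
#'   \code{perClass} (data.frame: class, recall, accuracy, specificity,
#'   precision, fscore, all percent), \code{misclassified} (data.frame:
#'   predictedClass, count, pctOfRow), \code{total}.
#' @examples
#' computeMetrics(confusionMatrix2x2(6877, 337, 515, 6671))
#' @export
computeMetrics <- function(cm) {
    cm <- unclass(as.matrix(cm))
    stopifnot(all(dim(cm) == c(2L, 2L)))
    total <- sum(cm)
    if (total <= 0) stop("confusion matrix total must be positive")
    safeDiv <- function(a, b) if (b > 0) a / b else NA_real_
    ccr <- 100 * sum(diag(cm)) / total
    classes <- c("healthy", "defective")
    perClass <- do.call(rbind, lapply(1:2, function(cl) {
        oth <- 3L - cl
        recall <- 100 * safeDiv(cm[cl, cl], sum(cm[, cl]))
        precision <- 100 * safeDiv(cm[cl, cl], sum(cm[cl, ]))
        specificity <- 100 * safeDiv(cm[oth, oth], sum(cm[, oth]))
        fscore <- if (!is.na(precision) && !is.na(recall) &&
                      (precision + recall) > 0) {
            2 * precision * recall / (precision + recall)
        } else NA_real_
        data.frame(class = classes[cl], recall = recall, accuracy = ccr,
                   specificity = specificity, precision = precision,
                   fscore = fscore, stringsAsFactors = FALSE)
    }))
    misclassified <- data.frame(
        predictedClass = classes,
        count = c(cm[1, 2], cm[2, 1]),
        pctOfRow = c(100 * safeDiv(cm[1, 2], sum(cm[1, ])),
                     100 * safeDiv(cm[2, 1], sum(cm[2, ]))),
        stringsAsFactors = FALSE
    )
    structure(list(ccr = ccr, perClass = perClass,
                   misclassified = misclassified, total = total,
                   convention = "rows-predicted/columns-actual"),
              class = "metricsReport")
}

#' @export
print.metricsReport <- function(x, ...) {
    cat(sprintf("CCR: %.1f%% (n = %d)\n", x$ccr, x$total))
    pc <- x$perClass
    pc[2:6] <- lapply(pc[2:6], round, 1)
    print(pc, row.names = FALSE)
    mc <- x$misclassified
    mc$pctOfRow <- round(mc$pctOfRow, 1)
    print(mc, row.names = FALSE)
    invisible(x)
}

#' Majority vote of four classifier labels
#'
#' If at least three of the four members agree, their class wins. On a
#' 2-2 tie the vote of the member with the highest validation CCR in the
#' current iteration decides.
#'
#' @param labels integer vector of exactly 4 member labels (0/1).
#' @param validationCCR numeric vector of the members' validation CCRs,
#'   required only to resolve 2-2 ties.
#' @return The ensemble label (0 or 1).
#' @examples
#' majorityVote(c(0, 0, 0, 1))              # 0
#' majorityVote(c(0, 0, 1, 1), c(0.9, 0.8, 0.95, 0.7))  # 1
#' @export
majorityVote <- function(labels, validationCCR = NULL) {
    if (length(labels) != 4L || anyNA(labels)) {
        stop("exactly 4 member predictions are required")
    }
    labels <- as.integer(labels)
    ones <- sum(labels == 1L)
    if (ones >= 3L) return(1L)
    if (ones <= 1L) return(0L)
    if (is.null(validationCCR) || length(validationCCR) != 4L) {
        stop("a 2-2 tie requires the four members' validation CCRs")
    }
    labels[which.max(validationCCR)]
}

#' Classifier member constructors for the evaluation harness
#'
#' A member is a named list with \code{fit(x, y, xVal, yVal, seed)} and
#' \code{predict(model, x)} returning \code{list(scores, labels)} with
#' scores in [0, 1]. \code{memberANN} retrains a fixed architecture each
#' iteration (the architecture itself having been chosen once by
#' \code{\link{annMetaheuristicFit}}); \code{memberKNN} memorises the
#' training set; \code{memberLDA} runs the stepwise discriminant;
#' \code{memberConstant} always predicts one class (a test stub).
#'
#' @param name display name.
#' @param architecture an \linkS4class{ANNArchitecture}.
#' @param epochs,patience training controls for the ANN member.
#' @param k neighbours for the KNN member.
#' @param entryAlpha,exitAlpha stepwise significance levels.
#' @param label the constant member's fixed label.
#' @return A member list.
#' @export
memberANN <- function(name, architecture, epochs = 150L, patience = 20L) {
    list(
        name = name,
        fit = function(x, y, xVal, yVal, seed) {
            trainANN(x, y, architecture = architecture, seed = seed,
                     epochs = epochs, patience = patience,
                     xVal = xVal, yVal = yVal)
        },
        predict = function(model, x) predictANN(model, x)
    )
}

#' @rdname memberANN
#' @export
memberKNN <- function(k = 5L, name = "KNN") {
    list(
        name = name,
        fit = function(x, y, xVal, yVal, seed) list(x = x, y = y, k = k),
        predict = function(model, x) {
            knnClassify(model$x, model$y, x, k = model$k)
        }
    )
}

#' @rdname memberANN
#' @export
memberLDA <- function(entryAlpha = 0.05, exitAlpha = 0.10, name = "LDA") {
    list(
        name = name,
        fit = function(x, y, xVal, yVal, seed) {
            ldaStepwiseFit(x, y, entryAlpha, exitAlpha)
        },
        predict = function(model, x) {
            pr <- ldaPredict(model, x)
            list(scores = stats::plogis(pr$scores), labels = pr$labels)
        }
    )
}

#' @rdname memberANN
#' @export
memberConstant <- function(label = 0L, name = "CONST") {
    list(
        name = name,
        fit = function(x, y, xVal, yVal, seed) label,
        predict = function(model, x) {
            list(scores = rep(as.numeric(model), nrow(as.matrix(x))),
                 labels = rep(as.integer(model), nrow(as.matrix(x))))
        }
    )
}

#' Repeated stratified-split evaluation with majority voting
#'
#' The core evaluation harness: for each of \code{nIterations} iterations
#' the data are split 60/30/10 into train/test/validation (stratified by
#' class), every member is fitted on the training split, its validation
#' CCR is recorded, the test split is predicted, and a majority-vote
#' ensemble label is formed per test sample (2-2 ties resolved by the
#' best-validation member of that iteration). Test confusions are pooled
#' over iterations, so with 240 samples and 200 iterations the pooled
#' total is 200 x 72 = 14,400. ROC curves are computed from the pooled
#' test scores; the ensemble score is the validation-CCR-weighted mean of
#' the member scores.
#'
#' @param dataset a \linkS4class{SpectralSet}.
#' @param members list of member constructors' outputs (any length for
#'   per-member evaluation; exactly 4 to enable the MV ensemble).
#' @param nIterations number of repeated splits (200 in the reference
#'   design).
#' @param fractions train/test/validation fractions (default 0.6/0.3/0.1).
#' @param seed master seed; iteration i uses a split seed derived from
#'   (seed, i).
#' @return A list of class \code{"evaluationReport"}: \code{pooled}
#'   (named list of \code{\link{confusionMatrix2x2}}, one per member plus
#'   \code{"MV"}), \code{metrics} (per member, from
#'   \code{\link{computeMetrics}}), \code{iterationCCR} (matrix, percent),
#'   \code{roc} (per member: points and AUC), \code{nIterations},
#'   \code{testSize}, \code{seed}.
#' @export
runRepeatedEvaluation <- function(dataset, members, nIterations = 200L,
                                  fractions = c(0.6, 0.3, 0.1), seed = 1L) {
    x <- spectraMatrix(dataset)
    y <- classLabels(dataset)
    if (min(table(factor(y, levels = c(0, 1)))) < 10L) {
        stop("at least 10 samples per class are required")
    }
    nm <- length(members)
    useMV <- nm == 4L
    memberNames <- vapply(members, `[[`, character(1), "name")
    allNames <- if (useMV) c(memberNames, "MV") else memberNames
    pooled <- stats::setNames(replicate(length(allNames), emptyConfusion(),
                                        simplify = FALSE), allNames)
    iterCCR <- matrix(NA_real_, nIterations, length(allNames),
                      dimnames = list(NULL, allNames))
    scorePool <- stats::setNames(replicate(length(allNames), numeric(0),
                                           simplify = FALSE), allNames)
    actualPool <- integer(0)
    testSize <- NA_integer_

    for (it in seq_len(nIterations)) {
        sp <- stratifiedSplit(y, fractions, deriveSeed(seed, 1001L, it))
        xt <- x[sp$train, , drop = FALSE]; yt <- y[sp$train]
        xe <- x[sp$test, , drop = FALSE]; ye <- y[sp$test]
        xv <- x[sp$validation, , drop = FALSE]; yv <- y[sp$validation]
        testSize <- length(ye)
        labelsMat <- matrix(NA_integer_, length(ye), nm)
        scoresMat <- matrix(NA_real_, length(ye), nm)
        valCCR <- numeric(nm)
        for (m in seq_len(nm)) {
            fitSeed <- deriveSeed(seed, 2002L, it, m)
            model <- members[[m]]$fit(xt, yt, xv, yv, fitSeed)
            predVal <- members[[m]]$predict(model, xv)
            valCCR[m] <- mean(predVal$labels == yv)
            predTest <- members[[m]]$predict(model, xe)
            labelsMat[, m] <- predTest$labels
            scoresMat[, m] <- predTest$scores
            pooled[[m]] <- tallyConfusion(pooled[[m]], predTest$labels, ye)
            iterCCR[it, m] <- 100 * mean(predTest$labels == ye)
            scorePool[[m]] <- c(scorePool[[m]], predTest$scores)
        }
        if (useMV) {
            mvLabels <- vapply(seq_len(nrow(labelsMat)), function(i) {
                majorityVote(labelsMat[i, ], valCCR)
            }, integer(1))
            wts <- if (sum(valCCR) > 0) valCCR / sum(valCCR)
                   else rep(0.25, 4L)
            mvScores <- as.numeric(scoresMat %*% wts)
            pooled[["MV"]] <- tallyConfusion(pooled[["MV"]], mvLabels, ye)
            iterCCR[it, "MV"] <- 100 * mean(mvLabels == ye)
            scorePool[["MV"]] <- c(scorePool[["MV"]], mvScores)
        }
        actualPool <- c(actualPool, ye)
    }

    roc <- lapply(scorePool, function(s) {
        if (length(unique(actualPool)) < 2L) NULL
        else rocAuc(s, actualPool)
    })
    structure(list(
        pooled = pooled,
        metrics = lapply(pooled, computeMetrics),
        iterationCCR = iterCCR,
        roc = roc,
        nIterations = as.integer(nIterations),
        testSize = testSize,
        seed = as.integer(seed)
    ), class = "evaluationReport")
}

#' @export
print.evaluationReport <- function(x, ...) {
    cat(sprintf("<evaluationReport> %d iterations, pooled n = %d\n",
                x$nIterations, sum(x$pooled[[1]])))
    for (nm in names(x$metrics)) {
        cat(sprintf("  %-8s CCR %.1f%%  AUC %.3f\n", nm, x$metrics[[nm]]$ccr,
                    if (is.null(x$roc[[nm]])) NA else x$roc[[nm]]$auc))
    }
    invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the observed score range (positive
#' class = defective = 1, predicted positive when score >= threshold) and
#' integrates the curve by the trapezoid rule.
#'
#' @param scores real-valued classifier scores.
#' @param labels actual 0/1 labels; both classes must be present.
#' @return A list with \code{points} (data.frame: threshold, fpr, tpr) and
#'   \code{auc}.
#' @examples
#' rocAuc(c(0.1, 0.4, 0.8, 0.9), c(0, 0, 1, 1))$auc  # 1
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2L) {
        stop("both classes must be present to compute a ROC curve")
    }
    stopifnot(length(scores) == length(labels))
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    nPos <- sum(labels == 1L)
    nNeg <- sum(labels == 0L)
    tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / nPos,
                  numeric(1))
    fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nNeg,
                  numeric(1))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
         auc = auc)
}

#' Paired two-tailed t-test on matched CCR series
#'
#' Computes d = a - b, t = mean(d) / (sd(d)/sqrt(n)) with the sample
#' standard deviation (n - 1 denominator), df = n - 1, and the two-tailed
#' p-value from the t distribution. \code{pairedTTestSummary} computes the
#' same quantities from a reported mean difference, SD and n.
#'
#' @param a,b equal-length numeric vectors of paired values.
#' @return A list of class \code{"comparisonResult"}: \code{meanDiff},
#'   \code{sdDiff}, \code{t}, \code{df}, \code{p}, \code{n}.
#' @examples
#' pairedTTestSummary(-2.475, 0.332, 2)$t   # about -10.54
#' @export
pairedTTest <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (length(a) < 2L) stop("at least 2 pairs are required")
    d <- a - b
    sdd <- stats::sd(d)
    if (sdd == 0) stop("zero variance of the differences; t is undefined")
    pairedTTestSummary(mean(d), sdd, length(d))
}

#' @rdname pairedTTest
#' @param meanDiff,sdDiff,n mean, sample SD and count of the differences.
#' @export
pairedTTestSummary <- function(meanDiff, sdDiff, n) {
    if (n < 2L) stop("at least 2 pairs are required")
    if (sdDiff <= 0) stop("sdDiff must be positive")
    t <- meanDiff / (sdDiff / sqrt(n))
    df <- n - 1L
    structure(list(meanDiff = meanDiff, sdDiff = sdDiff, t = t, df = df,
                   p = 2 * stats::pt(-abs(t), df), n = n),
              class = "comparisonResult")
}

#' @export
print.comparisonResult <- function(x, ...) {
    cat(sprintf(
        "paired t-test: mean diff %.3f (SD %.3f, n = %d), t = %.2f, df = %d, p = %.3f\n",
        x$meanDiff, x$sdDiff, x$n, x$t, x$df, x$p))
    invisible(x)
}
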