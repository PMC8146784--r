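#' Catalogs of network building blocks
#'
#' The architecture search ranges over declared catalogs of 6 transfer
#' functions, 4 full-batch training algorithms and 3 learning-rate rules.
#' The catalogs are categorical dimensions of the hyperparameter search
#' space; their exact membership is a package design choice.
#'
#' @return Character vector of ids.
#' @export
annTransferCatalog <- function() {
    c("logistic", "tanh", "relu", "satlin", "linear", "softplus")
}

#' @rdname annTransferCatalog
#' @export
annTrainingCatalog <- function() c("gd", "gdm", "bfgs", "adam")

#' @rdname annTransferCatalog
#' @export
annLearnCatalog <- function() c("constant", "decay", "adaptive")

#' Create an ANN architecture description
#'
#' @param neurons integer vector of hidden-layer widths (1-3 layers, each
#'   1-25 neurons).
#' @param transfer hidden transfer function ids, one per layer (recycled if
#'   scalar); see \code{\link{annTransferCatalog}}.
#' @param trainingFn training algorithm id.
#' @param learnFn learning-rate rule id (used by the iterative trainers).
#' @param outputActivation \code{"sigmoid"} (default) or \code{"linear"}.
#' @return An \linkS4class{ANNArchitecture}.
#' @examples
#' annArchitecture(c(8, 4), c("tanh", "logistic"), "bfgs")
#' @export
annArchitecture <- function(neurons, transfer = "logistic",
                            trainingFn = "bfgs", learnFn = "constant",
                            outputActivation = "sigmoid") {
    if (length(transfer) == 1L) transfer <- rep(transfer, length(neurons))
    new("ANNArchitecture", neurons = as.integer(neurons),
        transfer = transfer, trainingFn = trainingFn, learnFn = learnFn,
        outputActivation = outputActivation)
}

setMethod("show", "ANNArchitecture", function(object) {
    cat(sprintf("ANNArchitecture: %s hidden (%s), train=%s, learn=%s, out=%s\n",
                paste(object@neurons, collapse = "x"),
                paste(object@transfer, collapse = ","),
                object@trainingFn, object@learnFn, object@outputActivation))
})

#' The fixed network used inside wavelength selection
#'
#' The wrapper wavelength search trains one fixed classifier network for
#' every candidate wavelength subset: two hidden layers of 12 and 16
#' neurons, rectified-linear then log-sigmoid hidden activations, a linear
#' output unit, trained by the quasi-Newton (BFGS) algorithm.
#'
#' @return An \linkS4class{ANNArchitecture}.
#' @export
fixedSelectionANN <- function() {
    annArchitecture(c(12L, 16L), c("relu", "logistic"),
                    trainingFn = "bfgs", learnFn = "constant",
                    outputActivation = "linear")
}

actFun <- function(id) {
    switch(id,
        logistic = function(z) 1 / (1 + exp(-z)),
        tanh = tanh,
        relu = function(z) pmax(z, 0),
        satlin = function(z) pmin(pmax(z, 0), 1),
        linear = identity,
        softplus = function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
        sigmoid = function(z) 1 / (1 + exp(-z)),
        stop("unknown activation: ", id))
}

# derivative expressed in terms of pre-activation z and activation a
actDeriv <- function(id) {
    switch(id,
        logistic = function(z, a) a * (1 - a),
        sigmoid = function(z, a) a * (1 - a),
        tanh = function(z, a) 1 - a^2,
        relu = function(z, a) as.numeric(z > 0),
        satlin = function(z, a) as.numeric(z > 0 & z < 1),
        linear = function(z, a) rep(1, length(z)),
        softplus = function(z, a) 1 / (1 + exp(-z)),
        stop("unknown activation: ", id))
}

annLayerSizes <- function(arch, nInputs) {
    c(nInputs, arch@neurons, 1L)
}

annParamCount <- function(sizes) {
    sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
}

packWeights <- function(weights) {
    unlist(lapply(weights, function(l) c(l$W, l$b)), use.names = FALSE)
}

unpackWeights <- function(theta, sizes) {
    nl <- length(sizes) - 1L
    out <- vector("list", nl)
    pos <- 0L
    for (l in seq_len(nl)) {
        nin <- sizes[l]; nout <- sizes[l + 1L]
        out[[l]] <- list(
            W = matrix(theta[pos + seq_len(nin * nout)], nin, nout),
            b = theta[pos + nin * nout + seq_len(nout)]
        )
        pos <- pos + nin * nout + nout
    }
    out
}

annActivationIds <- function(arch) {
    c(arch@transfer, arch@outputActivation)
}

annForward <- function(weights, acts, X, keepIntermediate = FALSE) {
    a <- X
    zs <- list(); as_ <- list(X)
    for (l in seq_along(weights)) {
        z <- sweep(a %*% weights[[l]]$W, 2, weights[[l]]$b, `+`)
        a <- actFun(acts[l])(z)
        if (keepIntermediate) {
            zs[[l]] <- z
            as_[[l + 1L]] <- a
        }
    }
    if (keepIntermediate) list(output = a[, 1L], z = zs, a = as_)
    else a[, 1L]
}

annLossGrad <- function(theta, sizes, acts, X, y) {
    weights <- unpackWeights(theta, sizes)
    fw <- annForward(weights, acts, X, keepIntermediate = TRUE)
    n <- length(y)
    yhat <- fw$output
    loss <- mean((yhat - y)^2)
    nl <- length(weights)
    delta <- matrix(2 * (yhat - y) / n, ncol = 1L) *
        actDeriv(acts[nl])(fw$z[[nl]], matrix(yhat, ncol = 1L))
    grads <- vector("list", nl)
    for (l in nl:1) {
        grads[[l]] <- list(W = crossprod(fw$a[[l]], delta),
                           b = colSums(delta))
        if (l > 1L) {
            # a[[l]] is the activation of layer l-1 (a[[1]] is the input)
            delta <- (delta %*% t(weights[[l]]$W)) *
                actDeriv(acts[l - 1L])(fw$z[[l - 1L]], fw$a[[l]])
        }
    }
    list(loss = loss, grad = packWeights(grads))
}

glorotInit <- function(sizes) {
    weights <- vector("list", length(sizes) - 1L)
    for (l in seq_along(weights)) {
        nin <- sizes[l]; nout <- sizes[l + 1L]
        lim <- sqrt(6 / (nin + nout))
        weights[[l]] <- list(
            W = matrix(stats::runif(nin * nout, -lim, lim), nin, nout),
            b = rep(0, nout)
        )
    }
    weights
}

#' Train a feed-forward classifier network
#'
#' Fits the weights of the given \linkS4class{ANNArchitecture} to minimize
#' the mean squared error between the network output and the 0/1 class
#' target, full batch. Features are standardized with training-set
#' statistics only (z-score); the same statistics are reused at
#' prediction time. Training is deterministic for a given seed.
#'
#' Trainers: \code{"gd"} is plain gradient descent with step-halving line
#' search (the training loss is non-increasing by construction),
#' \code{"gdm"} adds momentum 0.9, \code{"adam"} is the adaptive-moment
#' scheme, and \code{"bfgs"} delegates the quasi-Newton step to
#' \code{stats::optim} with the analytic backpropagation gradient. The
#' learning-rate rule (\code{learnFn}) applies to the iterative trainers:
#' \code{"constant"}, \code{"decay"} (1/(1 + 0.01 t)), or
#' \code{"adaptive"} (grow on success, shrink on failure).
#'
#' @param xTrain,yTrain training features (matrix) and 0/1 labels.
#' @param xTest,yTest optional test split; its MSE is recorded as the
#'   model's \code{testMSE} (the wrapper-search fitness).
#' @param architecture an \linkS4class{ANNArchitecture}.
#' @param seed RNG seed for the weight initialisation.
#' @param epochs epoch (or BFGS iteration) budget.
#' @param patience early-stopping patience on validation MSE (iterative
#'   trainers, only when a validation split is given).
#' @param xVal,yVal optional validation split for early stopping.
#' @param learningRate base step size for the iterative trainers.
#' @return A list of class \code{"trainedANN"}: architecture, weights,
#'   standardization statistics, seed, \code{trainMSE}, \code{testMSE},
#'   \code{lossHistory}.
#' @export
trainANN <- function(xTrain, yTrain, xTest = NULL, yTest = NULL,
                     architecture = annArchitecture(4L), seed = 1L,
                     epochs = 300L, patience = 30L,
                     xVal = NULL, yVal = NULL, learningRate = 0.05) {
    validObject(architecture)
    xTrain <- as.matrix(xTrain)
    yTrain <- as.numeric(yTrain)
    if (length(unique(yTrain)) < 2L) {
        stop("training set must contain both classes")
    }
    center <- colMeans(xTrain)
    scale <- apply(xTrain, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
    xs <- sweep(sweep(xTrain, 2, center), 2, scale, `/`)
    sizes <- annLayerSizes(architecture, ncol(xTrain))
    acts <- annActivationIds(architecture)
    theta0 <- withLocalSeed(seed, packWeights(glorotInit(sizes)))
    hasVal <- !is.null(xVal) && nrow(as.matrix(xVal)) > 0L
    if (hasVal) {
        xvs <- sweep(sweep(as.matrix(xVal), 2, center), 2, scale, `/`)
        yv <- as.numeric(yVal)
    }
    lossHistory <- numeric(0)

    if (architecture@trainingFn == "bfgs") {
        fn <- function(th) annLossGrad(th, sizes, acts, xs, yTrain)$loss
        gr <- function(th) annLossGrad(th, sizes, acts, xs, yTrain)$grad
        if (!hasVal) {
            opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                                control = list(maxit = epochs,
                                               reltol = 1e-10))
            theta <- opt$par
            lossHistory <- opt$value
        } else {
            # quasi-Newton in chunks with validation-based early stopping:
            # the unbounded linear-output nets overfit sharply, so the
            # weights kept are those of the best-validation chunk
            chunk <- 10L
            theta <- theta0
            bestValMSE <- Inf; bestTheta <- theta0; wait <- 0L
            done <- 0L
            while (done < epochs) {
                opt <- stats::optim(theta, fn, gr, method = "BFGS",
                                    control = list(
                                        maxit = min(chunk, epochs - done),
                                        reltol = 1e-10))
                theta <- opt$par
                done <- done + chunk
                lossHistory <- c(lossHistory, opt$value)
                w <- unpackWeights(theta, sizes)
                valMSE <- mean((annForward(w, acts, xvs) - yv)^2)
                if (valMSE < bestValMSE - 1e-12) {
                    bestValMSE <- valMSE; bestTheta <- theta; wait <- 0L
                } else {
                    wait <- wait + 1L
                    if (wait >= max(2L, patience %/% chunk)) break
                }
            }
            theta <- bestTheta
        }
    } else {
        theta <- theta0
        lr <- learningRate
        mu <- 0.9
        v <- numeric(length(theta))
        m1 <- numeric(length(theta)); m2 <- numeric(length(theta))
        beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
        cur <- annLossGrad(theta, sizes, acts, xs, yTrain)
        bestValMSE <- Inf; bestTheta <- theta; wait <- 0L
        for (t in seq_len(epochs)) {
            stepLr <- switch(architecture@learnFn,
                constant = lr,
                decay = lr / (1 + 0.01 * t),
                adaptive = lr)
            if (architecture@trainingFn == "gd") {
                # monotone: halve the step until the loss does not increase
                ok <- FALSE
                tryLr <- stepLr
                for (h in 1:25) {
                    cand <- theta - tryLr * cur$grad
                    candLoss <- annLossGrad(cand, sizes, acts, xs,
                                            yTrain)$loss
                    if (candLoss <= cur$loss) { ok <- TRUE; break }
                    tryLr <- tryLr / 2
                }
                if (ok) {
                    theta <- cand
                    if (architecture@learnFn == "adaptive") {
                        lr <- if (tryLr >= stepLr) lr * 1.05 else tryLr
                    }
                } # else: no descent step found; keep theta
            } else if (architecture@trainingFn == "gdm") {
                v <- mu * v - stepLr * cur$grad
                theta <- theta + v
            } else { # adam
                m1 <- beta1 * m1 + (1 - beta1) * cur$grad
                m2 <- beta2 * m2 + (1 - beta2) * cur$grad^2
                mh <- m1 / (1 - beta1^t)
                vh <- m2 / (1 - beta2^t)
                theta <- theta - stepLr * mh / (sqrt(vh) + epsAdam)
            }
            cur <- annLossGrad(theta, sizes, acts, xs, yTrain)
            lossHistory <- c(lossHistory, cur$loss)
            if (hasVal) {
                w <- unpackWeights(theta, sizes)
                valMSE <- mean((annForward(w, acts, xvs) - yv)^2)
                if (valMSE < bestValMSE - 1e-12) {
                    bestValMSE <- valMSE; bestTheta <- theta; wait <- 0L
                } else {
                    wait <- wait + 1L
                    if (wait >= patience) break
                }
            }
        }
        if (hasVal && is.finite(bestValMSE)) theta <- bestTheta
    }

    weights <- unpackWeights(theta, sizes)
    trainMSE <- mean((annForward(weights, acts, xs) - yTrain)^2)
    model <- structure(list(
        architecture = architecture, weights = weights,
        center = center, scale = scale, seed = as.integer(seed),
        trainMSE = trainMSE, testMSE = NA_real_, lossHistory = lossHistory
    ), class = "trainedANN")
    if (!is.null(xTest) && nrow(as.matrix(xTest)) > 0L) {
        model$testMSE <- mean((predictANN(model, xTest)$scores -
                               as.numeric(yTest))^2)
    }
    model
}

#' Predict with a trained network
#'
#' @param model a \code{"trainedANN"}.
#' @param x feature matrix with the same columns as at training time.
#' @return A list with \code{scores} (network outputs; in [0, 1] for
#'   sigmoid-output networks) and \code{labels} (1 when score >= 0.5, the
#'   tie going to the defective class).
#' @export
predictANN <- function(model, x) {
    x <- as.matrix(x)
    if (ncol(x) != length(model$center)) {
        stop("feature count does not match the training data")
    }
    xs <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
    scores <- annForward(model$weights, annActivationIds(model$architecture),
                         xs)
    list(scores = scores, labels = as.integer(scores >= 0.5))
}

#' @export
print.trainedANN <- function(x, ...) {
    cat(sprintf("<trainedANN> %s; train MSE %.4g; test MSE %.4g\n",
                paste(x$architecture@neurons, collapse = "x"),
                x$trainMSE, x$testMSE))
    invisible(x)
}

#' Serialize a trained network to JSON
#'
#' Writes a portable JSON document holding the architecture and the
#' flattened weights; \code{annFromJSON} restores an equivalent model.
#'
#' @param model a \code{"trainedANN"}.
#' @param path JSON file path.
#' @export
annToJSON <- function(model, path) {
    arch <- model$architecture
    doc <- list(
        neurons = arch@neurons, transfer = arch@transfer,
        trainingFn = arch@trainingFn, learnFn = arch@learnFn,
        outputActivation = arch@outputActivation,
        center = model$center, scale = model$scale, seed = model$seed,
        trainMSE = model$trainMSE, testMSE = model$testMSE,
        theta = packWeights(model$weights)
    )
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname annToJSON
#' @export
annFromJSON <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    arch <- annArchitecture(doc$neurons, doc$transfer, doc$trainingFn,
                            doc$learnFn, doc$outputActivation)
    sizes <- annLayerSizes(arch, length(doc$center))
    structure(list(
        architecture = arch,
        weights = unpackWeights(doc$theta, sizes),
        center = doc$center, scale = doc$scale,
        seed = as.integer(doc$seed),
        trainMSE = doc$trainMSE, testMSE = doc$testMSE,
        lossHistory = numeric(0)
    ), class = "trainedANN")
}
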