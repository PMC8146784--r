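test_that("architecture invariants are enforced", {
    expect_s4_class(annArchitecture(c(12, 16), c("relu", "logistic")),
                    "ANNArchitecture")
    expect_error(annArchitecture(integer(0)), "hidden layers")
    expect_error(annArchitecture(c(2, 2, 2, 2)), "hidden layers")
    expect_error(annArchitecture(26L), "neurons")
    expect_error(annArchitecture(4L, "wiggle"), "transfer")
    expect_error(annArchitecture(4L, trainingFn = "sgd9000"), "training")
})

test_that("the fixed wavelength-selection network matches its reference design", {
    arch <- fixedSelectionANN()
    expect_equal(arch@neurons, c(12L, 16L))
    expect_equal(length(arch@neurons), 2L)
    expect_equal(arch@transfer, c("relu", "logistic"))
    expect_equal(arch@trainingFn, "bfgs")
    expect_equal(arch@outputActivation, "linear")
    expect_true(validObject(arch))
})

# independent layer-by-layer forward oracle using explicit loops
forwardOracle <- function(model, x) {
    acts <- c(model$architecture@transfer,
              model$architecture@outputActivation)
    fns <- list(logistic = function(z) 1 / (1 + exp(-z)),
                sigmoid = function(z) 1 / (1 + exp(-z)),
                tanh = tanh, relu = function(z) pmax(z, 0),
                satlin = function(z) pmin(pmax(z, 0), 1),
                linear = identity,
                softplus = function(z) log1p(exp(z)))
    out <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
        a <- (x[i, ] - model$center) / model$scale
        for (l in seq_along(model$weights)) {
            z <- as.numeric(a %*% model$weights[[l]]$W) + model$weights[[l]]$b
            a <- fns[[acts[l]]](z)
        }
        out[i] <- a
    }
    out
}

test_that("forward pass agrees with a loop-based oracle", {
    bd <- blobData(40)
    m <- trainANN(bd$x, bd$y, architecture = annArchitecture(
        c(5, 3), c("tanh", "softplus"), "adam"), seed = 4, epochs = 5)
    withr::with_seed(7, {
        xq <- matrix(rnorm(20), ncol = 2)
        expect_equal(predictANN(m, xq)$scores, forwardOracle(m, xq),
                     tolerance = 1e-10)
    })
})

test_that("a zero-weight sigmoid network outputs 0.5 and ties go defective", {
    bd <- blobData(20)
    m <- trainANN(bd$x, bd$y, architecture = annArchitecture(3L),
                  seed = 1, epochs = 1)
    for (l in seq_along(m$weights)) {
        m$weights[[l]]$W[] <- 0
        m$weights[[l]]$b[] <- 0
    }
    pr <- predictANN(m, bd$x[1:4, ])
    expect_equal(pr$scores, rep(0.5, 4))
    expect_equal(pr$labels, rep(1L, 4))   # score 0.5 -> defective
})

test_that("analytic gradients match finite differences", {
    withr::with_seed(12, {
        x <- matrix(rnorm(18), 6, 3)
        y <- rep(c(0, 1), 3)
        arch <- annArchitecture(c(4, 2), c("tanh", "logistic"))
        sizes <- SpectraVote:::annLayerSizes(arch, 3)
        acts <- SpectraVote:::annActivationIds(arch)
        theta <- rnorm(SpectraVote:::annParamCount(sizes), sd = 0.5)
        got <- SpectraVote:::annLossGrad(theta, sizes, acts, x, y)$grad
        eps <- 1e-6
        num <- vapply(seq_along(theta), function(j) {
            tp <- theta; tp[j] <- tp[j] + eps
            tm <- theta; tm[j] <- tm[j] - eps
            (SpectraVote:::annLossGrad(tp, sizes, acts, x, y)$loss -
             SpectraVote:::annLossGrad(tm, sizes, acts, x, y)$loss) / (2 * eps)
        }, numeric(1))
        expect_equal(got, num, tolerance = 1e-5)
    })
})

test_that("a separable problem is classified perfectly and reproducibly", {
    bd <- blobData(100, gap = 6)
    m1 <- trainANN(bd$x, bd$y, bd$x, bd$y,
                   annArchitecture(4L, "tanh", "bfgs"), seed = 1,
                   epochs = 150)
    expect_equal(mean(predictANN(m1, bd$x)$labels == bd$y), 1)
    m2 <- trainANN(bd$x, bd$y, bd$x, bd$y,
                   annArchitecture(4L, "tanh", "bfgs"), seed = 1,
                   epochs = 150)
    expect_identical(predictANN(m1, bd$x)$scores,
                     predictANN(m2, bd$x)$scores)
    expect_error(predictANN(m1, matrix(0, 2, 5)), "feature count")
})

test_that("standardization statistics come from the training data only", {
    bd <- blobData(60)
    m <- trainANN(bd$x, bd$y, architecture = annArchitecture(3L),
                  seed = 2, epochs = 3,
                  xVal = bd$x[1:5, ] + 100, yVal = bd$y[1:5])
    expect_equal(m$center, colMeans(bd$x), ignore_attr = TRUE)
    expect_equal(m$scale, apply(bd$x, 2, sd), ignore_attr = TRUE)
})

test_that("plain gradient descent with step halving is monotone in loss", {
    bd <- blobData(60, gap = 3)
    m <- trainANN(bd$x, bd$y, architecture = annArchitecture(
        4L, "logistic", "gd"), seed = 3, epochs = 60)
    expect_true(all(diff(m$lossHistory) <= 1e-12))
})

test_that("the XOR function is learned from most initialisations", {
    withr::with_seed(77, {
        x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
        x <- x[rep(1:4, 25), ] + matrix(rnorm(200, 0, 0.05), ncol = 2)
        y <- rep(c(0, 1, 1, 0), 25)
    })
    ok <- sum(vapply(1:20, function(s) {
        trainANN(x, y, architecture = annArchitecture(4L, "tanh", "bfgs"),
                 seed = s, epochs = 400)$trainMSE < 0.1
    }, logical(1)))
    expect_gte(ok, 16)
})

test_that("training rejects single-class input", {
    expect_error(trainANN(matrix(rnorm(10), 5), rep(1, 5)),
                 "both classes")
})

test_that("JSON serialization round-trips a trained model", {
    bd <- blobData(30)
    m <- trainANN(bd$x, bd$y, architecture = annArchitecture(
        c(3, 2), c("relu", "tanh"), "adam", "decay"), seed = 6, epochs = 10)
    path <- withr::local_tempfile(fileext = ".json")
    annToJSON(m, path)
    m2 <- annFromJSON(path)
    expect_equal(predictANN(m2, bd$x)$scores, predictANN(m, bd$x)$scores,
                 tolerance = 1e-12)
    expect_equal(m2$architecture@transfer, c("relu", "tanh"))
})
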