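test_that("KNN label rules match the worked examples", {
    train <- matrix(c(0, 0, 0, 1, 5, 5, 5, 6, 5, 4), ncol = 2, byrow = TRUE)
    y <- c(0L, 0L, 1L, 1L, 1L)
    # query equal to a training point, k = 1
    expect_equal(knnClassify(train, y, train[3, , drop = FALSE], 1)$labels, 1L)
    # brute-force enumerable case
    expect_equal(knnClassify(train, y, matrix(c(4, 4), 1), 3)$labels, 1L)
    # k = n gives the global majority regardless of the query
    expect_equal(knnClassify(train, y, matrix(c(-50, 80), 1), 5)$labels, 1L)
    expect_error(knnClassify(train, y, matrix(0, 1, 2), 6), "k must be")
    expect_error(knnClassify(train, y, matrix(0, 1, 3)), "dimension")
})

test_that("KNN agrees exactly with an exhaustive brute-force oracle", {
    bruteKNN <- function(trX, trY, q, k) {
        d <- sqrt(colSums((t(trX) - q)^2))
        nb <- order(d, seq_along(d))[1:k]
        v1 <- sum(trY[nb] == 1)
        if (2 * v1 > k) return(1L)
        if (2 * v1 < k) return(0L)
        as.integer(sum(d[nb][trY[nb] == 1]) <= sum(d[nb][trY[nb] == 0]))
    }
    withr::with_seed(21, {
        for (i in 1:200) {
            n <- sample(5:30, 1); d <- sample(1:5, 1)
            trX <- matrix(round(rnorm(n * d), 1), n)
            trY <- sample(0:1, n, replace = TRUE)
            k <- sample(1:min(7, n), 1)
            q <- matrix(round(rnorm(d), 1), 1)
            expect_identical(knnClassify(trX, trY, q, k)$labels,
                             bruteKNN(trX, trY, q[1, ], k))
        }
    })
})

test_that("stepwise LDA separates well-separated 1-D Gaussians", {
    withr::with_seed(31, {
        x <- matrix(c(rnorm(100, -10), rnorm(100, 10)), ncol = 1)
        y <- rep(0:1, each = 100)
        m <- ldaStepwiseFit(x, y)
        pr <- ldaPredict(m, x)
        expect_gte(mean(pr$labels == y), 0.99)
    })
})

test_that("the single informative feature enters first, matching a partial-F oracle", {
    withr::with_seed(32, {
        n <- 80
        x <- matrix(rnorm(n * 5), n)
        y <- rep(0:1, each = n / 2)
        x[, 3] <- x[, 3] + 5 * y     # only feature 3 separates the classes
        m <- ldaStepwiseFit(x, y)
        expect_equal(m$entryOrder[1], 3L)
        # oracle: first-step partial F computed directly per feature
        Fs <- vapply(1:5, function(j) {
            w <- sum((x[y == 0, j] - mean(x[y == 0, j]))^2) +
                 sum((x[y == 1, j] - mean(x[y == 1, j]))^2)
            t <- sum((x[, j] - mean(x[, j]))^2)
            lam <- w / t
            (n - 2) * (1 / lam - 1)
        }, numeric(1))
        expect_equal(which.max(Fs), 3L)
    })
})

test_that("stepwise boundary behaviour: alpha 1 keeps all, alpha 0 keeps none", {
    withr::with_seed(33, {
        x <- matrix(rnorm(200), 50)
        y <- rep(0:1, 25)
        all <- ldaStepwiseFit(x, y, entryAlpha = 1, exitAlpha = 1)
        expect_setequal(all$selected, 1:4)
        none <- ldaStepwiseFit(x, y, entryAlpha = 0, exitAlpha = 0)
        expect_length(none$selected, 0)
        expect_true(none$fallbackMajority)
        pr <- ldaPredict(none, x)
        expect_equal(pr$labels, rep(none$majorityLabel, 50))
        expect_error(ldaStepwiseFit(x, y, entryAlpha = 0.2, exitAlpha = 0.1),
                     "entryAlpha")
    })
})

test_that("LDA predictions follow the signed discriminant with midpoint tie to defective", {
    withr::with_seed(34, {
        x <- rbind(matrix(rnorm(40, 0, 0.5), ncol = 2),
                   matrix(rnorm(40, 3, 0.5), ncol = 2))
        y <- rep(0:1, each = 20)
        m <- ldaStepwiseFit(x, y, entryAlpha = 1, exitAlpha = 1)
        # hand-computed scores: w.x - threshold on the selected features
        manual <- as.numeric(x[, m$selected, drop = FALSE] %*% m$w) -
            m$threshold
        pr <- ldaPredict(m, x)
        expect_equal(pr$scores, manual)
        expect_equal(pr$labels, as.integer(manual >= 0))
        # duplicated query rows give identical labels
        dup <- ldaPredict(m, x[c(1, 1, 5, 5), ])
        expect_equal(dup$labels[1], dup$labels[2])
        # direction agrees with the reference LDA implementation
        ref <- MASS::lda(x, grouping = y)
        cosine <- sum(m$w * ref$scaling) /
            sqrt(sum(m$w^2) * sum(ref$scaling^2))
        expect_gt(abs(cosine), 0.99)
    })
})

test_that("ANN-ICA and ANN-HS search the same architecture space", {
    sp <- annSearchSpace()
    expect_identical(sp$dims[[1]], intDim(1, 3))
    for (j in 2:4) expect_identical(sp$dims[[j]], intDim(1, 25))
    for (j in 5:7) expect_identical(sp$dims[[j]],
                                    catDim(annTransferCatalog()))
    expect_identical(sp$dims[[8]], catDim(annTrainingCatalog()))
    expect_identical(sp$dims[[9]], catDim(annLearnCatalog()))
})

test_that("architecture search returns in-bounds architectures, deterministically", {
    bd <- blobData(80, gap = 6)
    sp <- SpectraVote:::stratifiedSplit(bd$y, c(0.6, 0.3, 0.1), 5)
    fit <- function(method, seed) {
        annMetaheuristicFit(bd$x[sp$train, ], bd$y[sp$train],
                            bd$x[sp$test, ], bd$y[sp$test],
                            bd$x[sp$validation, ], bd$y[sp$validation],
                            method = method,
                            params = optimizerParams(populationSize = 8,
                                                     maxIterations = 2,
                                                     nImperialists = 2,
                                                     harmonyMemorySize = 6,
                                                     maxEvaluations = 14),
                            seed = seed, epochs = 30)
    }
    for (method in c("ica", "hs")) {
        r <- fit(method, 9)
        arch <- r$architecture
        expect_true(length(arch@neurons) %in% 1:3)
        expect_true(all(arch@neurons >= 1 & arch@neurons <= 25))
        expect_true(all(arch@transfer %in% annTransferCatalog()))
        r2 <- fit(method, 9)
        expect_identical(r2$architecture@neurons, r$architecture@neurons)
        expect_identical(r2$trace, r$trace)
        # the best-MSE architecture's model is returned
        expect_equal(r$model$testMSE, r$fitness)
    }
})
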