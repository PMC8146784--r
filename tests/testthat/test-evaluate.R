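test_that("majority vote follows the three-agree rule on all 16 label combinations", {
    combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1, d = 0:1)
    ccr <- c(0.6, 0.7, 0.8, 0.9)   # member d is the best validated
    for (i in seq_len(nrow(combos))) {
        labels <- as.integer(combos[i, ])
        got <- majorityVote(labels, ccr)
        ones <- sum(labels)
        want <- if (ones >= 3) 1L else if (ones <= 1) 0L else labels[4]
        expect_identical(got, want)
    }
    # declared tie rule: best-validation member decides
    expect_equal(majorityVote(c(0, 0, 1, 1), c(0.9, 0.8, 0.95, 0.7)), 1L)
    expect_equal(majorityVote(c(1, 1, 1, 0)), 1L)
    expect_equal(majorityVote(c(1, 1, 1, 1)), 1L)
    expect_error(majorityVote(c(0, 1, 1)), "exactly 4")
    expect_error(majorityVote(c(0, 0, 1, NA)), "exactly 4")
    expect_error(majorityVote(c(0, 0, 1, 1)), "validation")
})

test_that("confusion matrices validate their counts", {
    cm <- confusionMatrix2x2(50, 0, 0, 50)
    expect_equal(sum(cm), 100)
    expect_error(confusionMatrix2x2(-1, 0, 0, 5), "nonnegative")
    expect_error(confusionMatrix2x2(1.5, 0, 0, 5), "nonnegative")
})

test_that("metrics handle perfect, degenerate and random matrices", {
    perfect <- computeMetrics(confusionMatrix2x2(50, 0, 0, 50))
    expect_equal(perfect$ccr, 100)
    expect_true(all(unlist(perfect$perClass[, 2:6]) == 100))
    expect_equal(perfect$misclassified$pctOfRow, c(0, 0))

    # a zero denominator yields NA, never 0: nothing predicted defective
    allHealthy <- computeMetrics(confusionMatrix2x2(5, 3, 0, 0))
    expect_true(is.na(allHealthy$perClass$precision[2]))
    expect_equal(allHealthy$perClass$recall[2], 0)   # 0 of 3 actual found
    # nothing actually defective: recall of that class is undefined
    noDefective <- computeMetrics(confusionMatrix2x2(5, 0, 2, 0))
    expect_true(is.na(noDefective$perClass$recall[2]))

    withr::with_seed(41, {
        for (i in 1:20) {
            cm <- confusionMatrix2x2(sample(1:99, 1), sample(1:99, 1),
                                     sample(1:99, 1), sample(1:99, 1))
            m <- computeMetrics(cm)
            # specificity of one class equals recall of the other
            expect_equal(m$perClass$specificity[1], m$perClass$recall[2])
            expect_equal(m$perClass$specificity[2], m$perClass$recall[1])
            # CCR does not depend on the axis convention
            expect_equal(m$ccr, computeMetrics(t(unclass(cm)))$ccr)
            expect_equal(m$ccr, 100 * sum(diag(cm)) / sum(cm))
        }
    })
})

test_that("repeated evaluation pools the expected totals and CCRs", {
    cfg <- generatorConfig(nHealthy = 20, nDefective = 20,
                           gridStart = 400, gridEnd = 420, gridStep = 10,
                           plantedBands = data.frame(center = 410,
                                                     delta = 0.2,
                                                     width = 10),
                           scatterSd = 0, baselineCoeffSd = 0,
                           noiseSd = 0.005, seed = 3)
    ds <- generateDataset(cfg)

    # a perfect classifier stub: matched-filter threshold on the band
    perfectMember <- list(
        name = "ORACLE",
        fit = function(x, y, xv, yv, seed) {
            list(cut = mean(c(mean(x[y == 0, 2]), mean(x[y == 1, 2]))))
        },
        predict = function(model, x) {
            lab <- as.integer(x[, 2] < model$cut)
            list(scores = as.numeric(lab), labels = lab)
        }
    )
    rep1 <- runRepeatedEvaluation(ds, list(perfectMember), nIterations = 1,
                                  seed = 5)
    expect_equal(sum(rep1$pooled$ORACLE), 12)  # 30% of 40
    expect_equal(rep1$pooled$ORACLE[1, 2] + rep1$pooled$ORACLE[2, 1], 0)

    # constant member on balanced, stratified test data: CCR exactly 50%
    repC <- runRepeatedEvaluation(ds, list(memberConstant(0L)),
                                  nIterations = 4, seed = 6)
    expect_equal(sum(repC$pooled$CONST), 4 * 12)
    expect_equal(repC$metrics$CONST$ccr, 50)
    expect_true(all(repC$iterationCCR[, "CONST"] == 50))
})

test_that("an ensemble of four identical members equals the member", {
    cfg <- generatorConfig(nHealthy = 15, nDefective = 15,
                           gridStart = 400, gridEnd = 440, gridStep = 10,
                           plantedBands = data.frame(center = 420,
                                                     delta = 0.05,
                                                     width = 10),
                           seed = 8)
    ds <- generateDataset(cfg)
    members <- replicate(4, memberKNN(3), simplify = FALSE)
    for (i in 1:4) members[[i]]$name <- paste0("KNN", i)
    rep4 <- runRepeatedEvaluation(ds, members, nIterations = 3, seed = 2)
    expect_identical(unclass(rep4$pooled$MV), unclass(rep4$pooled$KNN1))
    expect_identical(rep4$iterationCCR[, "MV"], rep4$iterationCCR[, "KNN1"],
                     ignore_attr = TRUE)
})

test_that("evaluation rejects undersized datasets", {
    tiny <- toySpectralSet(n = 6)
    expect_error(runRepeatedEvaluation(tiny, list(memberConstant(0L)),
                                       nIterations = 1),
                 "10 samples")
})

test_that("ROC sweep and trapezoid AUC behave at the extremes", {
    expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
    expect_equal(rocAuc(-c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 0)
    expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
    withr::with_seed(51, {
        scores <- runif(10000)
        labels <- sample(0:1, 10000, replace = TRUE)
        auc <- rocAuc(scores, labels)$auc
        expect_gt(auc, 0.48)
        expect_lt(auc, 0.52)
        # agreement with the reference implementation on a small case
        s <- rnorm(60); l <- rep(0:1, 30)
        ref <- suppressMessages(as.numeric(pROC::auc(l, s,
                                                     direction = "<")))
        expect_equal(rocAuc(s, l)$auc, ref, tolerance = 1e-10)
    })
})

test_that("ROC points trace a monotone staircase from (0,0) to (1,1)", {
    withr::with_seed(52, {
        pts <- rocAuc(rnorm(40), rep(0:1, 20))$points
        expect_equal(pts$fpr[1], 0)
        expect_equal(pts$tpr[1], 0)
        expect_equal(pts$fpr[nrow(pts)], 1)
        expect_equal(pts$tpr[nrow(pts)], 1)
        expect_true(all(diff(pts$fpr) >= 0))
        expect_true(all(diff(pts$tpr) >= 0))
    })
})

test_that("the paired t-test matches the reference implementation", {
    withr::with_seed(61, {
        for (i in 1:10) {
            n <- sample(3:12, 1)
            a <- rnorm(n, 90, 5); b <- rnorm(n, 88, 5)
            got <- pairedTTest(a, b)
            ref <- t.test(a, b, paired = TRUE)
            expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
            expect_equal(got$df, unname(ref$parameter))
            expect_equal(got$p, ref$p.value, tolerance = 1e-12)
        }
    })
    expect_error(pairedTTest(c(1, 2, 3), c(0, 1, 2)), "zero variance")
    expect_error(pairedTTest(1, 2), "2 pairs")
})
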