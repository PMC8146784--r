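optimizers <- list(CA = caOptimize, ICA = icaOptimize, HS = hsOptimize)

test_that("a constant objective returns its constant as best fitness", {
    sp <- searchSpace(realDim(0, 1), realDim(0, 1))
    for (opt in optimizers) {
        res <- opt(function(p) 7, sp,
                   optimizerParams(populationSize = 10, maxIterations = 5,
                                   nImperialists = 3, harmonyMemorySize = 5,
                                   seed = 1))
        expect_equal(res$best$fitness, 7)
    }
})

test_that("decoded points respect bounds, integrality and level sets", {
    sp <- searchSpace(realDim(-2, 3), intDim(4, 9),
                      catDim(c("a", "b", "c")))
    withr::with_seed(10, {
        for (i in 1:200) {
            pt <- SpectraVote:::decodePoint(sp, runif(3))
            expect_true(pt[[1]] >= -2 && pt[[1]] <= 3)
            expect_true(pt[[2]] %in% 4:9)
            expect_true(pt[[3]] %in% c("a", "b", "c"))
        }
        # extremes decode to the inclusive bounds
        expect_equal(SpectraVote:::decodePoint(sp, c(0, 0, 0))[[2]], 4)
        expect_equal(SpectraVote:::decodePoint(sp, c(1, 1, 1))[[2]], 9)
    })
})

test_that("identical seeds reproduce identical traces", {
    sp <- searchSpace(realDim(-5, 5), realDim(-5, 5))
    f <- function(p) sum(unlist(p)^2)
    for (opt in optimizers) {
        p <- optimizerParams(populationSize = 12, maxIterations = 15,
                             nImperialists = 3, harmonyMemorySize = 8,
                             seed = 99)
        r1 <- opt(f, sp, p)
        r2 <- opt(f, sp, p)
        expect_identical(r1$history, r2$history)
        expect_identical(r1$best$fitness, r2$best$fitness)
    }
})

test_that("objective evaluations never exceed the declared budget", {
    sp <- searchSpace(realDim(0, 1), realDim(0, 1), realDim(0, 1))
    for (opt in optimizers) {
        count <- 0
        f <- function(p) { count <<- count + 1; sum(unlist(p)^2) }
        res <- opt(f, sp, optimizerParams(populationSize = 10,
                                          maxIterations = 50,
                                          maxEvaluations = 83,
                                          nImperialists = 3,
                                          harmonyMemorySize = 6, seed = 2))
        expect_lte(count, 83)
        expect_equal(res$evaluations, count)
    }
})

test_that("best-so-far traces are monotone non-increasing", {
    sp <- searchSpace(realDim(-5, 5), realDim(-5, 5), realDim(-5, 5))
    f <- function(p) sum(unlist(p)^2)
    for (opt in optimizers) {
        for (s in 1:3) {
            res <- opt(f, sp, optimizerParams(populationSize = 15,
                                              maxIterations = 20,
                                              nImperialists = 4,
                                              harmonyMemorySize = 10,
                                              seed = s))
            expect_true(all(diff(res$history) <= 1e-12))
        }
    }
})

test_that("each optimizer solves a small exhaustively-checked problem", {
    prob <- discreteTripleProblem()
    for (opt in optimizers) {
        res <- opt(prob$objective, prob$space,
                   optimizerParams(populationSize = 20, maxIterations = 20,
                                   nImperialists = 4, harmonyMemorySize = 12,
                                   maxEvaluations = 400, seed = 5))
        expect_equal(res$best$fitness, prob$optimum)
    }
})

test_that("invalid optimizer setups are rejected", {
    sp <- searchSpace(realDim(0, 1))
    f <- function(p) 0
    expect_error(searchSpace(), "at least one dimension")
    expect_error(icaOptimize(f, sp, optimizerParams(populationSize = 5,
                                                    nImperialists = 5)),
                 "nImperialists")
    expect_error(hsOptimize(f, sp, optimizerParams(harmonyMemorySize = 1)),
                 "harmony memory")
    expect_error(optimizerParams(revolutionRate = 1.2), "rates")
})

test_that("optimizer traces serialize to CSV", {
    sp <- searchSpace(realDim(-1, 1))
    res <- caOptimize(function(p) p[[1]]^2, sp,
                      optimizerParams(populationSize = 8, maxIterations = 5,
                                      seed = 3))
    path <- withr::local_tempfile(fileext = ".csv")
    writeOptimizerTrace(res, path)
    tr <- read.csv(path)
    expect_equal(names(tr), c("iteration", "best_fitness", "mean_fitness"))
    expect_equal(nrow(tr), length(res$history))
})
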