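# Shared fixtures: small, fast synthetic objects built in code.

# A small labelled SpectralSet with arbitrary values.
toySpectralSet <- function(n = 6, wl = seq(400, 490, by = 10),
                           domain = "reflectance", seed = 1) {
    withr::with_seed(seed, {
        SpectralSet(matrix(runif(n * length(wl), 0.2, 0.8), n), wl,
                    labels = rep(c(0, 1), length.out = n), domain = domain)
    })
}

# Coarse-grid generator config: full 350-2500 nm span at a 10 nm step so
# generator-level properties stay cheap to test.
coarseConfig <- function(..., gridStep = 10) {
    generatorConfig(gridStep = gridStep,
                    plantedBands = data.frame(center = c(860, 1540),
                                              delta = c(0.01, 0.02),
                                              width = 10),
                    ...)
}

# Two well-separated Gaussian blobs in 2-D.
blobData <- function(n = 60, gap = 6, seed = 42) {
    withr::with_seed(seed, {
        x <- rbind(matrix(rnorm(n, 0, 1), ncol = 2),
                   matrix(rnorm(n, gap, 1), ncol = 2))
        list(x = x, y = rep(0:1, each = n / 2))
    })
}

# Exhaustive-enumeration discrete test space: all C(6,3) = 20 index
# triples with an injective objective.
discreteTripleProblem <- function() {
    combos <- utils::combn(6, 3)
    key <- function(v) paste(sort(v), collapse = "-")
    values <- stats::setNames(
        vapply(seq_len(ncol(combos)), function(i) {
            sum(combos[, i] * c(100, 10, 1))
        }, numeric(1)),
        apply(combos, 2, key)
    )
    objective <- function(point) {
        idx <- sort(unlist(point))
        if (anyDuplicated(idx)) return(1e6 + sum(idx))
        values[[key(idx)]]
    }
    list(objective = objective,
         space = searchSpace(intDim(1, 6), intDim(1, 6), intDim(1, 6)),
         optimum = min(values))
}
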