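# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withLocalSeed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv()),
            add = TRUE
        )
    }
    set.seed(as.integer(seed))
    force(code)
}

# Deterministically derive a child seed from a master seed and a stream of
# integer tags. Arithmetic kept in doubles below 2^53 so it is exact; the
# result always fits a 32-bit R integer.
deriveSeed <- function(seed, ...) {
    m <- 2147483629
    s <- as.numeric(seed) %% m
    for (k in as.numeric(c(...))) {
        s <- (s * 48271 + (k %% m) + 1) %% m
    }
    as.integer(s)
}

# Stratified shuffle-split of 0/1 labels into train/test/validation index
# sets. Fractions must sum to 1; counts are floored for train and test and
# the remainder goes to validation, per class, so all three subsets are
# non-empty for the sample sizes used here.
stratifiedSplit <- function(labels, fractions = c(0.6, 0.3, 0.1), seed = 1L) {
    stopifnot(length(fractions) == 3L)
    if (abs(sum(fractions) - 1) > 1e-8) {
        stop("split fractions must sum to 1")
    }
    train <- integer(0); test <- integer(0); validation <- integer(0)
    withLocalSeed(seed, {
        for (cl in sort(unique(labels))) {
            idx <- which(labels == cl)
            idx <- idx[sample.int(length(idx))]
            n <- length(idx)
            nTr <- floor(fractions[1] * n)
            nTe <- floor(fractions[2] * n)
            if (nTr < 1L || nTe < 1L || (n - nTr - nTe) < 1L) {
                stop("split fractions leave an empty subset for class ", cl)
            }
            train <- c(train, idx[seq_len(nTr)])
            test <- c(test, idx[nTr + seq_len(nTe)])
            validation <- c(validation, idx[(nTr + nTe + 1L):n])
        }
    })
    list(train = sort(train), test = sort(test), validation = sort(validation))
}
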