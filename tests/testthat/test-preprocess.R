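test_that("absorbance transform is log10(1/R)", {
    x <- SpectralSet(matrix(c(1, 0.1, 0.5, 0.25), 1), c(500, 501, 502, 503), 0)
    a <- reflectanceToAbsorbance(x)
    expect_equal(spectralDomain(a), "absorbance")
    expect_equal(as.numeric(spectraMatrix(a)),
                 c(0, 1, 0.301030, 0.602060), tolerance = 1e-6)
})

test_that("nonpositive reflectance is rejected, naming the sample", {
    m <- matrix(c(0.5, 0.5, 0, 0.5), 2, byrow = TRUE)
    x <- SpectralSet(m, c(500, 501), c(0, 1), ids = c("ok", "bad"))
    expect_error(reflectanceToAbsorbance(x), "bad")
})

test_that("absorbance is strictly decreasing in reflectance", {
    withr::with_seed(8, {
        r <- sort(runif(50, 0.01, 1))
        x <- SpectralSet(matrix(r, 1), seq_along(r), 0)
        a <- as.numeric(spectraMatrix(reflectanceToAbsorbance(x)))
        expect_true(all(diff(a) < 0))
    })
})

makeAbsorbance <- function(values, wl = seq_along(values[1, ])) {
    SpectralSet(values, wl, rep(0, nrow(values)), domain = "absorbance")
}

test_that("detrending removes polynomials up to the fitted order", {
    wl <- 1:50
    const <- makeAbsorbance(matrix(3.7, 1, 50), wl)
    expect_equal(max(abs(spectraMatrix(detrendSpectra(const, 2)))), 0,
                 tolerance = 1e-10)
    linear <- makeAbsorbance(matrix(2 + 0.05 * wl, 1), wl)
    expect_equal(max(abs(spectraMatrix(detrendSpectra(linear, 2)))), 0,
                 tolerance = 1e-8)
    expect_error(detrendSpectra(makeAbsorbance(matrix(1, 1, 3), 1:3), 5),
                 "order")
})

test_that("detrend residual matches a normal-equations oracle", {
    wl <- 1:40
    y <- 1 + 0.02 * wl - 0.001 * wl^2
    y[17] <- y[17] + 1   # unit impulse on a quadratic baseline
    x <- makeAbsorbance(matrix(y, 1), wl)
    got <- as.numeric(spectraMatrix(detrendSpectra(x, 2)))
    # oracle: explicit least-squares solve on the same scaled basis
    lam <- 2 * (wl - wl[1]) / (wl[40] - wl[1]) - 1
    X <- cbind(1, lam, lam^2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(got, as.numeric(y - X %*% beta), tolerance = 1e-8)
})

test_that("median smoothing follows the brute-force windowed median", {
    const <- makeAbsorbance(matrix(2, 1, 9))
    expect_equal(as.numeric(spectraMatrix(medianSmooth(const, 3))),
                 rep(2, 9))
    impulse <- makeAbsorbance(matrix(c(0, 0, 1, 0, 0), 1))
    expect_equal(as.numeric(spectraMatrix(medianSmooth(impulse, 3))),
                 rep(0, 5))
    expect_error(medianSmooth(const, 4), "odd")

    # independent oracle: explicit symmetric padding + windowed median
    bruteMedian <- function(v, w) {
        h <- (w - 1) / 2
        padded <- c(rev(v[1:h]), v, rev(v[(length(v) - h + 1):length(v)]))
        vapply(seq_along(v), function(i) median(padded[i:(i + 2 * h)]),
               numeric(1))
    }
    expect_equal(
        as.numeric(spectraMatrix(medianSmooth(
            makeAbsorbance(matrix(c(1, 2, 9, 4, 5), 1)), 3))),
        bruteMedian(c(1, 2, 9, 4, 5), 3))   # = 1 2 4 5 5
    withr::with_seed(3, {
        for (w in c(3, 5, 7)) {
            v <- rnorm(31)
            expect_equal(
                as.numeric(spectraMatrix(medianSmooth(
                    makeAbsorbance(matrix(v, 1)), w))),
                bruteMedian(v, w))
        }
    })
})

test_that("region split uses [350,1100) and [1100,2500] with 1100 in SWIR", {
    full <- SpectralSet(matrix(0.5, 2, 2151), seq(350, 2500), c(0, 1))
    rg <- splitRegions(full)
    expect_equal(nrow(rg$visnir), 750)
    expect_equal(nrow(rg$swir), 1401)
    expect_equal(max(wavelengths(rg$visnir)), 1099)
    expect_equal(min(wavelengths(rg$swir)), 1100)
    expect_equal(sort(c(wavelengths(rg$visnir), wavelengths(rg$swir))),
                 wavelengths(full))

    visOnly <- SpectralSet(matrix(0.5, 2, 10), seq(400, 490, 10), c(0, 1))
    expect_error(splitRegions(visOnly), "SWIR")
    wide <- SpectralSet(matrix(0.5, 2, 4), c(300, 400, 1200, 2600), c(0, 1))
    expect_warning(rg2 <- splitRegions(wide), "dropped")
    expect_equal(wavelengths(rg2$visnir), 400)
})

test_that("the pipeline applies absorbance, detrend, smooth in order", {
    x <- toySpectralSet(n = 4, wl = seq(400, 790, by = 10))
    pre <- preprocessSpectra(x, detrendOrder = 2, medianWindow = 3)
    expect_equal(spectralDomain(pre), "absorbance")
    expect_equal(dim(spectraMatrix(pre)), dim(spectraMatrix(x)))
    expect_equal(S4Vectors::metadata(pre)$processing,
                 c("absorbance[log10(1/R)]", "detrend[order=2]",
                   "medianSmooth[window=3]"))
    # detrend(median_smooth(constant)) is exactly zero
    const <- makeAbsorbance(matrix(5, 2, 20), 1:20)
    z <- detrendSpectra(medianSmooth(const, 5), 2)
    expect_equal(max(abs(spectraMatrix(z))), 0, tolerance = 1e-10)
})
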