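#' Configuration for the synthetic spectra generator
#'
#' Describes the generating model for labelled reflectance spectra: a
#' smooth class-shared base curve (a mixture of broad Gaussian peaks plus a
#' constant floor), class-discriminative Gaussian "defect bands" subtracted
#' from the defective class only (internally defective produce reflects
#' slightly less light inside those bands), and per-sample nuisance terms:
#' multiplicative scatter, a low-order polynomial baseline drift, and
#' additive point noise. Values are clipped to (1e-4, 1] so a subsequent
#' log10(1/R) transform is always finite.
#'
#' The default plants three bands in the Vis/NIR region (861, 883, 998 nm)
#' and three in the SWIR region (1539, 1858, 1896 nm), with the SWIR
#' amplitude deltas twice the Vis/NIR ones so that class separability is
#' larger in the SWIR region.
#'
#' @param nHealthy,nDefective samples per class.
#' @param gridStart,gridEnd,gridStep wavelength grid in nm (default
#'   350-2500 nm at 1 nm, 2151 points).
#' @param nBasePeaks number of class-shared base Gaussian peaks.
#' @param basePeakWidth standard deviation (nm) of the base peaks.
#' @param plantedBands data.frame with columns \code{center}, \code{delta},
#'   \code{width}: band center (nm, must lie on the grid), class amplitude
#'   difference (reflectance units), and band standard deviation (nm).
#' @param scatterSd standard deviation of the per-sample multiplicative
#'   scatter factor.
#' @param baselineDriftOrder polynomial order of the per-sample baseline.
#' @param baselineCoeffSd standard deviation of the baseline coefficients.
#' @param noiseSd standard deviation of the additive per-point noise.
#' @param seed master seed; one master seed fans out to per-sample streams
#'   indexed by sample counter, so row order never changes values.
#'
#' @return A list of class \code{"generatorConfig"}.
#' @seealso \code{\link{generateDataset}}, \code{\link{plantedTruth}}
#' @export
generatorConfig <- function(nHealthy = 120L, nDefective = 120L,
                            gridStart = 350, gridEnd = 2500, gridStep = 1,
                            nBasePeaks = 8L, basePeakWidth = 120,
                            plantedBands = defaultPlantedBands(),
                            scatterSd = 0.05,
                            baselineDriftOrder = 2L, baselineCoeffSd = 0.005,
                            noiseSd = 0.015, seed = 1L) {
    cfg <- list(
        nHealthy = as.integer(nHealthy), nDefective = as.integer(nDefective),
        gridStart = gridStart, gridEnd = gridEnd, gridStep = gridStep,
        nBasePeaks = as.integer(nBasePeaks), basePeakWidth = basePeakWidth,
        plantedBands = as.data.frame(plantedBands),
        scatterSd = scatterSd,
        baselineDriftOrder = as.integer(baselineDriftOrder),
        baselineCoeffSd = baselineCoeffSd,
        noiseSd = noiseSd, seed = as.integer(seed)
    )
    class(cfg) <- "generatorConfig"
    validateGeneratorConfig(cfg)
    cfg
}

#' @rdname generatorConfig
#' @export
defaultPlantedBands <- function() {
    data.frame(
        center = c(861, 883, 998, 1539, 1858, 1896),
        delta = c(0.010, 0.010, 0.010, 0.020, 0.020, 0.020),
        width = rep(10, 6)
    )
}

validateGeneratorConfig <- function(cfg) {
    if (cfg$nHealthy < 1L || cfg$nDefective < 1L) {
        stop("sample counts must be >= 1")
    }
    span <- cfg$gridEnd - cfg$gridStart
    if (span <= 0 || cfg$gridStep <= 0) stop("invalid wavelength grid")
    if (abs(span / cfg$gridStep - round(span / cfg$gridStep)) > 1e-9) {
        stop("grid step must divide the grid span")
    }
    if (cfg$scatterSd < 0 || cfg$baselineCoeffSd < 0 || cfg$noiseSd < 0) {
        stop("standard deviations must be nonnegative")
    }
    pb <- cfg$plantedBands
    if (nrow(pb)) {
        stopifnot(all(c("center", "delta", "width") %in% colnames(pb)))
        if (any(pb$width < 0)) stop("band widths must be nonnegative")
        grid <- generatorGrid(cfg)
        off <- pb$center[!vapply(pb$center, function(cc) {
            any(abs(grid - cc) < 1e-9)
        }, logical(1))]
        if (length(off)) {
            stop("planted band center(s) not on the wavelength grid: ",
                 paste(off, collapse = ", "))
        }
    }
    invisible(cfg)
}

generatorGrid <- function(cfg) {
    seq(cfg$gridStart, cfg$gridEnd, by = cfg$gridStep)
}

#' Planted discriminative band centers
#'
#' Ground truth of the generator: the sorted centers (nm) of the bands in
#' which the two class-mean spectra differ. Used by selection-recovery
#' tests.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return Sorted numeric vector of band centers (possibly empty).
#' @examples
#' plantedTruth(generatorConfig())
#' @export
plantedTruth <- function(config) {
    validateGeneratorConfig(config)
    sort(as.numeric(config$plantedBands$center))
}

# Noise-free class-mean spectra implied by the config (structure stream
# only). Returns list(grid, healthy, defective).
classMeanSpectra <- function(config) {
    grid <- generatorGrid(config)
    base <- withLocalSeed(deriveSeed(config$seed, 101L), {
        centers <- stats::runif(config$nBasePeaks, config$gridStart,
                                config$gridEnd)
        heights <- stats::runif(config$nBasePeaks, 0.05, 0.15)
        b <- rep(0.25, length(grid))
        for (j in seq_len(config$nBasePeaks)) {
            b <- b + heights[j] *
                exp(-0.5 * ((grid - centers[j]) / config$basePeakWidth)^2)
        }
        b
    })
    defect <- rep(0, length(grid))
    pb <- config$plantedBands
    for (j in seq_len(nrow(pb))) {
        w <- max(pb$width[j], 1e-9)
        defect <- defect + pb$delta[j] *
            exp(-0.5 * ((grid - pb$center[j]) / w)^2)
    }
    list(grid = grid, healthy = base, defective = base - defect)
}

#' Generate a labelled synthetic spectra dataset
#'
#' Draws \code{nHealthy + nDefective} reflectance spectra from the
#' generating model of \code{\link{generatorConfig}}. Each sample i is
#' produced from its own RNG stream derived from the master seed and i, so
#' the same (config, seed) always yields a bit-identical dataset and
#' changing the number of samples never changes the values of earlier
#' samples.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return A \linkS4class{SpectralSet} in the reflectance domain; healthy
#'   samples first.
#' @examples
#' cfg <- generatorConfig(nHealthy = 5, nDefective = 5)
#' generateDataset(cfg)
#' @export
generateDataset <- function(config) {
    validateGeneratorConfig(config)
    means <- classMeanSpectra(config)
    p <- length(means$grid)
    n <- config$nHealthy + config$nDefective
    labels <- c(rep(0L, config$nHealthy), rep(1L, config$nDefective))
    lamScaled <- if (p > 1L) {
        2 * (means$grid - means$grid[1]) / (means$grid[p] - means$grid[1]) - 1
    } else {
        rep(0, p)
    }
    powers <- outer(lamScaled, 0:config$baselineDriftOrder, `^`)
    values <- matrix(0, n, p)
    for (i in seq_len(n)) {
        mu <- if (labels[i] == 0L) means$healthy else means$defective
        values[i, ] <- withLocalSeed(deriveSeed(config$seed, 202L, i), {
            s <- if (config$scatterSd > 0) {
                stats::rnorm(1, 0, config$scatterSd)
            } else 0
            coef <- if (config$baselineCoeffSd > 0) {
                stats::rnorm(config$baselineDriftOrder + 1L, 0,
                             config$baselineCoeffSd)
            } else rep(0, config$baselineDriftOrder + 1L)
            eps <- if (config$noiseSd > 0) {
                stats::rnorm(p, 0, config$noiseSd)
            } else rep(0, p)
            mu * (1 + s) + as.numeric(powers %*% coef) + eps
        })
    }
    values <- pmin(pmax(values, 1e-4), 1)
    SpectralSet(values, means$grid, labels, domain = "reflectance")
}

#' Monte-Carlo correct classification rate of the generating-model oracle
#'
#' Classifies freshly generated samples with the matched filter implied by
#' the generator's own class-mean templates (projection onto the template
#' difference, midpoint threshold; exact ties are decided by a fair coin).
#' This is an upper-bound reference classifier used to characterise the
#' difficulty of a configuration: with zero planted amplitude it attains
#' 50% by symmetry, and its CCR is non-decreasing in the planted amplitude.
#'
#' @param config a \code{\link{generatorConfig}}; counts are overridden.
#' @param n total number of Monte-Carlo samples (split evenly).
#' @param seed RNG seed for the Monte-Carlo draw.
#' @return CCR in percent.
#' @export
bayesOracleCCR <- function(config, n = 10000L, seed = 1L) {
    half <- as.integer(ceiling(n / 2))
    cfg <- config
    cfg$nHealthy <- half
    cfg$nDefective <- half
    cfg$seed <- deriveSeed(seed, 303L)
    ds <- generateDataset(cfg)
    means <- classMeanSpectra(cfg)
    d <- means$defective - means$healthy
    mid <- (means$defective + means$healthy) / 2
    x <- spectraMatrix(ds)
    score <- as.numeric(sweep(x, 2, mid) %*% d)
    pred <- withLocalSeed(deriveSeed(seed, 304L), {
        tie <- score == 0
        out <- as.integer(score > 0)
        if (any(tie)) out[tie] <- stats::rbinom(sum(tie), 1L, 0.5)
        out
    })
    100 * mean(pred == classLabels(ds))
}
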