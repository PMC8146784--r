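#' Convert reflectance spectra to absorbance
#'
#' Applies the standard absorbance transform A = log10(1/R) element-wise.
#' All reflectance values must be strictly positive.
#'
#' @param x a \linkS4class{SpectralSet} in the reflectance domain.
#' @return A \linkS4class{SpectralSet} in the absorbance domain.
#' @examples
#' x <- SpectralSet(matrix(c(1, 0.1), 1), c(500, 501), 0)
#' spectraMatrix(reflectanceToAbsorbance(x))  # 0 and 1
#' @export
reflectanceToAbsorbance <- function(x) {
    if (spectralDomain(x) != "reflectance") {
        stop("input must be in the reflectance domain")
    }
    vals <- assay(x, "spectra")
    bad <- which(apply(vals <= 0, 2, any))
    if (length(bad)) {
        stop("nonpositive reflectance in sample(s): ",
             paste(sampleIds(x)[bad], collapse = ", "))
    }
    SummarizedExperiment::assay(x, "spectra") <- -log10(vals)
    spectralDomain(x) <- "absorbance"
    addProcessingStep(x, "absorbance[log10(1/R)]")
}

#' Remove a per-sample polynomial baseline (detrending)
#'
#' Fits, by least squares, a polynomial of the given order in wavelength to
#' each spectrum and subtracts it. This is the scatter-correction
#' detrending step of the preprocessing pipeline; order 2 removes constant
#' offset, slope and curvature.
#'
#' @param x a \linkS4class{SpectralSet} in the absorbance domain.
#' @param order polynomial order (default 2); must be smaller than the
#'   number of wavelengths.
#' @return A detrended \linkS4class{SpectralSet}.
#' @export
detrendSpectra <- function(x, order = 2L) {
    if (spectralDomain(x) != "absorbance") {
        stop("detrending expects absorbance spectra")
    }
    p <- nrow(x)
    if (order >= p) stop("polynomial order must be < number of wavelengths")
    wl <- wavelengths(x)
    lam <- if (p > 1L) 2 * (wl - wl[1]) / (wl[p] - wl[1]) - 1 else 0
    basis <- qr.Q(qr(outer(lam, 0:order, `^`)))
    m <- t(assay(x, "spectra"))            # samples x wavelengths
    fitted <- (m %*% basis) %*% t(basis)
    SummarizedExperiment::assay(x, "spectra") <- t(m - fitted)
    addProcessingStep(x, sprintf("detrend[order=%d]", order))
}

# Sliding-window median of one vector with symmetric (edge-reflecting)
# padding, so window medians at the ends are taken over real neighbouring
# values mirrored at the boundary.
slidingMedian <- function(v, window) {
    h <- (window - 1L) %/% 2L
    p <- length(v)
    padded <- c(rev(v[seq_len(h)]), v, rev(v[(p - h + 1L):p]))
    sm <- stats::runmed(padded, window, endrule = "keep")
    sm[(h + 1L):(h + p)]
}

#' Median smoothing of spectra
#'
#' Per-sample sliding-window median filter with an odd window and
#' symmetric edge padding.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param window odd window width >= 3, at most the number of wavelengths.
#' @return A smoothed \linkS4class{SpectralSet}.
#' @export
medianSmooth <- function(x, window = 5L) {
    window <- as.integer(window)
    if (window %% 2L == 0L) stop("median window must be odd")
    if (window < 3L || window > nrow(x)) {
        stop("median window must be between 3 and the number of wavelengths")
    }
    m <- t(assay(x, "spectra"))
    sm <- t(apply(m, 1, slidingMedian, window = window))
    SummarizedExperiment::assay(x, "spectra") <- t(sm)
    addProcessingStep(x, sprintf("medianSmooth[window=%d]", window))
}

#' Split a spectrum into Vis/NIR and SWIR regions
#'
#' Partitions the wavelength grid into the visible/near-infrared region
#' [350, 1100) nm and the short-wavelength infrared region [1100, 2500] nm.
#' The boundary wavelength 1100 nm belongs to SWIR only (half-open
#' convention, so no column is duplicated). Wavelengths outside
#' [350, 2500] nm are dropped with a warning.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @return A list with elements \code{visnir} and \code{swir}, both
#'   \linkS4class{SpectralSet}s. An error is raised if either region is
#'   empty.
#' @export
splitRegions <- function(x) {
    wl <- wavelengths(x)
    out <- wl < 350 | wl > 2500
    if (any(out)) {
        warning(sum(out), " wavelength(s) outside [350, 2500] nm dropped")
    }
    visIdx <- which(wl >= 350 & wl < 1100)
    swirIdx <- which(wl >= 1100 & wl <= 2500)
    if (!length(visIdx)) stop("Vis/NIR region [350, 1100) nm is empty")
    if (!length(swirIdx)) stop("SWIR region [1100, 2500] nm is empty")
    list(visnir = x[visIdx, ], swir = x[swirIdx, ])
}

#' Full preprocessing pipeline
#'
#' Applies, in this fixed order: absorbance conversion, polynomial
#' detrending, median smoothing. Each step appends a provenance line to
#' the object's processing log (see \code{show}).
#'
#' @param x a \linkS4class{SpectralSet} in the reflectance domain.
#' @param detrendOrder polynomial order for detrending.
#' @param medianWindow odd median filter window.
#' @return A preprocessed \linkS4class{SpectralSet} (absorbance domain).
#' @export
preprocessSpectra <- function(x, detrendOrder = 2L, medianWindow = 5L) {
    medianSmooth(detrendSpectra(reflectanceToAbsorbance(x),
                                order = detrendOrder),
                 window = medianWindow)
}
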