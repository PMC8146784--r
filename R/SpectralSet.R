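#' Construct a SpectralSet
#'
#' @param spectra numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, length \code{ncol(spectra)}.
#' @param labels binary vector (0 = healthy, 1 = defective), or a
#'   character/factor vector with levels \code{"healthy"}/\code{"defective"}.
#' @param ids optional sample identifiers; defaults to \code{S001, S002, ...}.
#' @param domain photometric domain of the values, \code{"reflectance"}
#'   (values in (0, 1]) or \code{"absorbance"}.
#'
#' @return A \linkS4class{SpectralSet}.
#' @examples
#' x <- SpectralSet(matrix(runif(20, 0.2, 0.8), 2), seq(400, 409), c(0, 1))
#' x
#' @export
SpectralSet <- function(spectra, wavelengths, labels, ids = NULL,
                        domain = c("reflectance", "absorbance")) {
    domain <- match.arg(domain)
    spectra <- as.matrix(spectra)
    if (length(wavelengths) != ncol(spectra)) {
        stop("length(wavelengths) must equal ncol(spectra)")
    }
    labels <- normalizeLabels(labels)
    if (length(labels) != nrow(spectra)) {
        stop("one label per sample (matrix row) is required")
    }
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(spectra)))
    ids <- as.character(ids)
    assayMat <- t(spectra)
    dimnames(assayMat) <- list(NULL, ids)
    se <- SummarizedExperiment(
        assays = list(spectra = assayMat),
        rowData = DataFrame(wavelength_nm = as.numeric(wavelengths)),
        colData = DataFrame(label = as.integer(labels),
                            class = classNameFromLabel(labels),
                            row.names = ids),
        metadata = list(domain = domain, processing = character(0))
    )
    new("SpectralSet", se)
}

normalizeLabels <- function(labels) {
    if (is.factor(labels)) labels <- as.character(labels)
    if (is.character(labels)) {
        bad <- setdiff(unique(labels), c("healthy", "defective"))
        if (length(bad)) {
            stop("unknown class label(s): ", paste(bad, collapse = ", "))
        }
        labels <- ifelse(labels == "defective", 1L, 0L)
    }
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
    as.integer(labels)
}

classNameFromLabel <- function(labels) {
    c("healthy", "defective")[as.integer(labels) + 1L]
}

#' Accessors for SpectralSet objects
#'
#' \code{wavelengths} returns the wavelength grid (nm);
#' \code{spectraMatrix} the samples-by-wavelengths value matrix;
#' \code{classLabels} the integer 0/1 labels (healthy = 0, defective = 1);
#' \code{sampleIds} the sample identifiers; \code{spectralDomain} the
#' photometric domain tag.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param value replacement domain, \code{"reflectance"} or
#'   \code{"absorbance"}.
#' @return see the individual descriptions.
#' @name SpectralSet-accessors
NULL

#' @rdname SpectralSet-accessors
#' @export
setMethod("wavelengths", "SpectralSet", function(x) {
    as.numeric(rowData(x)$wavelength_nm)
})

#' @rdname SpectralSet-accessors
#' @export
setMethod("spectraMatrix", "SpectralSet", function(x) {
    m <- t(assay(x, "spectra"))
    colnames(m) <- as.character(wavelengths(x))
    m
})

#' @rdname SpectralSet-accessors
#' @export
setMethod("classLabels", "SpectralSet", function(x) {
    as.integer(colData(x)$label)
})

#' @rdname SpectralSet-accessors
#' @export
setMethod("sampleIds", "SpectralSet", function(x) colnames(x))

#' @rdname SpectralSet-accessors
#' @export
setMethod("spectralDomain", "SpectralSet", function(x) metadata(x)$domain)

#' @rdname SpectralSet-accessors
#' @export
setReplaceMethod("spectralDomain", "SpectralSet", function(x, value) {
    stopifnot(value %in% c("reflectance", "absorbance"))
    metadata(x)$domain <- value
    x
})

setMethod("show", "SpectralSet", function(object) {
    wl <- wavelengths(object)
    lab <- classLabels(object)
    cat(sprintf(
        "SpectralSet: %d samples x %d wavelengths [%g-%g nm], %s domain\n",
        ncol(object), nrow(object), min(wl), max(wl), spectralDomain(object)
    ))
    cat(sprintf("  classes: %d healthy, %d defective\n",
                sum(lab == 0L), sum(lab == 1L)))
    steps <- metadata(object)$processing
    if (length(steps)) {
        cat("  processing:", paste(steps, collapse = " -> "), "\n")
    }
})

# Record a provenance line for a processing step.
addProcessingStep <- function(x, step) {
    metadata(x)$processing <- c(metadata(x)$processing, step)
    x
}

#' Restrict a SpectralSet to selected wavelengths
#'
#' Returns the column subset of the spectra at exactly the requested
#' wavelengths, in the requested order. Every wavelength must be present on
#' the grid.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param wl numeric vector of wavelengths (nm) to keep.
#' @return A \linkS4class{SpectralSet} with \code{length(wl)} wavelengths.
#' @examples
#' x <- SpectralSet(matrix(runif(20, 0.2, 0.8), 2), seq(400, 409), c(0, 1))
#' restrictWavelengths(x, c(402, 405, 408))
#' @export
restrictWavelengths <- function(x, wl) {
    grid <- wavelengths(x)
    idx <- match(wl, grid)
    if (anyNA(idx)) {
        stop("wavelength(s) not on the grid: ",
             paste(wl[is.na(idx)], collapse = ", "))
    }
    x[idx, ]
}

#' Read and write spectra in the project CSV format
#'
#' The interchange format is a plain CSV with header
#' \code{id,label,<wavelength_1>,...,<wavelength_n>}, one row per sample,
#' label \code{healthy} or \code{defective}, UTF-8, "." decimal separator.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param path file path.
#' @param domain photometric domain to tag the values read from file.
#' @return \code{readSpectraCSV} returns a \linkS4class{SpectralSet};
#'   \code{writeSpectraCSV} returns \code{path} invisibly.
#' @export
writeSpectraCSV <- function(x, path) {
    df <- data.frame(
        id = sampleIds(x),
        label = classNameFromLabel(classLabels(x)),
        spectraMatrix(x),
        check.names = FALSE,
        stringsAsFactors = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path, domain = c("reflectance", "absorbance")) {
    domain <- match.arg(domain)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!identical(colnames(df)[1:2], c("id", "label"))) {
        stop("expected header to start with 'id,label'")
    }
    wl <- as.numeric(colnames(df)[-(1:2)])
    if (anyNA(wl)) stop("non-numeric wavelength column name(s)")
    SpectralSet(as.matrix(df[, -(1:2), drop = FALSE]), wl,
                labels = df$label, ids = df$id, domain = domain)
}
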