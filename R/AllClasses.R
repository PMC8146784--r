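#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SpectralSet: labelled reflectance/absorbance spectra
#'
#' A \code{SpectralSet} holds one spectrum per sample on a common, strictly
#' increasing wavelength grid, together with a binary condition label
#' (healthy = 0, defective = 1). It extends
#' \linkS4class{SummarizedExperiment}: wavelengths are rows, samples are
#' columns, the single assay \code{"spectra"} carries the values, and the
#' photometric domain (\code{"reflectance"} or \code{"absorbance"}) is kept
#' in the object metadata so that preprocessing steps can enforce their
#' preconditions.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#'
#' @seealso \code{\link{SpectralSet}} (constructor),
#'   \code{\link{spectraMatrix}}, \code{\link{wavelengths}},
#'   \code{\link{classLabels}}, \code{\link{spectralDomain}}
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
    msg <- character(0)
    if (!"spectra" %in% SummarizedExperiment::assayNames(object)) {
        msg <- c(msg, "assay 'spectra' is missing")
    } else {
        vals <- SummarizedExperiment::assay(object, "spectra")
        if (anyNA(vals)) msg <- c(msg, "spectra contain missing values")
    }
    wl <- rowData(object)$wavelength_nm
    if (is.null(wl)) {
        msg <- c(msg, "rowData column 'wavelength_nm' is missing")
    } else if (length(wl) > 1L && any(diff(wl) <= 0)) {
        msg <- c(msg, "wavelengths must be strictly increasing")
    }
    lab <- colData(object)$label
    if (is.null(lab)) {
        msg <- c(msg, "colData column 'label' is missing")
    } else if (!all(lab %in% c(0L, 1L))) {
        msg <- c(msg, "labels must be 0 (healthy) or 1 (defective)")
    }
    dom <- metadata(object)$domain
    if (is.null(dom) || !dom %in% c("reflectance", "absorbance")) {
        msg <- c(msg, "metadata 'domain' must be 'reflectance' or 'absorbance'")
    }
    if (length(msg)) msg else TRUE
})

#' ANNArchitecture: configuration of a small feed-forward classifier net
#'
#' Describes the hyperparameters the metaheuristic architecture search
#' ranges over: 1-3 hidden layers of 1-25 neurons each, one transfer
#' function per hidden layer from \code{\link{annTransferCatalog}}, a
#' training algorithm from \code{\link{annTrainingCatalog}}, a weight/bias
#' learning-rate rule from \code{\link{annLearnCatalog}}, and the output
#' activation (\code{"sigmoid"} for class scores in [0,1], or
#' \code{"linear"}).
#'
#' @slot neurons integer vector, one entry per hidden layer.
#' @slot transfer character vector of hidden transfer-function ids.
#' @slot trainingFn character, training-algorithm id.
#' @slot learnFn character, learning-rate rule id.
#' @slot outputActivation character, \code{"sigmoid"} or \code{"linear"}.
#'
#' @seealso \code{\link{annArchitecture}}, \code{\link{trainANN}}
#' @export
setClass("ANNArchitecture", representation(
    neurons = "integer",
    transfer = "character",
    trainingFn = "character",
    learnFn = "character",
    outputActivation = "character"
))

setValidity("ANNArchitecture", function(object) {
    msg <- character(0)
    nl <- length(object@neurons)
    if (nl < 1L || nl > 3L) {
        msg <- c(msg, "number of hidden layers must be between 1 and 3")
    }
    if (any(object@neurons < 1L) || any(object@neurons > 25L)) {
        msg <- c(msg, "neurons per hidden layer must be between 1 and 25")
    }
    if (length(object@transfer) != nl) {
        msg <- c(msg, "one transfer function per hidden layer is required")
    }
    if (!all(object@transfer %in% annTransferCatalog())) {
        msg <- c(msg, "unknown transfer function id")
    }
    if (length(object@trainingFn) != 1L ||
        !object@trainingFn %in% annTrainingCatalog()) {
        msg <- c(msg, "unknown training function id")
    }
    if (length(object@learnFn) != 1L ||
        !object@learnFn %in% annLearnCatalog()) {
        msg <- c(msg, "unknown learning function id")
    }
    if (length(object@outputActivation) != 1L ||
        !object@outputActivation %in% c("sigmoid", "linear")) {
        msg <- c(msg, "outputActivation must be 'sigmoid' or 'linear'")
    }
    if (length(msg)) msg else TRUE
})
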