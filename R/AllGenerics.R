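#' @rdname SpectralSet-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("spectralDomain", function(x) standardGeneric("spectralDomain"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("spectralDomain<-",
    function(x, value) standardGeneric("spectralDomain<-"))
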