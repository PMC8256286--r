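#' @rdname SpectrumRun
#' @param object,x an object
#' @export
setGeneric("rtime", function(x) standardGeneric("rtime"))

#' @rdname Chromatogram
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname GlycoPeptide
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' @rdname GlycoPeptide
#' @export
setGeneric("nConsensusTrp", function(x) standardGeneric("nConsensusTrp"))
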