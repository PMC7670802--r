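#' @rdname OtuTable-accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("treatmentArm", function(x) standardGeneric("treatmentArm"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname Grm-accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname Grm-accessors
#' @export
setGeneric("nSnpsUsed", function(x) standardGeneric("nSnpsUsed"))

#' @rdname VarCompFit-accessors
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
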