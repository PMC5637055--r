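#' @rdname TranscriptSet-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("biotypes", function(x) standardGeneric("biotypes"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname NBModel-accessors
#' @export
setGeneric("dispersions", function(x) standardGeneric("dispersions"))

#' @rdname NBModel-accessors
#' @export
setGeneric("sizeFactors", function(x) standardGeneric("sizeFactors"))
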