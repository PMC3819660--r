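#' @rdname scaffoldLengths
#' @export
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))

#' @rdname abundance
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname sampleTotals
#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))

#' @rdname normFactors
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' @rdname normalizedExpression
#' @export
setGeneric("normalizedExpression",
           function(x) standardGeneric("normalizedExpression"))

#' @rdname referenceGenes
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))

#' @rdname trimmedSets
#' @export
setGeneric("trimmedSets", function(x) standardGeneric("trimmedSets"))

#' @rdname classification
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
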