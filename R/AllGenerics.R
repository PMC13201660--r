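#' @rdname RiboReference-class
#' @param x,object an object.
#' @export
setGeneric("refName", function(x) standardGeneric("refName"))

#' @rdname RiboReference-class
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname RiboReference-class
#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' @rdname TemplateSet-class
#' @export
setGeneric("templateNames", function(x) standardGeneric("templateNames"))

#' @rdname TemplateSet-class
#' @export
setGeneric("templateRanges", function(x) standardGeneric("templateRanges"))

#' @rdname TemplateSet-class
#' @export
setGeneric("templateCategory", function(x) standardGeneric("templateCategory"))

#' @rdname RiboReadSet-class
#' @export
setGeneric("readRanges", function(x) standardGeneric("readRanges"))

#' @rdname RiboReadSet-class
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))

#' @rdname RiboReadSet-class
#' @export
setGeneric("readDeletions", function(x) standardGeneric("readDeletions"))

#' @rdname RiboReadSet-class
#' @export
setGeneric("modProbs", function(x) standardGeneric("modProbs"))

#' @rdname RiboReadSet-class
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname RiboReadSet-class
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname RiboReadSet-class
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @rdname RiboReadSet-class
#' @export
setGeneric("totalAligned", function(x) standardGeneric("totalAligned"))

#' @rdname IntensityMatrix-class
#' @export
setGeneric("matrixCells", function(x) standardGeneric("matrixCells"))

#' @rdname IntensityMatrix-class
#' @export
setGeneric("matrixDim", function(x) standardGeneric("matrixDim"))
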