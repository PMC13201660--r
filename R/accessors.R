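#' @rdname RiboReference-class
#' @export
setMethod("refName", "RiboReference", function(x) x@name)

#' @rdname RiboReference-class
#' @export
setMethod("refSequence", "RiboReference", function(x) x@sequence)

#' @rdname RiboReference-class
#' @export
setMethod("refLength", "RiboReference", function(x) nchar(x@sequence))

setMethod("show", "RiboReference", function(object) {
  cat("RiboReference '", object@name, "': ", nchar(object@sequence),
      " nt\n", sep = "")
})

#' @rdname TemplateSet-class
#' @export
setMethod("templateNames", "TemplateSet", function(x) names(x@ranges))

#' @rdname TemplateSet-class
#' @export
setMethod("templateRanges", "TemplateSet", function(x) x@ranges)

#' @rdname TemplateSet-class
#' @export
setMethod("templateCategory", "TemplateSet", function(x) {
  stats::setNames(x@category, names(x@ranges))
})

#' @rdname TemplateSet-class
#' @export
setMethod("length", "TemplateSet", function(x) length(x@ranges))

#' @rdname TemplateSet-class
#' @export
setMethod("refLength", "TemplateSet", function(x) x@refLength)

#' @rdname TemplateSet-class
#' @param i index (name, integer or logical) of templates to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TemplateSet", function(x, i, j, ..., drop = FALSE) {
  new("TemplateSet", ranges = x@ranges[i], category = x@category[.tplIdx(x, i)],
      refLength = x@refLength)
})

.tplIdx <- function(x, i) {
  if (is.character(i)) match(i, names(x@ranges)) else i
}

setMethod("show", "TemplateSet", function(object) {
  cat("TemplateSet with ", length(object@ranges), " templates on a ",
      object@refLength, "-nt reference\n", sep = "")
  tab <- table(object@category)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
})

#' @rdname RiboReadSet-class
#' @export
setMethod("readRanges", "RiboReadSet", function(x) x@reads)

#' @rdname RiboReadSet-class
#' @export
setMethod("readIds", "RiboReadSet", function(x) mcols(x@reads)$read_id)

#' @rdname RiboReadSet-class
#' @export
setMethod("readDeletions", "RiboReadSet", function(x) x@deletions)

#' @rdname RiboReadSet-class
#' @export
setMethod("modProbs", "RiboReadSet", function(x) {
  stats::setNames(list(pos = x@modPos, prob = x@modProb), c("pos", "prob"))
})

#' @rdname RiboReadSet-class
#' @export
setMethod("sampleName", "RiboReadSet", function(x) x@sample)

#' @rdname RiboReadSet-class
#' @export
setMethod("condition", "RiboReadSet", function(x) x@condition)

#' @rdname RiboReadSet-class
#' @export
setMethod("replicateId", "RiboReadSet", function(x) x@replicate)

#' @rdname RiboReadSet-class
#' @export
setMethod("totalAligned", "RiboReadSet", function(x) length(x@reads))

#' @rdname RiboReadSet-class
#' @export
setMethod("length", "RiboReadSet", function(x) length(x@reads))

setMethod("show", "RiboReadSet", function(object) {
  cat("RiboReadSet: ", length(object@reads), " aligned reads",
      if (nzchar(object@sample)) sprintf(" [sample %s", object@sample),
      if (nzchar(object@condition)) sprintf(", condition %s", object@condition),
      if (nzchar(object@sample)) sprintf(", replicate %d]", object@replicate),
      "\n", sep = "")
  nmod <- sum(lengths(object@modPos) > 0L)
  if (nmod)
    cat("  ", nmod, " reads carry modification probabilities\n", sep = "")
  if (object@hasBasecalls)
    cat("  mismatch basecalls available\n")
})

#' @rdname IntensityMatrix-class
#' @export
setMethod("matrixCells", "IntensityMatrix", function(x) x@cells)

#' @rdname IntensityMatrix-class
#' @export
setMethod("matrixDim", "IntensityMatrix", function(x) x@dim)

setMethod("show", "IntensityMatrix", function(object) {
  cat("IntensityMatrix: ", nrow(object@cells), " occupied cells, ",
      sum(object@cells$count), " reads, dim ", object@dim, "^2\n", sep = "")
})
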