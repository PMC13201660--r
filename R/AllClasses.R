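#' @import methods
#' @importFrom S4Vectors metadata mcols mcols<- DataFrame
#' @importFrom IRanges IRanges IRangesList NumericList IntegerList CharacterList
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges CompressedIRangesList
#'   CompressedIntegerList CompressedNumericList CompressedCharacterList
NULL

#' Single pre-rRNA reference sequence
#'
#' Holds the 47S/45SN1-like primary-transcript sequence that every read is
#' aligned against. All coordinates in the package are 1-based and inclusive
#' on this reference.
#'
#' @slot name single reference name (the SAM/BAM target name).
#' @slot sequence the nucleotide sequence as one upper-case string
#'   (alphabet A, C, G, T, U, N; T and U are treated as equivalent).
#'
#' @aliases RiboReference-class
#' @exportClass RiboReference
setClass("RiboReference",
  representation(name = "character", sequence = "character"))

setValidity("RiboReference", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@sequence) != 1L)
    msg <- c(msg, "'sequence' must be a single string")
  else {
    if (nchar(object@sequence) == 0L)
      msg <- c(msg, "reference sequence is empty")
    bad <- gsub("[ACGTUN]", "", object@sequence)
    if (nzchar(bad))
      msg <- c(msg, sprintf("invalid characters in sequence: %s",
                            paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Catalogue of named processing intermediates
#'
#' A set of named intervals on the reference, one per pre-rRNA intermediate,
#' mature rRNA, spacer fragment or aberrant species. Categories follow the
#' processing literature: \code{precursor}, \code{mature},
#' \code{spacer-fragment}, \code{aberrant}, \code{extension-series}.
#' Extension-series entries named \code{"<base>+<k>"} must share the start of
#' their base entry and end exactly \code{k} nt downstream of it.
#'
#' @slot ranges named \linkS4class{IRanges} of template intervals (1-based,
#'   inclusive).
#' @slot category character vector parallel to \code{ranges}.
#' @slot refLength length of the reference the coordinates live on.
#'
#' @aliases TemplateSet-class
#' @exportClass TemplateSet
setClass("TemplateSet",
  representation(ranges = "IRanges", category = "character",
                 refLength = "integer"))

.validExtensionSeries <- function(rng, category) {
  msg <- NULL
  idx <- which(category == "extension-series")
  for (i in idx) {
    nm <- names(rng)[i]
    if (!grepl("\\+\\d+$", nm)) {
      msg <- c(msg, sprintf("extension-series entry '%s' is not named '<base>+<k>'", nm))
      next
    }
    k <- as.integer(sub(".*\\+(\\d+)$", "\\1", nm))
    base <- sub("\\+\\d+$", "", nm)
    j <- match(base, names(rng))
    if (is.na(j)) {
      msg <- c(msg, sprintf("extension-series entry '%s' has no base entry '%s'", nm, base))
      next
    }
    if (IRanges::start(rng)[i] != IRanges::start(rng)[j] ||
        IRanges::end(rng)[i] != IRanges::end(rng)[j] + k)
      msg <- c(msg, sprintf(
        "'%s' must share the start of '%s' and end exactly %d nt past it", nm, base, k))
  }
  msg
}

setValidity("TemplateSet", function(object) {
  msg <- NULL
  rng <- object@ranges
  if (length(object@category) != length(rng))
    msg <- c(msg, "'category' must be parallel to 'ranges'")
  if (is.null(names(rng)) || anyNA(names(rng)) || any(!nzchar(names(rng))))
    msg <- c(msg, "all templates must be named")
  else if (anyDuplicated(names(rng)))
    msg <- c(msg, sprintf("duplicate template names: %s",
                          paste(unique(names(rng)[duplicated(names(rng))]), collapse = ", ")))
  if (length(object@refLength) != 1L || is.na(object@refLength) ||
      object@refLength < 1L)
    msg <- c(msg, "'refLength' must be a single positive integer")
  else if (length(rng)) {
    if (any(IRanges::start(rng) < 1L) || any(IRanges::end(rng) > object@refLength))
      msg <- c(msg, "template coordinates outside [1, refLength]")
  }
  if (length(rng) && any(IRanges::width(rng) < 1L))
    msg <- c(msg, "templates with end < start")
  known <- c("precursor", "mature", "spacer-fragment", "aberrant",
             "extension-series")
  if (length(object@category) && !all(object@category %in% known))
    msg <- c(msg, sprintf("unknown categories: %s",
                          paste(setdiff(object@category, known), collapse = ", ")))
  if (is.null(msg))
    msg <- .validExtensionSeries(rng, object@category)
  if (is.null(msg)) TRUE else msg
})

#' Aligned long reads on the single reference
#'
#' Per-read alignment spans plus optional per-read evidence: intra-read
#' deletion spans (from the CIGAR), sparse per-position modification
#' probabilities (decoded from SAM MM/ML base-modification tags) and sparse
#' mismatch basecalls relative to the reference. Only primary forward-strand
#' alignments are kept by \code{\link{readAlignments}}.
#'
#' @slot reads \linkS4class{GRanges} of aligned reference spans (1-based,
#'   closed); \code{mcols(reads)$read_id} holds read identifiers.
#' @slot deletions \linkS4class{IRangesList} of deletion spans per read
#'   (reference coordinates).
#' @slot modPos,modProb parallel \code{IntegerList}/\code{NumericList}:
#'   reference positions with a modification-probability record and the
#'   probabilities in [0, 1].
#' @slot callPos,callBase parallel \code{IntegerList}/\code{CharacterList}:
#'   reference positions where the basecall differs from the reference, and
#'   the called base (A/C/G/U). Positions deleted in the read are tracked in
#'   \code{deletions}, not here.
#' @slot hasBasecalls whether read sequences were available, i.e. whether
#'   mismatch evidence is meaningful.
#' @slot sample,condition,replicate sample annotation.
#' @slot metadata free-form list (the simulator stores its truth table here).
#'
#' @aliases RiboReadSet-class
#' @exportClass RiboReadSet
setClass("RiboReadSet",
  representation(reads = "GRanges", deletions = "CompressedIRangesList",
                 modPos = "CompressedIntegerList",
                 modProb = "CompressedNumericList",
                 callPos = "CompressedIntegerList",
                 callBase = "CompressedCharacterList",
                 hasBasecalls = "logical",
                 sample = "character", condition = "character",
                 replicate = "integer", metadata = "list"))

setValidity("RiboReadSet", function(object) {
  msg <- NULL
  n <- length(object@reads)
  if (is.null(mcols(object@reads)$read_id))
    msg <- c(msg, "reads must carry mcols()$read_id")
  for (sl in c("deletions", "modPos", "modProb", "callPos", "callBase"))
    if (length(slot(object, sl)) != n)
      msg <- c(msg, sprintf("'%s' must be parallel to 'reads'", sl))
  if (is.null(msg) && n) {
    if (!identical(lengths(object@modPos), lengths(object@modProb)))
      msg <- c(msg, "modPos and modProb lengths differ per read")
    if (!identical(lengths(object@callPos), lengths(object@callBase)))
      msg <- c(msg, "callPos and callBase lengths differ per read")
    p <- unlist(object@modProb, use.names = FALSE)
    if (length(p) && (min(p) < 0 || max(p) > 1))
      msg <- c(msg, "modification probabilities outside [0, 1]")
    dl <- unlist(object@deletions, use.names = FALSE)
    if (length(dl)) {
      ridx <- rep(seq_len(n), lengths(object@deletions))
      if (any(IRanges::start(dl) < GenomicRanges::start(object@reads)[ridx]) ||
          any(IRanges::end(dl) > GenomicRanges::end(object@reads)[ridx]))
        msg <- c(msg, "deletion spans outside their read's aligned span")
    }
  }
  if (length(object@replicate) != 1L || is.na(object@replicate) ||
      object@replicate < 1L)
    msg <- c(msg, "'replicate' must be a single integer >= 1")
  if (is.null(msg)) TRUE else msg
})

#' 2D start/end intensity matrix
#'
#' Sparse two-dimensional histogram of reads keyed by (alignment start,
#' alignment end). Conceptually a reference-length squared matrix; only
#' occupied cells are stored. Dense clusters of occupied cells ("hubs") mark
#' abundant RNA species; horizontal/vertical lines of cells trace 5'->3' and
#' 3'->5' exonucleolytic trimming.
#'
#' @slot cells data.frame with columns \code{start}, \code{end},
#'   \code{count}; one row per occupied cell, sorted by (start, end).
#' @slot readIds \code{CharacterList} of read ids per cell.
#' @slot dim the reference length (both matrix dimensions).
#'
#' @aliases IntensityMatrix-class
#' @exportClass IntensityMatrix
setClass("IntensityMatrix",
  representation(cells = "data.frame", readIds = "CompressedCharacterList",
                 dim = "integer"))

setValidity("IntensityMatrix", function(object) {
  msg <- NULL
  cl <- object@cells
  if (!all(c("start", "end", "count") %in% names(cl)))
    msg <- c(msg, "'cells' needs columns start, end, count")
  else if (nrow(cl)) {
    if (any(cl$start > cl$end))
      msg <- c(msg, "cells with start > end")
    if (any(cl$start < 1L) || any(cl$end > object@dim))
      msg <- c(msg, "cell coordinates outside [1, dim]")
    if (any(cl$count < 1L))
      msg <- c(msg, "cells with count < 1")
  }
  if (length(object@readIds) != NROW(cl))
    msg <- c(msg, "'readIds' must be parallel to 'cells'")
  if (length(object@dim) != 1L || is.na(object@dim) || object@dim < 1L)
    msg <- c(msg, "'dim' must be a single positive integer")
  if (is.null(msg)) TRUE else msg
})
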