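#' Construct a RiboReadSet in memory
#'
#' Builds the container directly from vectors, mainly for the simulator and
#' for tests; sequencing data enters via \code{\link{readAlignments}}.
#'
#' @param start,end 1-based inclusive aligned reference spans.
#' @param readId read identifiers (generated if \code{NULL}).
#' @param refLength reference length (stored as the seqlength).
#' @param refname reference name.
#' @param deletions optional \code{IRangesList} of per-read deletion spans.
#' @param modPos,modProb optional lists of per-read modification positions
#'   (reference coordinates) and probabilities.
#' @param callPos,callBase optional lists of per-read mismatch positions and
#'   called bases.
#' @param hasBasecalls whether mismatch evidence is present.
#' @param sample,condition,replicate sample annotation.
#' @param metadata free-form list.
#' @return A \linkS4class{RiboReadSet}.
#' @export
RiboReadSet <- function(start, end, readId = NULL, refLength,
                        refname = "RNA45SN1", deletions = NULL,
                        modPos = NULL, modProb = NULL,
                        callPos = NULL, callBase = NULL,
                        hasBasecalls = FALSE, sample = "", condition = "",
                        replicate = 1L, metadata = list()) {
  n <- length(start)
  stopifnot(length(end) == n)
  if (is.null(readId))
    readId <- sprintf("read_%06d", seq_len(n))
  si <- GenomeInfoDb::Seqinfo(seqnames = refname,
                              seqlengths = as.integer(refLength))
  gr <- GenomicRanges::GRanges(rep(refname, n),
                               IRanges(as.integer(start), as.integer(end)),
                               strand = if (n) "+" else character(0),
                               seqinfo = si)
  mcols(gr)$read_id <- as.character(readId)
  part <- IRanges::PartitioningByEnd(integer(n))
  emptyIL <- function(x, ctor, empty) {
    if (is.null(x)) IRanges::relist(empty, part) else ctor(x)
  }
  new("RiboReadSet", reads = gr,
      deletions = emptyIL(deletions, IRanges::IRangesList, IRanges()),
      modPos = emptyIL(modPos, IntegerList, integer(0)),
      modProb = emptyIL(modProb, NumericList, numeric(0)),
      callPos = emptyIL(callPos, IntegerList, integer(0)),
      callBase = emptyIL(callBase, CharacterList, character(0)),
      hasBasecalls = hasBasecalls,
      sample = sample, condition = condition,
      replicate = as.integer(replicate), metadata = metadata)
}

# per-query-base reference position (NA over insertions/soft clips)
.queryToRefMap <- function(cigar, pos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  qlen <- sum(lens[ops %in% c("M", "=", "X", "I", "S")])
  map <- rep(NA_integer_, qlen)
  q <- 0L; r <- pos
  for (k in seq_along(ops)) {
    op <- ops[k]; ln <- lens[k]
    if (op %in% c("M", "=", "X")) {
      map[q + seq_len(ln)] <- r + seq_len(ln) - 1L
      q <- q + ln; r <- r + ln
    } else if (op %in% c("I", "S")) {
      q <- q + ln
    } else if (op %in% c("D", "N")) {
      r <- r + ln
    }
  }
  map
}

# Decode SAM MM/ML base-modification tags for one forward-strand read.
# MM items look like "T+17802?,0,2;": positions are delta-encoded counts of
# skipped occurrences of the canonical base in SEQ; ML holds one 0..255
# probability byte per recorded position, scaled to [0,1] by v/255.
.decodeModTags <- function(mm, ml, seq, q2r) {
  if (is.null(mm) || is.na(mm) || !nzchar(mm))
    return(list(pos = integer(0), prob = numeric(0)))
  items <- strsplit(sub(";$", "", mm), ";", fixed = TRUE)[[1L]]
  ml <- as.integer(ml)
  chars <- strsplit(seq, "")[[1L]]
  pos <- integer(0); prob <- numeric(0); used <- 0L
  for (it in items) {
    head <- sub(",.*$", "", it)
    base <- substr(head, 1L, 1L)
    if (!grepl("^[ACGTUN][-+]", head))
      stop("malformed MM tag item: ", it)
    deltas <- if (grepl(",", it))
      as.integer(strsplit(sub("^[^,]*,", "", it), ",", fixed = TRUE)[[1L]])
    else integer(0)
    if (length(deltas)) {
      occ <- if (base == "N") seq_along(chars) else which(chars == base)
      idx <- cumsum(deltas + 1L)
      if (any(idx > length(occ)))
        stop("MM tag addresses more '", base, "' bases than present in SEQ")
      qpos <- occ[idx]
      p <- ml[used + seq_along(idx)] / 255
      used <- used + length(idx)
      rpos <- q2r[qpos]
      keep <- !is.na(rpos)
      pos <- c(pos, rpos[keep])
      prob <- c(prob, p[keep])
    }
  }
  o <- order(pos)
  list(pos = pos[o], prob = prob[o])
}

#' Read alignments against the single reference
#'
#' Parses a SAM or BAM file of alignments against the reference, keeping
#' primary forward-strand alignments only (the rRNA template is
#' single-stranded; reverse and secondary/supplementary alignments are
#' counted and reported). Start/end are the aligned reference span
#' (soft-clipped bases do not extend it), deletion spans come from the
#' CIGAR, mismatch basecalls from comparing SEQ to the reference, and
#' MM/ML base-modification tags are decoded into per-position modification
#' probabilities when present.
#'
#' @param path SAM or BAM file.
#' @param ref a \linkS4class{RiboReference}; alignment target names must
#'   match \code{refName(ref)}.
#' @param sample,condition,replicate annotation attached to the result.
#' @return A \linkS4class{RiboReadSet}.
#' @export
readAlignments <- function(path, ref, sample = "", condition = "",
                           replicate = 1L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!refName(ref) %in% names(hdr))
    stop("alignment target(s) [", paste(names(hdr), collapse = ", "),
         "] do not include reference '", refName(ref), "'")
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MM", "ML"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  if (length(res$pos) == 0L) {
    warning("no mapped primary alignments in ", path)
    return(RiboReadSet(integer(0), integer(0), refLength = refLength(ref),
                       refname = refName(ref), sample = sample,
                       condition = condition, replicate = replicate))
  }
  if (any(as.character(res$rname) != refName(ref)))
    stop("alignments against unexpected reference: ",
         paste(setdiff(unique(as.character(res$rname)), refName(ref)),
               collapse = ", "))
  minus <- bitwAnd(res$flag, 16L) > 0L
  if (any(minus))
    message(sum(minus), " reverse-strand alignment(s) excluded")
  keep <- which(!minus)
  pos <- res$pos[keep]
  cigar <- res$cigar[keep]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  dels <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, ops = "D", pos = pos)
  seqs <- res$seq[keep]
  hasSeq <- all(BiocGenerics::width(seqs) > 0L)
  n <- length(keep)
  callPos <- vector("list", n); callBase <- vector("list", n)
  modPos <- vector("list", n); modProb <- vector("list", n)
  mm <- res$tag$MM; ml <- res$tag$ML
  refChars <- strsplit(chartr("U", "T", refSequence(ref)), "")[[1L]]
  layAll <- if (hasSeq)
    strsplit(as.character(GenomicAlignments::sequenceLayer(seqs, cigar)), "")
  seqChars <- if (hasSeq) as.character(seqs)
  for (i in seq_len(n)) {
    j <- keep[i]
    if (hasSeq) {
      lay <- layAll[[i]]
      rpos <- pos[i] + seq_along(lay) - 1L
      mis <- which(lay != "-" & lay != refChars[rpos])
      callPos[[i]] <- rpos[mis]
      callBase[[i]] <- chartr("T", "U", lay[mis])
    }
    if (!is.null(mm) && !is.null(mm[[j]]) && !is.na(mm[[j]])) {
      dec <- .decodeModTags(mm[[j]], ml[[j]], seqChars[i],
                            .queryToRefMap(cigar[i], pos[i]))
      modPos[[i]] <- dec$pos
      modProb[[i]] <- dec$prob
    }
  }
  RiboReadSet(pos, pos + width - 1L, readId = res$qname[keep],
              refLength = refLength(ref), refname = refName(ref),
              deletions = dels, modPos = modPos, modProb = modProb,
              callPos = callPos, callBase = callBase,
              hasBasecalls = hasSeq, sample = sample, condition = condition,
              replicate = replicate)
}

#' Per-position read coverage
#'
#' @param rs a \linkS4class{RiboReadSet}.
#' @return Integer vector of length \code{refLength}; position \code{i}
#'   counts reads whose aligned span contains \code{i}.
#' @export
coverageTrack <- function(rs) {
  L <- GenomeInfoDb::seqlengths(rs@reads)[[1L]]
  if (length(rs@reads) == 0L)
    return(integer(L))
  as.integer(IRanges::coverage(GenomicRanges::ranges(rs@reads), width = L))
}

#' Write a coverage track as bedGraph
#'
#' @param rs a \linkS4class{RiboReadSet}.
#' @param path output bedGraph path.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(rs, path) {
  cov <- coverageTrack(rs)
  L <- length(cov)
  refname <- GenomeInfoDb::seqlevels(rs@reads)[1L]
  rle <- S4Vectors::Rle(cov)
  ends <- cumsum(S4Vectors::runLength(rle))
  starts <- ends - S4Vectors::runLength(rle) + 1L
  tab <- data.frame(chrom = refname, start = starts - 1L, end = ends,
                    value = S4Vectors::runValue(rle))
  tab <- tab[tab$value > 0, , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Detect recurrent large intra-read deletions
#'
#' Aggregates CIGAR deletion spans of at least \code{minLen} nt across
#' reads: spans whose boundaries agree within \code{tolerance} nt are pooled
#' into one event (such events arise e.g. when reverse transcriptase
#' bypasses a stable secondary-structure element, producing a recurrent
#' multi-kilobase deletion in cDNA reads).
#'
#' @param rs a \linkS4class{RiboReadSet}.
#' @param minLen minimum deletion length in nt (>= 1).
#' @param tolerance boundary agreement window in nt (default 20).
#' @return data.frame with columns \code{del_start}, \code{del_end},
#'   \code{length}, \code{supporting_reads}, sorted by support.
#' @export
detectLargeDeletions <- function(rs, minLen = 100L, tolerance = 20L) {
  stopifnot(minLen >= 1L)
  dl <- unlist(rs@deletions, use.names = FALSE)
  empty <- data.frame(del_start = integer(0), del_end = integer(0),
                      length = integer(0), supporting_reads = integer(0))
  if (is.null(dl) || length(dl) == 0L)
    return(empty)
  dl <- dl[IRanges::width(dl) >= minLen]
  if (length(dl) == 0L)
    return(empty)
  s <- IRanges::start(dl); e <- IRanges::end(dl)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cluster <- integer(length(s))
  cur <- 0L; anchorS <- -Inf; anchorE <- -Inf
  for (i in seq_along(s)) {
    if (abs(s[i] - anchorS) <= tolerance && abs(e[i] - anchorE) <= tolerance) {
      cluster[i] <- cur
    } else {
      cur <- cur + 1L
      cluster[i] <- cur
      anchorS <- s[i]; anchorE <- e[i]
    }
  }
  agg <- do.call(rbind, lapply(split(seq_along(s), cluster), function(idx) {
    # modal boundary pair; ties resolved towards the smallest coordinates
    key <- paste(s[idx], e[idx])
    mode <- names(sort(table(key), decreasing = TRUE))[1L]
    kv <- as.integer(strsplit(mode, " ")[[1L]])
    data.frame(del_start = kv[1L], del_end = kv[2L],
               length = kv[2L] - kv[1L] + 1L, supporting_reads = length(idx))
  }))
  agg <- agg[order(-agg$supporting_reads, agg$del_start), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Per-position basecall pileup
#'
#' Counts A/C/G/U basecalls and deletions among reads covering each
#' reference position, from per-read mismatch records (positions without a
#' mismatch or deletion record are counted as the reference base). Used for
#' U-to-C mismatch ratios at pseudouridine candidates.
#'
#' @param rs a \linkS4class{RiboReadSet} with basecall evidence.
#' @param ref the \linkS4class{RiboReference}.
#' @return data.frame with one row per reference position: \code{position},
#'   \code{ref_base}, counts \code{A}/\code{C}/\code{G}/\code{U},
#'   \code{del}, \code{coverage}.
#' @export
mismatchPileup <- function(rs, ref) {
  if (!rs@hasBasecalls)
    stop("no basecalls in this RiboReadSet; supply alignments with SEQ ",
         "(e.g. a SAM/BAM whose records carry the read sequence)")
  L <- refLength(ref)
  cov <- coverageTrack(rs)
  dl <- unlist(rs@deletions, use.names = FALSE)
  del <- if (length(dl)) as.integer(IRanges::coverage(dl, width = L))
         else integer(L)
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "U")))
  mpos <- unlist(rs@callPos, use.names = FALSE)
  mbase <- unlist(rs@callBase, use.names = FALSE)
  if (length(mpos)) {
    tb <- table(factor(mbase, levels = c("A", "C", "G", "U")), mpos)
    posIdx <- as.integer(colnames(tb))
    counts[posIdx, ] <- counts[posIdx, , drop = FALSE] + t(tb)
  }
  refBase <- chartr("T", "U", strsplit(refSequence(ref), "")[[1L]])
  nMis <- rowSums(counts)
  matchN <- cov - del - nMis
  for (b in c("A", "C", "G", "U")) {
    sel <- refBase == b
    counts[sel, b] <- counts[sel, b] + matchN[sel]
  }
  data.frame(position = seq_len(L), ref_base = refBase,
             A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
             G = as.integer(counts[, "G"]), U = as.integer(counts[, "U"]),
             del = del, coverage = cov)
}
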