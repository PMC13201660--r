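# hand-built SAM fixture: 5 records against the toy reference; only the two
# primary forward-strand mapped records should survive ingestion
writeFiveRecordSam <- function(path, ref) {
  sq <- strsplit(chartr("U", "T", refSequence(ref)), "")[[1L]]
  seqAt <- function(s, e) paste(sq[s:e], collapse = "")
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", refName(ref), refLength(ref)),
    sprintf("keep1\t0\t%s\t101\t60\t100M\t*\t0\t0\t%s\t*",
            refName(ref), seqAt(101, 200)),
    sprintf("keep2\t0\t%s\t201\t60\t50M\t*\t0\t0\t%s\t*",
            refName(ref), seqAt(201, 250)),
    sprintf("sec1\t256\t%s\t301\t0\t50M\t*\t0\t0\t*\t*", refName(ref)),
    sprintf("sup1\t2048\t%s\t401\t60\t50M\t*\t0\t0\t*\t*", refName(ref)),
    sprintf("rev1\t16\t%s\t501\t60\t50M\t*\t0\t0\t%s\t*",
            refName(ref), seqAt(501, 550)))
  writeLines(lines, path)
  path
}

test_that("only primary forward-strand alignments are ingested", {
  ref <- tinyRef()
  sam <- withr::local_tempfile(fileext = ".sam")
  writeFiveRecordSam(sam, ref)
  expect_message(rs <- readAlignments(sam, ref), "reverse-strand")
  expect_identical(sort(readIds(rs)), c("keep1", "keep2"))
  expect_identical(GenomicRanges::start(readRanges(rs)), c(101L, 201L))
  expect_identical(GenomicRanges::end(readRanges(rs)), c(200L, 250L))
  expect_identical(totalAligned(rs), 2L)
})

test_that("reference-name mismatch and unmapped-only input are handled", {
  ref <- tinyRef()
  other <- RiboReference("otherref", refSequence(ref))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeFiveRecordSam(sam, ref)
  expect_error(readAlignments(sam, other), "otherref")

  empty <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", refName(ref), refLength(ref))),
             empty)
  expect_warning(rs <- readAlignments(empty, ref), "no mapped")
  expect_identical(totalAligned(rs), 0L)
})

test_that("MM/ML base-modification tags decode to [0,1] probabilities", {
  ref <- tinyRef(uAt = c(105L, 110L, 120L))
  sq <- strsplit(chartr("U", "T", refSequence(ref)), "")[[1L]]
  readSeq <- paste(sq[101:130], collapse = "")
  tcount <- cumsum(strsplit(readSeq, "")[[1L]] == "T")
  # address the T at reference 105 and at 120, skipping the one at 110
  skip <- tcount[120 - 101 + 1] - tcount[105 - 101 + 1] - 1L
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", refName(ref), refLength(ref)),
    sprintf("m1\t0\t%s\t101\t60\t30M\t*\t0\t0\t%s\t*\tMM:Z:T+17802?,%d,%d;\tML:B:C,255,128",
            refName(ref), readSeq, tcount[105 - 101 + 1] - 1L, skip)), sam)
  rs <- readAlignments(sam, ref)
  mp <- modProbs(rs)
  expect_identical(as.integer(mp$pos[[1]]), c(105L, 120L))
  expect_equal(as.numeric(mp$prob[[1]]), c(255, 128) / 255)
  expect_equal(max(mp$prob[[1]]), 1.0)
})

test_that("coverage counts interval membership and conserves read length", {
  rs <- makeReads(c(1L, 3L), c(4L, 7L), refLength = 10L)
  expect_identical(coverageTrack(rs),
                   c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_identical(sum(coverageTrack(rs)),
                   sum(IRanges::width(GenomicRanges::ranges(readRanges(rs)))))
  expect_identical(coverageTrack(makeReads(integer(0), integer(0),
                                           refLength = 10L)),
                   integer(10L))

  # brute-force membership oracle on a random instance
  set.seed(5)
  s <- sample.int(900L, 500L, replace = TRUE)
  e <- s + sample.int(100L, 500L, replace = TRUE)
  rs2 <- makeReads(s, e)
  cov <- coverageTrack(rs2)
  brute <- vapply(seq_len(1000L),
                  function(i) sum(s <= i & e >= i), 1L)
  expect_identical(cov, brute)
})

test_that("recurrent large deletions aggregate by boundary agreement", {
  # 20 reads carrying the same ~1,916-nt deletion
  dels <- replicate(20, IRanges::IRanges(3000L, width = 1916L))
  rs <- makeReads(rep(1000L, 20), rep(6000L, 20), refLength = 13351L,
                  refname = "RNA45SN1", deletions = as.list(dels))
  tab <- detectLargeDeletions(rs, minLen = 100L)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$supporting_reads, 20L)
  expect_identical(tab$length, 1916L)

  # below-threshold deletions are dropped
  rs2 <- makeReads(100L, 500L, refLength = 1000L,
                   deletions = list(IRanges::IRanges(200L, width = 50L)))
  expect_identical(nrow(detectLargeDeletions(rs2, minLen = 100L)), 0L)

  # two populations 50 nt apart with tolerance 10 stay separate
  mk <- function(startDel) IRanges::IRanges(startDel, width = 300L)
  rs3 <- makeReads(rep(10L, 8), rep(900L, 8), refLength = 1000L,
                   deletions = c(replicate(5, mk(200L)),
                                 replicate(3, mk(250L))))
  tab3 <- detectLargeDeletions(rs3, minLen = 100L, tolerance = 10L)
  expect_identical(nrow(tab3), 2L)
  expect_identical(tab3$supporting_reads, c(5L, 3L))

  # support counts are invariant under read order
  set.seed(9)
  perm <- sample(8)
  rs4 <- makeReads(rep(10L, 8)[perm], rep(900L, 8)[perm],
                   refLength = 1000L,
                   deletions = c(replicate(5, mk(200L)),
                                 replicate(3, mk(250L)))[perm])
  expect_identical(detectLargeDeletions(rs4, minLen = 100L, tolerance = 10L),
                   tab3)
})

test_that("mismatch pileup counts calls, deletions and conserves coverage", {
  ref <- tinyRef(uAt = 150L)
  # 10 reads over the U at 150; 3 call C there
  call <- lapply(seq_len(10), function(i)
    if (i <= 3) list(pos = 150L, base = "C") else list(pos = integer(0),
                                                       base = character(0)))
  rs <- makeReads(rep(101L, 10), rep(200L, 10),
                  callPos = lapply(call, `[[`, "pos"),
                  callBase = lapply(call, `[[`, "base"),
                  hasBasecalls = TRUE)
  pu <- mismatchPileup(rs, ref)
  expect_identical(pu$C[150], 3L)
  expect_identical(pu$U[150], 7L)
  expect_identical(pu$coverage[150], 10L)
  # zero-coverage rows are all zero
  expect_true(all(pu[pu$coverage == 0, c("A", "C", "G", "U", "del")] == 0))
  # conservation at every position
  expect_identical(pu$A + pu$C + pu$G + pu$U + pu$del, pu$coverage)

  rs_noseq <- makeReads(1L, 10L)
  expect_error(mismatchPileup(rs_noseq, ref), "no basecalls")
})

test_that("pileup agrees with the samtools-style pileup on a SAM round trip", {
  ref <- tinyRef(uAt = c(150L, 400L))
  ts <- tinyTemplates()
  cfg <- simConfig(seed = 3, nReads = 60,
                   templateProportions = c(matA = 0.5, matB = 0.5),
                   plantedSites = data.frame(position = c(150, 700),
                                             stoichiometry = c(0.6, 0.5)))
  rs <- simulateReads(ts, cfg)
  rs <- simulateModifications(rs, cfg, mismatchCFraction = 0.5)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(rs, ref, sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)
  rt <- readAlignments(sam, ref)
  pu <- mismatchPileup(rt, ref)
  # independent oracle: Rsamtools pileup engine on the same alignments
  orc <- Rsamtools::pileup(bam, pileupParam = Rsamtools::PileupParam(
    distinguish_strands = FALSE, min_base_quality = 0L,
    max_depth = 10000L))
  for (nt in c("A", "C", "G", "T")) {
    o <- orc[orc$nucleotide == nt, ]
    col <- chartr("T", "U", nt)
    expect_identical(pu[[col]][o$pos], o$count, label = nt)
    mismatchElsewhere <- setdiff(which(pu[[col]] > 0 &
                                         pu$ref_base != col), o$pos)
    expect_length(mismatchElsewhere, 0)
  }
})

test_that("SAM round trip preserves spans, deletions and read ids", {
  ref <- tinyRef()
  ts <- tinyTemplates()
  cfg <- simConfig(seed = 21, nReads = 100,
                   templateProportions = c(pre = 0.3, matA = 0.4, matB = 0.3),
                   jitterSd = 3,
                   plantedDeletion = c(position = 620L, length = 120L))
  rs <- simulateReads(ts, cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(rs, ref, sam)
  rt <- readAlignments(sam, ref)
  expect_identical(length(rt), length(rs))
  i <- match(readIds(rt), readIds(rs))
  expect_identical(GenomicRanges::start(readRanges(rs))[i],
                   GenomicRanges::start(readRanges(rt)))
  expect_identical(GenomicRanges::end(readRanges(rs))[i],
                   GenomicRanges::end(readRanges(rt)))
  expect_true(all(as.character(GenomicRanges::strand(readRanges(rt))) == "+"))
  # planted deletion spans survive
  nDel <- sum(lengths(readDeletions(rs)) > 0)
  expect_identical(sum(lengths(readDeletions(rt)) > 0), nDel)
  expect_gt(nDel, 0)
  tab <- detectLargeDeletions(rt, minLen = 100L)
  expect_identical(tab$del_start[1], 620L)
  expect_identical(tab$length[1], 120L)
})
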