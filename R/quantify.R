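#' Minimal reciprocal overlap between two intervals
#'
#' The assignment score of the supervised approach: with overlap
#' \eqn{O} between a read span and a template span, the score is
#' \eqn{\min(O / |read|, O / |template|)} -- the smaller of the two
#' reciprocal overlap fractions, in [0, 1]. It is 1 only for identical
#' intervals and 0 for disjoint ones, and symmetric in its arguments.
#'
#' @param readStart,readEnd,templateStart,templateEnd 1-based inclusive
#'   interval coordinates; vectors are recycled.
#' @return Numeric vector of scores in [0, 1].
#' @examples
#' mro(1, 100, 1, 100)    # 1
#' mro(101, 210, 101, 300)  # 110/200 = 0.55
#' mro(1, 50, 100, 200)   # 0
#' @export
mro <- function(readStart, readEnd, templateStart, templateEnd) {
  if (any(readEnd < readStart) || any(templateEnd < templateStart))
    stop("invalid (empty) interval: end < start")
  ov <- pmax(0L, pmin(readEnd, templateEnd) -
                  pmax(readStart, templateStart) + 1L)
  pmin(ov / (readEnd - readStart + 1L),
       ov / (templateEnd - templateStart + 1L))
}

#' Assign reads to templates by maximal MRO
#'
#' Each read is assigned to the template maximising the minimal reciprocal
#' overlap of its aligned span with the template interval. Ties are broken
#' deterministically: first towards the template whose length is closest to
#' the read's, then towards the lexicographically smallest template name.
#' Reads overlapping no template (MRO 0), or below \code{minMro}, are
#' "unassigned".
#'
#' @param rs a \linkS4class{RiboReadSet}.
#' @param ts a non-empty \linkS4class{TemplateSet}.
#' @param minMro minimum accepted score (default 0: any positive overlap
#'   assigns).
#' @return data.frame with columns \code{read_id}, \code{template},
#'   \code{mro}, \code{start}, \code{end}; one row per read.
#' @export
assignReads <- function(rs, ts, minMro = 0) {
  if (length(ts) == 0L)
    stop("empty TemplateSet")
  # lexicographic (C-locale) column order implements the name tie-break
  nmOrder <- order(templateNames(ts), method = "radix")
  trng <- templateRanges(ts)[nmOrder]
  n <- length(rs)
  rstart <- GenomicRanges::start(rs@reads)
  rend <- GenomicRanges::end(rs@reads)
  out <- data.frame(read_id = readIds(rs),
                    template = rep("unassigned", n),
                    mro = numeric(n), start = rstart, end = rend,
                    stringsAsFactors = FALSE)
  if (n == 0L)
    return(out)
  tstart <- IRanges::start(trng); tend <- IRanges::end(trng)
  twidth <- IRanges::width(trng)
  k <- length(trng)
  scores <- matrix(0, nrow = n, ncol = k)
  for (j in seq_len(k))
    scores[, j] <- mro(rstart, rend, tstart[j], tend[j])
  best <- do.call(pmax, c(as.data.frame(scores), list(0)))
  tie <- scores == best
  lenPenalty <- abs(outer(rend - rstart + 1L, twidth, "-"))
  lenPenalty[!tie] <- Inf
  pick <- max.col(-lenPenalty, ties.method = "first")
  hit <- best > 0 & best >= minMro
  out$template[hit] <- names(trng)[pick[hit]]
  out$mro[hit] <- best[hit]
  out
}

#' Quantify template abundances
#'
#' Turns an assignment table into per-template absolute counts, reads per
#' million aligned reads (RPM) and log10 RPM. Unassigned reads appear as a
#' template of their own so counts sum to the total; RPM uses the full
#' aligned-read total as denominator.
#'
#' @param assignments assignment table from \code{\link{assignReads}}.
#' @param rs the \linkS4class{RiboReadSet} the assignments came from.
#' @param ts optional \linkS4class{TemplateSet}; templates with zero reads
#'   are then reported with count 0.
#' @param pseudocount RPM pseudocount added before taking log10 (default 1,
#'   so species with zero reads stay finite on heatmaps).
#' @return data.frame with columns \code{template}, \code{condition},
#'   \code{replicate}, \code{count}, \code{rpm}, \code{log10_rpm}.
#' @export
quantifyAssignments <- function(assignments, rs, ts = NULL, pseudocount = 1) {
  total <- totalAligned(rs)
  if (total == 0L)
    stop("cannot quantify an empty ReadSet (total aligned reads is 0)")
  lev <- unique(c(if (!is.null(ts)) templateNames(ts),
                  assignments$template, "unassigned"))
  cnt <- table(factor(assignments$template, levels = lev))
  rpm <- as.numeric(cnt) / total * 1e6
  data.frame(template = lev,
             condition = condition(rs), replicate = replicateId(rs),
             count = as.integer(cnt), rpm = rpm,
             log10_rpm = log10(rpm + pseudocount),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise replicate abundances per condition
#'
#' Replicate mean and standard deviation of RPM per template, the layout
#' used for abundance histograms and log10 heatmaps.
#'
#' @param abundance row-bound \code{\link{quantifyAssignments}} tables over
#'   replicates (and possibly conditions).
#' @param pseudocount RPM pseudocount for the log10 of the replicate mean.
#' @param average how to compute the heatmap value: \code{"log10_of_mean"}
#'   (log10 of the replicate-mean RPM, the default) or
#'   \code{"mean_of_log10"}.
#' @return data.frame with columns \code{template}, \code{condition},
#'   \code{mean_rpm}, \code{sd_rpm}, \code{n}, \code{log10_value}.
#' @export
summariseAbundance <- function(abundance, pseudocount = 1,
                               average = c("log10_of_mean",
                                           "mean_of_log10")) {
  average <- match.arg(average)
  sp <- split(abundance, list(abundance$template, abundance$condition),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(template = d$template[1L], condition = d$condition[1L],
               mean_rpm = mean(d$rpm), sd_rpm = stats::sd(d$rpm),
               n = nrow(d),
               log10_value = if (average == "log10_of_mean")
                 log10(mean(d$rpm) + pseudocount)
               else mean(log10(d$rpm + pseudocount)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$template), , drop = FALSE]
}

#' Compare template abundances between two conditions
#'
#' Per-template log2 fold change of mean RPM between two abundance tables
#' (e.g. knockdown vs control), with a two-sided Welch t-test on replicate
#' RPM values and Benjamini-Hochberg adjustment when both conditions have
#' at least two replicates.
#'
#' @param a,b abundance tables from \code{\link{quantifyAssignments}}, each
#'   covering the replicates of one condition; \code{a} is the numerator.
#' @param pseudocount added to both mean RPMs before the ratio (default 0;
#'   if both means are 0 the fold change is reported as 0).
#' @return data.frame with columns \code{template}, \code{mean_rpm_a},
#'   \code{mean_rpm_b}, \code{log2fc}, \code{p_value}, \code{q_value}.
#' @export
compareConditions <- function(a, b, pseudocount = 0) {
  tpl <- union(unique(a$template), unique(b$template))
  getRpm <- function(tab, t) tab$rpm[tab$template == t]
  rows <- lapply(tpl, function(t) {
    ra <- getRpm(a, t); rb <- getRpm(b, t)
    ma <- if (length(ra)) mean(ra) else 0
    mb <- if (length(rb)) mean(rb) else 0
    fc <- if (ma + pseudocount == 0 && mb + pseudocount == 0) 0
          else log2((ma + pseudocount) / (mb + pseudocount))
    p <- NA_real_
    if (length(ra) >= 2L && length(rb) >= 2L &&
        (stats::sd(ra) > 0 || stats::sd(rb) > 0))
      p <- stats::t.test(ra, rb, var.equal = FALSE)$p.value
    else if (identical(ra, rb))
      p <- 1
    data.frame(template = t, mean_rpm_a = ma, mean_rpm_b = mb, log2fc = fc,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Export per-template read BED files
#'
#' One BED6 file per template, rows being the aligned spans of the reads
#' assigned to it (name = read id), for genome-browser inspection; an
#' \code{unassigned.bed} completes the partition. Empty templates yield
#' empty files.
#'
#' @param assignments assignment table from \code{\link{assignReads}}.
#' @param ts the \linkS4class{TemplateSet} used for assignment.
#' @param dir output directory (created if needed).
#' @param refname BED chromosome name.
#' @return Named character vector of written paths, invisibly.
#' @export
exportIntermediateBeds <- function(assignments, ts, dir,
                                   refname = "RNA45SN1") {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  groups <- c(templateNames(ts), "unassigned")
  paths <- character(0)
  for (g in groups) {
    d <- assignments[assignments$template == g, , drop = FALSE]
    safe <- gsub("[^A-Za-z0-9._+-]", "_", g)
    p <- file.path(dir, paste0(safe, ".bed"))
    tab <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
    if (nrow(d))
      tab <- data.frame(chrom = refname, start = d$start - 1L, end = d$end,
                        name = d$read_id, score = 0L, strand = "+")
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[g] <- p
  }
  invisible(paths)
}
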