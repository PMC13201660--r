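#' Site-calling configuration
#'
#' Parameters of the statistical cleavage-site caller: sites must rise at
#' least \code{k} standard deviations above the mean boundary abundance of
#' their template interval, and be reproduced in at least
#' \code{minReplicates} of \code{replicateTotal} biological replicates
#' (default 2 of 3).
#'
#' @param k SD multiplier (default 2).
#' @param minReplicates replicates a site must appear in (default 2).
#' @param replicateTotal number of replicates (default 3).
#' @return list of validated parameters.
#' @export
siteCallConfig <- function(k = 2, minReplicates = 2L, replicateTotal = 3L) {
  stopifnot(k > 0, minReplicates >= 1L, minReplicates <= replicateTotal)
  list(k = k, minReplicates = as.integer(minReplicates),
       replicateTotal = as.integer(replicateTotal))
}

#' Per-position read boundary counts
#'
#' @param rs a \linkS4class{RiboReadSet}.
#' @return list with integer vectors \code{start} and \code{end} over the
#'   reference; \code{start[i]} counts reads starting at i, \code{end[i]}
#'   reads ending at i. Each vector sums to the read count.
#' @export
boundaryCounts <- function(rs) {
  L <- GenomeInfoDb::seqlengths(rs@reads)[[1L]]
  tab <- function(x) tabulate(x, nbins = L)
  list(start = tab(GenomicRanges::start(rs@reads)),
       end = tab(GenomicRanges::end(rs@reads)))
}

#' Call significantly abundant cleavage sites
#'
#' For each template interval, the mean and sample standard deviation of
#' the boundary counts over the interval's positions define a threshold
#' mean + k*SD; a position is called when its count reaches the threshold
#' and the SD is positive (uniform intervals yield no calls). Positions
#' lying in several overlapping template intervals use the mean of the
#' template means and the mean of the template SDs; positions outside
#' every template fall back to a whole-reference baseline. Templates of
#' length 1 are skipped (SD undefined).
#'
#' @param vec per-position boundary count vector (one of the two vectors
#'   from \code{\link{boundaryCounts}}).
#' @param ts a \linkS4class{TemplateSet}.
#' @param cfg a \code{\link{siteCallConfig}}.
#' @param kind label stored with the calls ("start" or "end").
#' @return data.frame of calls: \code{position}, \code{kind}, \code{count},
#'   \code{threshold}, \code{templates} (comma-joined covering templates).
#' @export
significantSites <- function(vec, ts, cfg = siteCallConfig(),
                             kind = "site") {
  L <- refLength(ts)
  if (length(vec) != L)
    stop("count vector length (", length(vec),
         ") does not match the reference length (", L, ")")
  rng <- templateRanges(ts)
  w <- IRanges::width(rng)
  if (any(w < 2L)) {
    warning("skipping length-1 template(s) (SD undefined): ",
            paste(names(rng)[w < 2L], collapse = ", "))
    rng <- rng[w >= 2L]
  }
  tmean <- numeric(length(rng)); tsd <- numeric(length(rng))
  for (j in seq_along(rng)) {
    seg <- vec[IRanges::start(rng)[j]:IRanges::end(rng)[j]]
    tmean[j] <- mean(seg)
    tsd[j] <- stats::sd(seg)
  }
  # per-position pooled baseline: mean of means / mean of SDs over the
  # covering templates
  nCover <- meanSum <- sdSum <- numeric(L)
  for (j in seq_along(rng)) {
    idx <- IRanges::start(rng)[j]:IRanges::end(rng)[j]
    nCover[idx] <- nCover[idx] + 1
    meanSum[idx] <- meanSum[idx] + tmean[j]
    sdSum[idx] <- sdSum[idx] + tsd[j]
  }
  poolMean <- ifelse(nCover > 0, meanSum / pmax(nCover, 1), mean(vec))
  poolSd <- ifelse(nCover > 0, sdSum / pmax(nCover, 1), stats::sd(vec))
  thr <- poolMean + cfg$k * poolSd
  hit <- which(vec >= thr & poolSd > 0 & vec > 0)
  if (length(hit) == 0L)
    return(data.frame(position = integer(0), kind = character(0),
                      count = integer(0), threshold = numeric(0),
                      templates = character(0)))
  covering <- vapply(hit, function(p) {
    j <- which(IRanges::start(rng) <= p & IRanges::end(rng) >= p)
    paste(names(rng)[j], collapse = ",")
  }, "")
  data.frame(position = hit, kind = kind, count = vec[hit],
             threshold = thr[hit], templates = covering,
             stringsAsFactors = FALSE)
}

#' Call cleavage sites from a read set
#'
#' Convenience wrapper: computes boundary counts and calls start- and
#' end-generating sites separately (start and end boundaries are never
#' pooled).
#'
#' @param rs a \linkS4class{RiboReadSet}.
#' @param ts a \linkS4class{TemplateSet}.
#' @param cfg a \code{\link{siteCallConfig}}.
#' @return data.frame of start and end calls (see
#'   \code{\link{significantSites}}).
#' @export
callCleavageSites <- function(rs, ts, cfg = siteCallConfig()) {
  bc <- boundaryCounts(rs)
  rbind(significantSites(bc$start, ts, cfg, kind = "start"),
        significantSites(bc$end, ts, cfg, kind = "end"))
}

#' Replicate consensus of site calls
#'
#' A (position, kind) pair is kept when present in at least
#' \code{cfg$minReplicates} of the supplied replicate call lists.
#'
#' @param callsPerReplicate list of call data.frames, one per biological
#'   replicate (from \code{\link{callCleavageSites}} or
#'   \code{\link{significantSites}}).
#' @param cfg a \code{\link{siteCallConfig}}.
#' @return data.frame: \code{position}, \code{kind}, \code{n_replicates},
#'   \code{mean_count}, \code{counts} (semicolon-joined per-replicate
#'   counts, 0 where absent).
#' @export
replicateConsensus <- function(callsPerReplicate, cfg = siteCallConfig()) {
  nrep <- length(callsPerReplicate)
  if (nrep < cfg$minReplicates)
    stop("need at least ", cfg$minReplicates, " replicate call lists, got ",
         nrep)
  keys <- lapply(callsPerReplicate, function(d) paste(d$position, d$kind))
  all <- unique(unlist(keys))
  if (length(all) == 0L)
    return(data.frame(position = integer(0), kind = character(0),
                      n_replicates = integer(0), mean_count = numeric(0),
                      counts = character(0)))
  present <- vapply(keys, function(k) all %in% k, logical(length(all)))
  present <- matrix(present, nrow = length(all))
  n <- rowSums(present)
  keep <- which(n >= cfg$minReplicates)
  if (length(keep) == 0L)
    return(data.frame(position = integer(0), kind = character(0),
                      n_replicates = integer(0), mean_count = numeric(0),
                      counts = character(0)))
  parts <- strsplit(all[keep], " ")
  pos <- as.integer(vapply(parts, `[[`, "", 1L))
  kind <- vapply(parts, `[[`, "", 2L)
  cnt <- vapply(seq_along(keep), function(i) {
    vapply(callsPerReplicate, function(d) {
      hit <- d$position == pos[i] & d$kind == kind[i]
      if (any(hit)) as.numeric(d$count[hit][1L]) else 0
    }, 1)
  }, numeric(nrep))
  cnt <- matrix(cnt, nrow = nrep)
  out <- data.frame(position = pos, kind = kind,
                    n_replicates = as.integer(n[keep]),
                    mean_count = colMeans(cnt),
                    counts = apply(cnt, 2L, paste, collapse = ";"),
                    stringsAsFactors = FALSE)
  out[order(out$position, out$kind), , drop = FALSE]
}

#' Export site calls as TSV and BED
#'
#' The TSV carries position/kind/count/threshold (round-trippable with
#' \code{\link{readSiteTsv}}); the BED9 colours start sites green and end
#' sites orange for browser display.
#'
#' @param calls call table (from \code{\link{significantSites}} or
#'   \code{\link{callCleavageSites}}).
#' @param tsvPath,bedPath output paths (either may be \code{NULL}).
#' @param refname BED chromosome name.
#' @return Invisibly, the written paths.
#' @export
exportSites <- function(calls, tsvPath = NULL, bedPath = NULL,
                        refname = "RNA45SN1") {
  if (!is.null(tsvPath))
    utils::write.table(calls, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bedPath)) {
    col <- ifelse(calls$kind == "start", "0,128,0", "255,165,0")
    cnt <- if ("count" %in% names(calls)) calls$count else calls$mean_count
    tab <- data.frame(chrom = refname, start = calls$position - 1L,
                      end = calls$position,
                      name = paste0(calls$kind, "_", calls$position),
                      score = as.integer(pmin(1000, round(cnt))),
                      strand = "+", thickStart = calls$position - 1L,
                      thickEnd = calls$position, itemRgb = col)
    utils::write.table(tab, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv = tsvPath, bed = bedPath))
}

#' Read a site-call TSV back
#'
#' @param path TSV written by \code{\link{exportSites}}.
#' @return The call data.frame.
#' @export
readSiteTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
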