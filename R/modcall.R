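#' Modification-calling configuration
#'
#' @param probThreshold per-read probability at or above which a base is
#'   called modified (default 0.95; inclusive).
#' @param minSiteRatio site-level stoichiometry filter (default 0.10;
#'   inclusive): a site must reach this modification ratio in at least one
#'   condition to be retained.
#' @param minCoverage minimum covering reads for a site to be evaluated
#'   without a low-coverage flag (default 30).
#' @return list of validated parameters.
#' @export
modConfig <- function(probThreshold = 0.95, minSiteRatio = 0.10,
                      minCoverage = 30L) {
  stopifnot(probThreshold > 0, probThreshold <= 1,
            minSiteRatio >= 0, minSiteRatio <= 1, minCoverage >= 0)
  list(probThreshold = probThreshold, minSiteRatio = minSiteRatio,
       minCoverage = as.integer(minCoverage))
}

#' Per-position binary modification calls for one read
#'
#' @param probs named (by position) or plain numeric vector of
#'   modification probabilities in [0, 1].
#' @param cfg a \code{\link{modConfig}}.
#' @return Logical vector: modified iff probability >= threshold.
#' @examples
#' callModified(c(`100` = 0.96, `200` = 0.94, `300` = 0.95))
#' @export
callModified <- function(probs, cfg = modConfig()) {
  stopifnot(all(probs >= 0 & probs <= 1))
  probs >= cfg$probThreshold
}

#' Site-level modification stoichiometry
#'
#' For every reference position carrying modification-probability records,
#' computes the modification ratio (reads called modified / covering reads
#' with a probability record) and, at reference-U positions when a pileup
#' is supplied, the U-to-C mismatch ratio (C calls / (coverage -
#' deletions); deleted bases express no identity and are excluded from the
#' denominator). Ratios with an empty denominator are NA, never 0.
#'
#' @param rs a \linkS4class{RiboReadSet} with modification probabilities.
#' @param cfg a \code{\link{modConfig}}.
#' @param pileup optional pileup from \code{\link{mismatchPileup}}.
#' @param positions optional positions to evaluate (defaults to all
#'   positions with a probability record).
#' @return data.frame: \code{position}, \code{mod_ratio},
#'   \code{mismatch_c_ratio}, \code{coverage}, \code{n_prob_reads},
#'   \code{low_coverage}, \code{condition}.
#' @export
siteStoichiometry <- function(rs, cfg = modConfig(), pileup = NULL,
                              positions = NULL) {
  pos <- unlist(rs@modPos, use.names = FALSE)
  prob <- unlist(rs@modProb, use.names = FALSE)
  if (is.null(positions))
    positions <- sort(unique(pos))
  np <- length(positions)
  out <- data.frame(position = positions,
                    mod_ratio = rep(NA_real_, np),
                    mismatch_c_ratio = rep(NA_real_, np),
                    coverage = rep(0L, np), n_prob_reads = rep(0L, np),
                    low_coverage = rep(TRUE, np),
                    condition = rep(condition(rs), np),
                    stringsAsFactors = FALSE)
  if (length(positions) == 0L)
    return(out)
  f <- factor(pos, levels = positions)
  nProb <- as.integer(table(f))
  nMod <- as.integer(tapply(prob >= cfg$probThreshold, f, sum,
                            default = 0L))
  cov <- coverageTrack(rs)
  out$coverage <- cov[positions]
  out$n_prob_reads <- nProb
  out$mod_ratio <- ifelse(nProb > 0, nMod / nProb, NA_real_)
  out$low_coverage <- out$coverage < cfg$minCoverage
  if (!is.null(pileup)) {
    pu <- pileup[match(positions, pileup$position), , drop = FALSE]
    isU <- pu$ref_base == "U"
    denom <- pu$coverage - pu$del
    out$mismatch_c_ratio <- ifelse(isU & denom > 0, pu$C / denom, NA_real_)
  }
  out
}

#' Filter modification sites across conditions
#'
#' Removes sites whose modification ratio stays below the threshold in
#' every condition; a site reaching the threshold in at least one condition
#' is retained (\code{mode = "any"}, the default). With
#' \code{mode = "each"} every condition is filtered independently and a
#' site is retained only where it reaches the threshold. An unmodified
#' (IVT-like) condition therefore contributes no sites of its own.
#'
#' @param stoich row-bound \code{\link{siteStoichiometry}} tables over
#'   conditions (column \code{condition} distinguishes them).
#' @param cfg a \code{\link{modConfig}}.
#' @param mode see above.
#' @return data.frame of retained sites: \code{position},
#'   \code{max_ratio}, \code{n_conditions_passing},
#'   \code{conditions_passing}.
#' @export
filterSites <- function(stoich, cfg = modConfig(),
                        mode = c("any", "each")) {
  mode <- match.arg(mode)
  ok <- !is.na(stoich$mod_ratio) & stoich$mod_ratio >= cfg$minSiteRatio
  if (mode == "each") {
    stoich <- stoich[ok, , drop = FALSE]
    ok <- ok[ok]
  }
  sp <- split(seq_len(nrow(stoich)), stoich$position)
  rows <- lapply(sp, function(idx) {
    pass <- ok[idx]
    if (!any(pass))
      return(NULL)
    data.frame(position = stoich$position[idx[1L]],
               max_ratio = max(stoich$mod_ratio[idx], na.rm = TRUE),
               n_conditions_passing = sum(pass),
               conditions_passing = paste(unique(
                 stoich$condition[idx][pass]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(position = integer(0), max_ratio = numeric(0),
                      n_conditions_passing = integer(0),
                      conditions_passing = character(0)))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precursor-specific modification stoichiometry
#'
#' Computes site stoichiometry separately over the reads assigned to each
#' precursor (supervised assignment), yielding a precursor x site matrix of
#' modification ratios -- the layout of per-precursor pseudouridine
#' heatmaps. Cells where the site lies outside the precursor's interval,
#' or where no assigned read carries a probability record, are NA. A final
#' row \code{"all"} is computed over every read in the set.
#'
#' @param assignments assignment table from \code{\link{assignReads}}.
#' @param rs the assigned \linkS4class{RiboReadSet}.
#' @param cfg a \code{\link{modConfig}}.
#' @param ts optional \linkS4class{TemplateSet}; when given, sites outside
#'   a precursor's interval are masked NA even if stray records exist.
#' @param positions optional site positions (default: all recorded).
#' @return numeric matrix, rownames = precursors (+ "all"), colnames =
#'   site positions.
#' @export
precursorStoichiometry <- function(assignments, rs, cfg = modConfig(),
                                   ts = NULL, positions = NULL) {
  if (is.null(positions))
    positions <- sort(unique(unlist(rs@modPos, use.names = FALSE)))
  tpl <- setdiff(unique(assignments$template), "unassigned")
  idx <- match(assignments$read_id, readIds(rs))
  m <- matrix(NA_real_, nrow = length(tpl) + 1L, ncol = length(positions),
              dimnames = list(c(tpl, "all"), as.character(positions)))
  for (t in tpl) {
    sub <- .subsetReads(rs, idx[assignments$template == t])
    st <- siteStoichiometry(sub, cfg, positions = positions)
    ratio <- st$mod_ratio
    if (!is.null(ts)) {
      rng <- templateRanges(ts)[t]
      outside <- positions < IRanges::start(rng) |
        positions > IRanges::end(rng)
      ratio[outside] <- NA_real_
    }
    m[t, ] <- ratio
  }
  m["all", ] <- siteStoichiometry(rs, cfg, positions = positions)$mod_ratio
  m
}

.subsetReads <- function(rs, i) {
  i <- i[!is.na(i)]
  new("RiboReadSet", reads = rs@reads[i], deletions = rs@deletions[i],
      modPos = rs@modPos[i], modProb = rs@modProb[i],
      callPos = rs@callPos[i], callBase = rs@callBase[i],
      hasBasecalls = rs@hasBasecalls, sample = rs@sample,
      condition = rs@condition, replicate = rs@replicate,
      metadata = rs@metadata)
}

#' Summarise a z-normalised raw-signal window around a locus
#'
#' Consumes a per-read table of z-normalised mean current values at offsets
#' -10..+10 nt around a locus (the output contract of signal-level
#' resquiggling) and summarises each offset across reads by the mean of
#' means and the semi-standard deviations: dispersion computed separately
#' from the values below and above the per-offset mean.
#'
#' @param signalTable data.frame with columns \code{read_id},
#'   \code{offset} (integers in -10..10) and \code{z_mean}.
#' @param locus 1-based reference position the offsets are centred on.
#' @return data.frame with 21 rows: \code{locus}, \code{offset},
#'   \code{mean_of_means}, \code{semi_sd_lower}, \code{semi_sd_upper},
#'   \code{n_reads}.
#' @export
signalWindowSummary <- function(signalTable, locus) {
  need <- c("read_id", "offset", "z_mean")
  if (!all(need %in% names(signalTable)))
    stop("signal table must have columns: ", paste(need, collapse = ", "))
  if (nrow(signalTable) == 0L)
    stop("no reads cover locus ", locus)
  if (any(signalTable$offset < -10L | signalTable$offset > 10L))
    stop("offsets must lie in -10..10")
  offsets <- -10L:10L
  rows <- lapply(offsets, function(o) {
    x <- signalTable$z_mean[signalTable$offset == o]
    if (length(x) == 0L)
      return(data.frame(locus = locus, offset = o,
                        mean_of_means = NA_real_,
                        semi_sd_lower = NA_real_, semi_sd_upper = NA_real_,
                        n_reads = 0L))
    m <- mean(x)
    semi <- function(sel) if (any(sel))
      sqrt(mean((x[sel] - m)^2)) else 0
    data.frame(locus = locus, offset = o, mean_of_means = m,
               semi_sd_lower = semi(x < m), semi_sd_upper = semi(x > m),
               n_reads = length(x))
  })
  do.call(rbind, rows)
}
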