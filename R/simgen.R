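#' Simulation configuration
#'
#' Describes one synthetic sample: how many reads, which template
#' proportions they are drawn from, boundary jitter, exonucleolytic-trail
#' behaviour, uniform background fraction, planted modification sites and
#' an optional planted intra-read deletion. With a fixed seed the whole
#' simulation (including SAM output) is byte-identical.
#'
#' @param seed master RNG seed (integer).
#' @param nReads number of reads to draw.
#' @param templateProportions named fractions over template names; must sum
#'   to 1 (within 1e-9).
#' @param jitterSd SD (nt) of the rounded Gaussian perturbation applied to
#'   both read boundaries (0 = exact template bounds).
#' @param trailProb fraction of reads whose boundary is exonucleolytically
#'   retracted into the template.
#' @param trailDecay geometric decay parameter in (0, 1); retraction length
#'   is geometric with mean trailDecay/(1 - trailDecay), emulating
#'   one-nucleotide-at-a-time trimming.
#' @param trailSide which boundary retracts: \code{"3p"} (end moves
#'   upstream; 3'->5' exonuclease, vertical matrix trails), \code{"5p"}
#'   (start moves downstream; 5'->3', horizontal trails) or \code{"auto"}
#'   (coin flip per read).
#' @param backgroundRate fraction of uniform-random fragments.
#' @param plantedSites data.frame with columns \code{position},
#'   \code{stoichiometry} for \code{\link{simulateModifications}}.
#' @param plantedDeletion optional \code{c(position, length)}: reads
#'   spanning it acquire the deletion.
#' @param conditionFoldChanges named per-template factors for
#'   \code{\link{simulateKnockdown}}.
#' @return Validated list.
#' @export
simConfig <- function(seed = 1L, nReads = 1000L,
                      templateProportions = NULL, jitterSd = 0,
                      trailProb = 0, trailDecay = 0.9,
                      trailSide = c("3p", "5p", "auto"),
                      backgroundRate = 0, plantedSites = NULL,
                      plantedDeletion = NULL,
                      conditionFoldChanges = NULL) {
  trailSide <- match.arg(trailSide)
  if (!is.null(templateProportions)) {
    if (is.null(names(templateProportions)) ||
        any(!nzchar(names(templateProportions))))
      stop("templateProportions must be a named vector")
    if (abs(sum(templateProportions) - 1) > 1e-9)
      stop("template proportions must sum to 1 (got ",
           sum(templateProportions), ")")
  }
  stopifnot(jitterSd >= 0, trailProb >= 0, trailProb <= 1,
            trailDecay > 0, trailDecay < 1,
            backgroundRate >= 0, backgroundRate <= 1)
  if (!is.null(plantedSites)) {
    stopifnot(all(c("position", "stoichiometry") %in% names(plantedSites)))
    if (any(plantedSites$stoichiometry < 0 | plantedSites$stoichiometry > 1))
      stop("planted stoichiometries must lie in [0, 1]")
  }
  list(seed = as.integer(seed), nReads = as.integer(nReads),
       templateProportions = templateProportions, jitterSd = jitterSd,
       trailProb = trailProb, trailDecay = trailDecay,
       trailSide = trailSide, backgroundRate = backgroundRate,
       plantedSites = plantedSites, plantedDeletion = plantedDeletion,
       conditionFoldChanges = conditionFoldChanges)
}

#' Derive a per-replicate seed from the master seed
#'
#' Fixed integer mix keeping results below 2^31 so each replicate is
#' individually reproducible.
#'
#' @param seed master seed.
#' @param i replicate (or stream) index.
#' @return integer seed.
#' @export
mixSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(i) * 104729 + 7) %%
               2147483647)
}

#' Generate a synthetic single-transcript reference
#'
#' A random-sequence stand-in for the 45SN1 primary transcript: same
#' length and coordinate system, synthetic nucleotides. Positions listed
#' in \code{uAt} are forced to T (uridine in the transcript) so that
#' modification sites can be planted on them.
#'
#' @param length reference length (default the 45SN1 length, 13351).
#' @param name reference name.
#' @param seed RNG seed.
#' @param uAt positions forced to T/U.
#' @return A \linkS4class{RiboReference}.
#' @export
syntheticReference <- function(length = 13351L, name = "RNA45SN1",
                               seed = 42L, uAt = integer(0)) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  chars[uAt] <- "T"
  RiboReference(name, paste(chars, collapse = ""))
}

#' Simulate reads from template proportions
#'
#' Each read samples a template by proportion; both boundaries are
#' perturbed by rounded Gaussian jitter (truncated so the span stays
#' valid); a \code{trailProb} fraction of reads has one boundary retracted
#' into the template by a geometric number of nucleotides (emulating
#' progressive exonucleolytic trimming); a \code{backgroundRate} fraction
#' is replaced by uniform random fragments. If \code{plantedDeletion} is
#' set, every read spanning it acquires that deletion. The truth table
#' (read id, source template) is stored in the result's metadata under
#' \code{"truth"}.
#'
#' @param ts a \linkS4class{TemplateSet}.
#' @param cfg a \code{\link{simConfig}} with \code{templateProportions}.
#' @param sample,condition,replicate annotation for the resulting set.
#' @return A \linkS4class{RiboReadSet}.
#' @export
simulateReads <- function(ts, cfg, sample = "sim", condition = "sim",
                          replicate = 1L) {
  props <- cfg$templateProportions
  if (is.null(props))
    stop("simConfig lacks templateProportions")
  missing <- setdiff(names(props), templateNames(ts))
  if (length(missing))
    stop("unknown template(s) in proportions: ",
         paste(missing, collapse = ", "))
  set.seed(cfg$seed)
  L <- refLength(ts)
  n <- cfg$nReads
  rng <- templateRanges(ts)
  tpl <- sample(names(props), n, replace = TRUE, prob = props)
  s <- IRanges::start(rng)[match(tpl, names(rng))]
  e <- IRanges::end(rng)[match(tpl, names(rng))]
  isBg <- stats::runif(n) < cfg$backgroundRate
  if (any(isBg)) {
    nb <- sum(isBg)
    bs <- sample.int(L - 1L, nb, replace = TRUE)
    bw <- pmin(50L + stats::rgeom(nb, 1 / 800), L - bs)
    s[isBg] <- bs
    e[isBg] <- bs + pmax(bw, 1L)
    tpl[isBg] <- "background"
  }
  if (cfg$jitterSd > 0) {
    s <- s + as.integer(round(stats::rnorm(n, 0, cfg$jitterSd)))
    e <- e + as.integer(round(stats::rnorm(n, 0, cfg$jitterSd)))
    s <- pmax(1L, pmin(s, L))
    e <- pmax(1L, pmin(e, L))
    swap <- s > e
    if (any(swap)) {
      tmp <- s[swap]; s[swap] <- e[swap]; e[swap] <- tmp
    }
  }
  if (cfg$trailProb > 0) {
    hasTrail <- stats::runif(n) < cfg$trailProb & !isBg
    ln <- stats::rgeom(n, 1 - cfg$trailDecay)
    side <- switch(cfg$trailSide,
                   "3p" = rep(TRUE, n), "5p" = rep(FALSE, n),
                   "auto" = stats::runif(n) < 0.5)
    retract <- hasTrail & ln > 0L
    threeP <- retract & side
    fiveP <- retract & !side
    e[threeP] <- pmax(s[threeP], e[threeP] - ln[threeP])
    s[fiveP] <- pmin(e[fiveP], s[fiveP] + ln[fiveP])
  }
  dels <- NULL
  if (!is.null(cfg$plantedDeletion)) {
    dp <- as.integer(cfg$plantedDeletion[[1L]])
    dw <- as.integer(cfg$plantedDeletion[[2L]])
    spans <- s <= dp & e >= dp + dw - 1L
    dels <- lapply(spans, function(x)
      if (x) IRanges(dp, width = dw) else IRanges())
  }
  ids <- sprintf("sim_%s_r%d_%06d", sample, replicate, seq_len(n))
  RiboReadSet(s, e, readId = ids, refLength = L, deletions = dels,
              sample = sample, condition = condition,
              replicate = replicate,
              metadata = list(truth = data.frame(read_id = ids,
                                                 template = tpl,
                                                 stringsAsFactors = FALSE)))
}

#' Plant modification stoichiometries into simulated reads
#'
#' At each planted site, every covering read is modified with probability
#' equal to the site's stoichiometry. Modified reads receive a per-read
#' modification probability drawn from a clipped Normal(0.99, 0.02),
#' unmodified reads from a clipped Normal(0.02, 0.02) -- straddling the
#' 0.95 calling threshold the way a well-separated basecaller does. A
#' \code{mismatchCFraction} of the modified reads additionally gets a C
#' basecall at the site, emulating the U-to-C basecalling mismatches that
#' pseudouridine induces.
#'
#' @param rs a \linkS4class{RiboReadSet} from \code{\link{simulateReads}}.
#' @param cfg a \code{\link{simConfig}} with \code{plantedSites}.
#' @param mismatchCFraction fraction of modified reads called C.
#' @return The read set with modification (and possibly mismatch) records;
#'   the per-site truth is appended to metadata under
#'   \code{"planted_sites"}.
#' @export
simulateModifications <- function(rs, cfg, mismatchCFraction = 0) {
  sites <- cfg$plantedSites
  if (is.null(sites) || nrow(sites) == 0L)
    return(rs)
  if (any(sites$stoichiometry < 0 | sites$stoichiometry > 1))
    stop("planted stoichiometries must lie in [0, 1]")
  set.seed(mixSeed(cfg$seed, 313L))
  n <- length(rs)
  s <- GenomicRanges::start(rs@reads)
  e <- GenomicRanges::end(rs@reads)
  modPos <- as.list(rs@modPos); modProb <- as.list(rs@modProb)
  callPos <- as.list(rs@callPos); callBase <- as.list(rs@callBase)
  clip01 <- function(x) pmin(1, pmax(0, x))
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]; st <- sites$stoichiometry[i]
    cover <- which(s <= p & e >= p)
    if (!length(cover))
      next
    isMod <- stats::runif(length(cover)) < st
    prob <- ifelse(isMod,
                   clip01(stats::rnorm(length(cover), 0.99, 0.02)),
                   clip01(stats::rnorm(length(cover), 0.02, 0.02)))
    for (k in seq_along(cover)) {
      j <- cover[k]
      modPos[[j]] <- c(modPos[[j]], p)
      modProb[[j]] <- c(modProb[[j]], prob[k])
    }
    if (mismatchCFraction > 0) {
      asC <- cover[isMod & stats::runif(length(cover)) < mismatchCFraction]
      for (j in asC) {
        callPos[[j]] <- c(callPos[[j]], p)
        callBase[[j]] <- c(callBase[[j]], "C")
      }
    }
  }
  o <- lapply(modPos, order)
  for (j in seq_len(n)) {
    modPos[[j]] <- modPos[[j]][o[[j]]]
    modProb[[j]] <- modProb[[j]][o[[j]]]
  }
  new("RiboReadSet", reads = rs@reads, deletions = rs@deletions,
      modPos = IntegerList(modPos), modProb = NumericList(modProb),
      callPos = IntegerList(callPos), callBase = CharacterList(callBase),
      hasBasecalls = rs@hasBasecalls || mismatchCFraction > 0,
      sample = rs@sample, condition = rs@condition,
      replicate = rs@replicate,
      metadata = c(rs@metadata, list(planted_sites = sites)))
}

#' Simulate a control/knockdown pair with replicates
#'
#' Knockdown proportions are the control proportions multiplied by the
#' per-template fold changes and renormalised; each replicate of each
#' condition gets its own seed derived from the master seed via
#' \code{\link{mixSeed}}.
#'
#' @param ts a \linkS4class{TemplateSet}.
#' @param cfg a \code{\link{simConfig}} (control proportions, master seed).
#' @param foldChanges named per-template factors (names must exist in the
#'   control proportions).
#' @param nReplicates replicates per condition (default 3).
#' @return list with elements \code{control} and \code{knockdown}, each a
#'   list of \linkS4class{RiboReadSet}s.
#' @export
simulateKnockdown <- function(ts, cfg, foldChanges = NULL,
                              nReplicates = 3L) {
  if (is.null(foldChanges))
    foldChanges <- cfg$conditionFoldChanges
  props <- cfg$templateProportions
  unknown <- setdiff(names(foldChanges), names(props))
  if (length(unknown))
    stop("fold-change key(s) not in control proportions: ",
         paste(unknown, collapse = ", "))
  kdProps <- props
  kdProps[names(foldChanges)] <- kdProps[names(foldChanges)] * foldChanges
  kdProps <- kdProps / sum(kdProps)
  one <- function(p, cond, i, stream) {
    c2 <- cfg
    c2$seed <- mixSeed(cfg$seed, stream + i)
    c2$templateProportions <- p
    simulateReads(ts, c2, sample = paste0(cond, "_", i), condition = cond,
                  replicate = i)
  }
  list(control = lapply(seq_len(nReplicates), function(i)
         one(props, "control", i, 0L)),
       knockdown = lapply(seq_len(nReplicates), function(i)
         one(kdProps, "knockdown", i, 1000L)))
}

#' Simulate boundary peaks at processing sites
#'
#' Builds one replicate of a site-recovery experiment: a uniform background
#' of random fragments plus, for each processing site, a stack of reads
#' whose start (for start-generating sites), end (end-generating) or both
#' (in separate reads) sit exactly on the site coordinate -- the boundary
#' signature that cleavage leaves in the data.
#'
#' @param sites processing-site data.frame (see
#'   \code{\link{processingSites}}).
#' @param refLength reference length.
#' @param nPerSite reads per planted boundary (default 40).
#' @param nBackground uniform background fragments (default 400).
#' @param seed RNG seed.
#' @param replicate replicate index stored in the result.
#' @return A \linkS4class{RiboReadSet}.
#' @export
simulateSitePeaks <- function(sites, refLength = 13351L, nPerSite = 40L,
                              nBackground = 400L, seed = 1L,
                              replicate = 1L) {
  set.seed(seed)
  L <- as.integer(refLength)
  s <- integer(0); e <- integer(0)
  # partner boundaries are spread uniformly over the room available on the
  # other side of the site, so only the planted boundary forms a peak
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    side <- sites$side[i]
    if (side %in% c("start-generating", "both")) {
      lo <- min(L, p + 100L)
      s <- c(s, rep(p, nPerSite))
      e <- c(e, lo + sample.int(max(1L, L - lo), nPerSite, replace = TRUE) - 1L)
    }
    if (side %in% c("end-generating", "both")) {
      hi <- max(1L, p - 100L)
      s <- c(s, sample.int(hi, nPerSite, replace = TRUE))
      e <- c(e, rep(p, nPerSite))
    }
  }
  bw <- pmin(100L + sample.int(1900L, nBackground, replace = TRUE),
             L - 1L)
  bs <- 1L + as.integer(floor(stats::runif(nBackground) * (L - bw)))
  s <- c(s, bs)
  e <- c(e, bs + bw)
  RiboReadSet(s, e, refLength = L, sample = paste0("peaks_", replicate),
              condition = "peaks", replicate = replicate)
}

#' Write a RiboReadSet as SAM
#'
#' Emits plain-text SAM (flag 0, MAPQ 60) with CIGARs reconstructed from
#' the aligned span and deletion records, SEQ reconstructed from the
#' reference (mismatch basecalls applied, U written as T) and MM/ML
#' base-modification tags for the recorded modification probabilities.
#' Modification records at positions whose basecall is not T cannot be
#' addressed by the T+ MM delta encoding and are dropped with a note in
#' the tag's own terms (see package vignette).
#'
#' @param rs a \linkS4class{RiboReadSet}.
#' @param ref the \linkS4class{RiboReference} (sequence source).
#' @param path output SAM path.
#' @param modCode modification code used in the MM tag (default 17802,
#'   the pseudouridine ChEBI id).
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(rs, ref, path, modCode = "17802") {
  refChars <- strsplit(chartr("U", "T", refSequence(ref)), "")[[1L]]
  n <- length(rs)
  lines <- character(n + 2L)
  lines[1L] <- "@HD\tVN:1.6\tSO:coordinate"
  lines[2L] <- sprintf("@SQ\tSN:%s\tLN:%d", refName(ref), refLength(ref))
  s <- GenomicRanges::start(rs@reads)
  e <- GenomicRanges::end(rs@reads)
  ids <- readIds(rs)
  ord <- order(s, e, ids)
  for (row in seq_len(n)) {
    i <- ord[row]
    dl <- rs@deletions[[i]]
    dl <- dl[order(IRanges::start(dl))]
    # CIGAR: alternate M segments and D gaps across the aligned span
    bounds_s <- c(s[i], IRanges::end(dl) + 1L)
    bounds_e <- c(IRanges::start(dl) - 1L, e[i])
    mlen <- bounds_e - bounds_s + 1L
    cig <- character(0)
    for (k in seq_along(mlen)) {
      if (mlen[k] > 0L)
        cig <- c(cig, sprintf("%dM", mlen[k]))
      if (k <= length(dl))
        cig <- c(cig, sprintf("%dD", IRanges::width(dl)[k]))
    }
    keepRef <- rep(TRUE, e[i] - s[i] + 1L)
    if (length(dl))
      for (k in seq_along(dl))
        keepRef[(IRanges::start(dl)[k]:IRanges::end(dl)[k]) - s[i] + 1L] <- FALSE
    seqChars <- refChars[s[i]:e[i]]
    cp <- rs@callPos[[i]]; cb <- rs@callBase[[i]]
    if (length(cp))
      seqChars[cp - s[i] + 1L] <- chartr("U", "T", cb)
    seqChars <- seqChars[keepRef]
    tags <- ""
    mp <- rs@modPos[[i]]; pr <- rs@modProb[[i]]
    if (length(mp)) {
      # query position of each modified reference position
      refIdx <- mp - s[i] + 1L
      ok <- keepRef[refIdx]
      qpos <- cumsum(keepRef)[refIdx]
      ok <- ok & seqChars[qpos] == "T"
      if (any(ok)) {
        tIdx <- which(seqChars == "T")
        rank <- match(qpos[ok], tIdx)
        deltas <- diff(c(0L, rank)) - 1L
        tags <- sprintf("\tMM:Z:T+%s?,%s;\tML:B:C,%s", modCode,
                        paste(deltas, collapse = ","),
                        paste(as.integer(round(pr[ok] * 255)),
                              collapse = ","))
      }
    }
    lines[row + 2L] <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*%s",
                               ids[i], refName(ref), s[i],
                               paste(cig, collapse = ""),
                               paste(seqChars, collapse = ""), tags)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Truth table of a simulated read set
#'
#' @param rs a \linkS4class{RiboReadSet} produced by the simulator.
#' @return data.frame mapping read ids to source templates (NULL if the
#'   set carries no truth metadata).
#' @export
simTruth <- function(rs) {
  rs@metadata$truth
}
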