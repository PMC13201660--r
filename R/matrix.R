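#' Build the start/end intensity matrix
#'
#' Embeds every read at the cell given by its (alignment start, alignment
#' end) coordinates; the count of a cell is the number of reads sharing
#' that exact boundary pair. Abundant species form dense "hubs"; one-
#' nucleotide exonucleolytic trimming draws horizontal (5'->3') or vertical
#' (3'->5') lines of occupied cells.
#'
#' @param rs a \linkS4class{RiboReadSet}.
#' @return An \linkS4class{IntensityMatrix}.
#' @export
buildMatrix <- function(rs) {
  L <- GenomeInfoDb::seqlengths(rs@reads)[[1L]]
  s <- GenomicRanges::start(rs@reads)
  e <- GenomicRanges::end(rs@reads)
  if (length(s) == 0L)
    return(new("IntensityMatrix",
               cells = data.frame(start = integer(0), end = integer(0),
                                  count = integer(0)),
               readIds = CharacterList(), dim = as.integer(L)))
  key <- paste(s, e)
  o <- order(s, e)
  ids <- split(readIds(rs)[o], factor(key[o], levels = unique(key[o])))
  first <- !duplicated(key[o])
  cells <- data.frame(start = s[o][first], end = e[o][first],
                      count = as.integer(lengths(ids)))
  rownames(cells) <- NULL
  new("IntensityMatrix", cells = cells,
      readIds = CharacterList(unname(ids)), dim = as.integer(L))
}

#' Detect intensity hubs
#'
#' Clusters occupied matrix cells whose Chebyshev distance is at most
#' \code{mergeRadius} (single linkage) and retains clusters holding at
#' least \code{minReads} reads in total. The hub apex is the modal cell
#' (ties towards the smallest (start, end) pair). When a processing-site
#' table is given, each hub is annotated with the nearest site on each
#' axis and its distance -- reported, not thresholded, since hub
#' coordinates are estimates.
#'
#' @param m an \linkS4class{IntensityMatrix}.
#' @param minReads minimum reads per hub (default 10).
#' @param mergeRadius cell-merge radius in nt (default 3).
#' @param sites optional processing-site data.frame (see
#'   \code{\link{processingSites}}).
#' @return data.frame with one row per hub: \code{hub}, \code{apex_start},
#'   \code{apex_end}, \code{total_reads}, \code{n_cells}, and (if
#'   \code{sites} given) \code{start_site}, \code{start_site_dist},
#'   \code{end_site}, \code{end_site_dist}; ordered by decreasing support.
#'   The member cells of each hub are attached as a list column
#'   \code{cells}.
#' @export
detectHubs <- function(m, minReads = 10L, mergeRadius = 3L, sites = NULL) {
  stopifnot(minReads >= 1L)
  cl <- m@cells
  empty <- data.frame(hub = integer(0), apex_start = integer(0),
                      apex_end = integer(0), total_reads = integer(0),
                      n_cells = integer(0))
  if (nrow(cl) == 0L)
    return(empty)
  # neighbour pairs via a 1D overlap query on the start axis, then the
  # Chebyshev condition on the end axis
  sr <- IRanges(cl$start, cl$start)
  hits <- IRanges::findOverlaps(sr, sr, maxgap = mergeRadius)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- qh < sh & abs(cl$end[qh] - cl$end[sh]) <= mergeRadius
  g <- igraph::graph_from_data_frame(
    data.frame(from = qh[keep], to = sh[keep]), directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(cl))))
  comp <- igraph::components(g)$membership[as.character(seq_len(nrow(cl)))]
  rows <- lapply(split(seq_len(nrow(cl)), comp), function(idx) {
    tot <- sum(cl$count[idx])
    o <- idx[order(-cl$count[idx], cl$start[idx], cl$end[idx])]
    apex <- o[1L]
    data.frame(apex_start = cl$start[apex], apex_end = cl$end[apex],
               total_reads = tot, n_cells = length(idx))
  })
  out <- do.call(rbind, rows)
  members <- split(seq_len(nrow(cl)), comp)
  sel <- out$total_reads >= minReads
  out <- out[sel, , drop = FALSE]
  members <- members[sel]
  if (nrow(out) == 0L)
    return(empty)
  o <- order(-out$total_reads, out$apex_start, out$apex_end)
  out <- out[o, , drop = FALSE]
  members <- members[o]
  out <- cbind(hub = seq_len(nrow(out)), out)
  if (!is.null(sites) && nrow(sites)) {
    near <- function(p) {
      i <- which.min(abs(sites$position - p))
      list(name = sites$name[i], dist = abs(sites$position[i] - p))
    }
    ns <- lapply(out$apex_start, near)
    ne <- lapply(out$apex_end, near)
    out$start_site <- vapply(ns, `[[`, "", "name")
    out$start_site_dist <- vapply(ns, function(x) as.integer(x$dist), 1L)
    out$end_site <- vapply(ne, `[[`, "", "name")
    out$end_site_dist <- vapply(ne, function(x) as.integer(x$dist), 1L)
  }
  out$cells <- lapply(members, function(idx)
    cl[idx, c("start", "end", "count"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Normalise matrix intensities for display
#'
#' Min-max scales occupied-cell counts to [0, 1], then applies contrast
#' enhancement by clipping at the \code{contrastPct}-th and
#' (100 - \code{contrastPct})-th percentiles of the occupied-cell values
#' and rescaling; with \code{contrastPct = 0} this reduces to plain
#' min-max normalisation. Empty cells stay absent (transparent).
#'
#' @param m an \linkS4class{IntensityMatrix}.
#' @param contrastPct symmetric percentile clip in percent (default 2,
#'   in [0, 50)).
#' @return data.frame with columns \code{start}, \code{end}, \code{value}
#'   (values in [0, 1]).
#' @export
renderMatrix <- function(m, contrastPct = 2) {
  stopifnot(contrastPct >= 0, contrastPct < 50)
  cl <- m@cells
  if (nrow(cl) == 0L) {
    warning("empty intensity matrix: nothing to render")
    return(data.frame(start = integer(0), end = integer(0),
                      value = numeric(0)))
  }
  v <- as.numeric(cl$count)
  rng <- range(v)
  v <- if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L])
       else rep(0, length(v))  # constant matrix: degenerate range guard
  if (contrastPct > 0 && rng[2L] > rng[1L]) {
    q <- stats::quantile(v, c(contrastPct, 100 - contrastPct) / 100,
                         names = FALSE)
    if (q[2L] > q[1L])
      v <- (pmin(pmax(v, q[1L]), q[2L]) - q[1L]) / (q[2L] - q[1L])
    else
      v <- as.numeric(v >= q[1L])
  }
  data.frame(start = cl$start, end = cl$end, value = v)
}

#' Overlay intensity matrices from several conditions
#'
#' Renders each matrix (see \code{\link{renderMatrix}}), assigns it a
#' colour, and composites the per-condition channels with screen blending,
#' so regions occupied by a single condition keep its pure colour and
#' shared regions blend.
#'
#' @param matrices named list of \linkS4class{IntensityMatrix} objects
#'   (names become legend labels).
#' @param colors character vector of colours, parallel to \code{matrices}
#'   (e.g. nucleus blue, cytoplasm red).
#' @param contrastPct percentile clip passed to \code{\link{renderMatrix}}.
#' @return data.frame with columns \code{start}, \code{end}, \code{R},
#'   \code{G}, \code{B}, \code{color} (hex); attribute \code{"legend"}
#'   maps labels to colours.
#' @export
overlayMatrices <- function(matrices, colors, contrastPct = 2) {
  stopifnot(length(matrices) == length(colors), length(matrices) >= 1L)
  dims <- vapply(matrices, matrixDim, 1L)
  if (length(unique(dims)) != 1L)
    stop("matrices have mismatching dimensions: ",
         paste(unique(dims), collapse = " vs "))
  layers <- lapply(seq_along(matrices), function(i) {
    r <- renderMatrix(matrices[[i]], contrastPct)
    rgb <- grDevices::col2rgb(colors[i]) / 255
    r$R <- r$value * rgb[1L]; r$G <- r$value * rgb[2L]
    r$B <- r$value * rgb[3L]
    r[c("start", "end", "R", "G", "B")]
  })
  all <- do.call(rbind, layers)
  key <- paste(all$start, all$end)
  screen <- function(x) 1 - tapply(1 - x, key, prod)
  R <- screen(all$R); G <- screen(all$G); B <- screen(all$B)
  first <- !duplicated(key)
  out <- data.frame(start = all$start[first], end = all$end[first])
  k <- paste(out$start, out$end)
  out$R <- as.numeric(R[k]); out$G <- as.numeric(G[k])
  out$B <- as.numeric(B[k])
  out$color <- grDevices::rgb(out$R, out$G, out$B)
  attr(out, "legend") <- stats::setNames(colors, names(matrices))
  out[order(out$start, out$end), , drop = FALSE]
}

#' Plot an intensity matrix or overlay
#'
#' @param x output of \code{\link{renderMatrix}} (plotted in one colour) or
#'   \code{\link{overlayMatrices}} (plotted with its composite colours).
#' @param color fill colour for single-matrix input.
#' @param pointSize tile size in mm.
#' @return A ggplot object (start on x, end on y).
#' @export
plotMatrix <- function(x, color = "blue", pointSize = 0.4) {
  stopifnot(all(c("start", "end") %in% names(x)))
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$start, y = .data$end))
  if ("color" %in% names(x))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$color),
                                 size = pointSize) +
      ggplot2::scale_colour_identity()
  else
    p <- p + ggplot2::geom_point(ggplot2::aes(alpha = .data$value),
                                 colour = color, size = pointSize) +
      ggplot2::scale_alpha_identity()
  p + ggplot2::labs(x = "alignment start (nt)", y = "alignment end (nt)") +
    ggplot2::theme_minimal()
}

#' Extract an exonucleolytic trail profile
#'
#' Reads produced by one-nucleotide exonucleolytic trimming share one
#' boundary and spread along the other; this extracts the corresponding
#' row (\code{fixed_end}: counts over starts in [anchor - span, anchor])
#' or column (\code{fixed_start}: counts over ends in
#' [anchor, anchor + span]) and reports pause positions -- local maxima
#' whose count is at least \code{prominence} times the larger immediate
#' neighbour.
#'
#' @param m an \linkS4class{IntensityMatrix}.
#' @param axis \code{"fixed_end"} (horizontal trail, 5'->3' trimming) or
#'   \code{"fixed_start"} (vertical trail, 3'->5' trimming).
#' @param anchor the fixed boundary coordinate (nt).
#' @param span profile extent along the free axis (nt).
#' @param prominence pause detection factor (default 2).
#' @return list with \code{profile} (data.frame \code{position},
#'   \code{count}) and \code{pauses} (integer positions).
#' @export
extractTrails <- function(m, axis = c("fixed_end", "fixed_start"), anchor,
                          span, prominence = 2) {
  axis <- match.arg(axis)
  stopifnot(anchor >= 1L, anchor <= m@dim)
  cl <- m@cells
  if (axis == "fixed_end") {
    lo <- max(1L, anchor - span); hi <- anchor
    sel <- cl$end == anchor & cl$start >= lo & cl$start <= hi
    pos <- cl$start[sel]
  } else {
    lo <- anchor; hi <- min(m@dim, anchor + span)
    sel <- cl$start == anchor & cl$end >= lo & cl$end <= hi
    pos <- cl$end[sel]
  }
  prof <- data.frame(position = lo:hi, count = 0L)
  prof$count[match(pos, prof$position)] <- cl$count[sel]
  n <- nrow(prof)
  pauses <- integer(0)
  if (n >= 2L) {
    left <- c(0L, prof$count[-n])
    right <- c(prof$count[-1L], 0L)
    nb <- pmax(left, right)
    hit <- prof$count > 0L & prof$count > left & prof$count > right &
      prof$count >= prominence * nb
    pauses <- prof$position[hit]
  }
  list(profile = prof, pauses = pauses)
}

#' Write the intensity matrix as CSV
#'
#' One row per occupied cell with columns \code{start}, \code{end},
#' \code{read_count} and the semicolon-joined \code{read_ids}.
#'
#' @param m an \linkS4class{IntensityMatrix}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixCsv <- function(m, path) {
  tab <- data.frame(start = m@cells$start, end = m@cells$end,
                    read_count = m@cells$count,
                    read_ids = vapply(m@readIds, paste, "", collapse = ";"))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
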