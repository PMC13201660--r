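#' Construct a RiboReference
#'
#' @param name reference name.
#' @param sequence nucleotide string (case-insensitive; A/C/G/T/U/N).
#' @return A \linkS4class{RiboReference}.
#' @export
RiboReference <- function(name, sequence) {
  new("RiboReference", name = as.character(name),
      sequence = toupper(as.character(sequence)))
}

#' Load the single pre-rRNA reference from FASTA
#'
#' The whole package operates on one reference sequence (a 47S/45SN1-like
#' primary transcript), so the FASTA must contain exactly one record.
#'
#' @param path path to a FASTA file with exactly one record.
#' @return A \linkS4class{RiboReference}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">ref", "ACGT"), fa)
#' refLength(loadReference(fa))  # 4
#' @export
loadReference <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 1L)
    stop("expected exactly one reference record, found ", length(seqs))
  RiboReference(sub("\\s.*$", "", names(seqs)), as.character(seqs[[1L]]))
}

#' Construct a TemplateSet
#'
#' @param name,start,end,category parallel vectors describing intermediates
#'   (1-based inclusive coordinates).
#' @param refLength reference length the coordinates refer to.
#' @return A \linkS4class{TemplateSet}.
#' @export
TemplateSet <- function(name, start, end, category, refLength) {
  if (any(end < start))
    stop("templates with end < start: ",
         paste(name[end < start], collapse = ", "))
  rng <- IRanges(start = as.integer(start), end = as.integer(end),
                 names = as.character(name))
  new("TemplateSet", ranges = rng, category = as.character(category),
      refLength = as.integer(refLength))
}

#' Read a template table
#'
#' Parses a TSV of named intermediates with header
#' \code{name<TAB>start<TAB>end<TAB>category} (1-based inclusive
#' coordinates) and validates it against the reference length.
#'
#' @param path TSV file path.
#' @param refLength reference length used for range validation.
#' @return A \linkS4class{TemplateSet}.
#' @seealso \code{\link{defaultTemplates}} for the packaged 45SN1 catalogue.
#' @export
loadTemplateTable <- function(path, refLength) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "category")
  if (!all(need %in% names(tab)))
    stop("template table must have columns: ", paste(need, collapse = ", "))
  bad <- which(tab$end < tab$start)
  if (length(bad))
    stop("template rows with end < start: ",
         paste(sprintf("%s (row %d)", tab$name[bad], bad), collapse = ", "))
  out <- which(tab$start < 1L | tab$end > refLength)
  if (length(out))
    stop("template coordinates outside [1, ", refLength, "]: ",
         paste(tab$name[out], collapse = ", "))
  TemplateSet(tab$name, tab$start, tab$end, tab$category, refLength)
}

#' Write a template table
#'
#' Inverse of \code{\link{loadTemplateTable}}: emits the same TSV schema so
#' that a load/write round trip reproduces the rows.
#'
#' @param ts a \linkS4class{TemplateSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTemplateTable <- function(ts, path) {
  tab <- as.data.frame(ts)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname TemplateSet-class
#' @param row.names,optional passed on (unused).
#' @export
as.data.frame.TemplateSet <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(name = names(x@ranges), start = IRanges::start(x@ranges),
             end = IRanges::end(x@ranges), category = x@category,
             stringsAsFactors = FALSE)
}

#' Packaged 45SN1 template catalogue
#'
#' The literature-derived catalogue of human pre-rRNA intermediates, mature
#' rRNAs, spacer fragments, aberrant species and the 18S-E 3'-extension
#' series (+10/+24/+36/+40/+78), on the 13,351-nt 45SN1 coordinate system.
#' The 21S_S/21S_L isoform end coordinates are provisional (the two ends of
#' the C-site region). Tests pair these coordinates with a synthetic
#' reference sequence of matching length; see \code{\link{syntheticReference}}.
#'
#' @param refLength reference length (defaults to the 45SN1 length, 13351).
#' @return A \linkS4class{TemplateSet}.
#' @export
defaultTemplates <- function(refLength = 13351L) {
  loadTemplateTable(system.file("extdata", "templates_45SN1.tsv",
                                package = "riboslicer", mustWork = TRUE),
                    refLength)
}

#' Packaged catalogue of pre-rRNA processing sites
#'
#' The 13 known human processing sites (01, A0, 1, 3, E, C, 2, B1, 4', 4a,
#' 4, 3', 02) at single-nucleotide 45SN1 coordinates. \code{side} says
#' whether cleavage at the site generates read starts, read ends, or both;
#' \code{provenance} records whether the coordinate refines a literature
#' site. Where the site has multiple reported endpoints (E, 2) the principal
#' coordinate is recorded.
#'
#' @param path optional TSV with columns name/position/side/provenance;
#'   defaults to the packaged catalogue.
#' @param refLength reference length for validation.
#' @return data.frame with columns \code{name}, \code{position},
#'   \code{side}, \code{provenance}.
#' @export
processingSites <- function(path = NULL, refLength = 13351L) {
  if (is.null(path))
    path <- system.file("extdata", "processing_sites_45SN1.tsv",
                        package = "riboslicer", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "position", "side", "provenance")
  if (!all(need %in% names(tab)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate site names")
  if (any(tab$position < 1L | tab$position > refLength))
    stop("site positions outside [1, ", refLength, "]")
  stopifnot(all(tab$side %in% c("start-generating", "end-generating", "both")))
  tab
}

#' Incorporate detected hubs as new templates
#'
#' Promotes intensity-matrix hubs (see \code{\link{detectHubs}}) to
#' first-class templates so the supervised assignment can quantify newly
#' discovered species, mirroring how novel intermediates (e.g. 47S-01-like
#' species) enter the supervised analysis. Hubs below \code{minReads} are
#' ignored; hubs whose apex interval is already present are not duplicated,
#' making the operation idempotent.
#'
#' @param ts a \linkS4class{TemplateSet}.
#' @param hubs hub table from \code{\link{detectHubs}} (columns
#'   \code{apex_start}, \code{apex_end}, \code{total_reads}).
#' @param minReads minimum hub read support for promotion (default 10).
#' @param labels optional character vector of user labels, parallel to
#'   \code{hubs} rows; \code{NA} entries fall back to the automatic
#'   \code{"novel_<start>_<end>"} name.
#' @param category category assigned to new entries.
#' @return A new \linkS4class{TemplateSet}; original entries untouched.
#' @export
extendWithHubs <- function(ts, hubs, minReads = 10L, labels = NULL,
                           category = "precursor") {
  if (NROW(hubs) == 0L)
    return(ts)
  stopifnot(all(c("apex_start", "apex_end", "total_reads") %in% names(hubs)))
  if (any(hubs$apex_start < 1L | hubs$apex_end > ts@refLength))
    stop("hub coordinates outside the reference")
  keep <- hubs$total_reads >= minReads
  hubs <- hubs[keep, , drop = FALSE]
  if (!is.null(labels))
    labels <- labels[keep]
  if (nrow(hubs) == 0L)
    return(ts)
  nm <- sprintf("novel_%d_%d", hubs$apex_start, hubs$apex_end)
  if (!is.null(labels))
    nm[!is.na(labels)] <- labels[!is.na(labels)]
  # drop hubs whose interval (or name) is already catalogued
  old <- paste(IRanges::start(ts@ranges), IRanges::end(ts@ranges))
  fresh <- !(paste(hubs$apex_start, hubs$apex_end) %in% old) &
    !(nm %in% names(ts@ranges)) & !duplicated(paste(hubs$apex_start, hubs$apex_end))
  hubs <- hubs[fresh, , drop = FALSE]
  nm <- nm[fresh]
  if (nrow(hubs) == 0L)
    return(ts)
  old_tab <- as.data.frame(ts)
  TemplateSet(c(old_tab$name, nm), c(old_tab$start, hubs$apex_start),
              c(old_tab$end, hubs$apex_end),
              c(old_tab$category, rep(category, nrow(hubs))), ts@refLength)
}

#' Export templates or sites as BED
#'
#' Writes BED6 (0-based half-open, per the BED standard) for visualisation
#' in genome browsers.
#'
#' @param ts a \linkS4class{TemplateSet}.
#' @param path output BED path.
#' @param refname reference name used as the BED chromosome.
#' @return \code{path}, invisibly.
#' @export
exportTemplateBed <- function(ts, path, refname = "RNA45SN1") {
  gr <- GenomicRanges::GRanges(refname, ts@ranges, strand = "+")
  names(gr) <- names(ts@ranges)
  gr$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}
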