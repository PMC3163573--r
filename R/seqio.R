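#' Read sequences from FASTA, GenBank or EMBL
#'
#' Returns one record per entry, in file order, as a
#' \code{\link[Biostrings]{BStringSet}} whose names are the full headers
#' ("id description"). For GenBank/EMBL flat files the ORIGIN/SQ sequence is
#' extracted verbatim and uppercased; FASTA residues are preserved as read.
#'
#' @param path path to the sequence file.
#' @param format one of \code{"fasta"}, \code{"genbank"}, \code{"embl"}.
#' @return A \code{BStringSet}; use \code{\link{seqIds}} and
#'   \code{\link{seqDescriptions}} to split the headers.
#' @export
readSequences <- function(path, format = c("fasta", "genbank", "embl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  recs <- switch(format,
    fasta = Biostrings::readBStringSet(path),
    genbank = flatfileToStringSet(parseFlatFile(path, "genbank")),
    embl = flatfileToStringSet(parseFlatFile(path, "embl"))
  )
  if (length(recs) == 0L)
    stop("zero records in '", path, "'")
  if (any(Biostrings::width(recs) == 0L))
    stop("empty sequence record in '", path, "'")
  recs
}

flatfileToStringSet <- function(records) {
  if (length(records) == 0L)
    return(Biostrings::BStringSet(character(0)))
  seqs <- vapply(records, function(r) r$sequence, character(1))
  hdr <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- hdr
  x
}

#' Sequence ids and descriptions from header lines
#'
#' The id is the first whitespace-delimited word of the header; the
#' description is the remainder (possibly empty).
#'
#' @param x a \code{BStringSet} as returned by \code{\link{readSequences}}.
#' @return character vector, one element per record.
#' @export
seqIds <- function(x) {
  sub("\\s.*$", "", names(x))
}

#' @rdname seqIds
#' @export
seqDescriptions <- function(x) {
  d <- sub("^\\S+\\s*", "", names(x))
  d[is.na(d)] <- ""
  d
}

#' Write records as multi-FASTA
#'
#' Headers are \code{>id description} (description omitted when empty);
#' sequence lines wrap at 70 columns. Round trip through
#' \code{\link{readSequences}} reproduces ids and residues exactly.
#'
#' @param records a \code{BStringSet} (or named character vector).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(records, path) {
  if (is.character(records)) {
    records <- Biostrings::BStringSet(records)
  }
  if (length(records) == 0L) stop("no records to write")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(records, path, width = 70L)
  invisible(path)
}

#' Build the concatenated reference coordinate system
#'
#' Segments are laid out in input order with cumulative 0-based offsets; the
#' total length is the sum of the record lengths. This is the coordinate
#' system every ring, track and annotation is expressed in.
#'
#' @param records a \code{BStringSet} of reference sequences.
#' @param circular whether the concatenated coordinates wrap (default TRUE
#'   for a single complete sequence, FALSE for multi-segment panels).
#' @return A \linkS4class{ReferenceMap}.
#' @export
buildReferenceMap <- function(records, circular = length(records) == 1L) {
  if (length(records) == 0L) stop("at least one record required")
  len <- as.numeric(Biostrings::width(records))
  seg <- data.frame(
    name = seqIds(records),
    offset = cumsum(c(0, len))[seq_along(len)],
    length = len,
    stringsAsFactors = FALSE
  )
  new("ReferenceMap", segments = seg, totalLength = sum(len),
      circular = isTRUE(circular))
}

#' Annotations from segment headers
#'
#' One annotation per reference segment, spanning the segment and labelled
#' with its name, placed outside the rings — the standard way to label a
#' concatenated gene-panel reference with its FASTA headers.
#'
#' @param refmap a \linkS4class{ReferenceMap}.
#' @return data.frame of annotations (start, end, label, color, decoration,
#'   placement), 0-based half-open.
#' @export
headerAnnotations <- function(refmap) {
  seg <- refSegments(refmap)
  data.frame(
    start = seg$offset,
    end = seg$offset + seg$length,
    label = seg$name,
    color = "#000000",
    decoration = "arc",
    placement = "outside",
    stringsAsFactors = FALSE
  )
}

#' Extract matching features from a GenBank/EMBL file as annotations
#'
#' Selects every feature of the given key whose concatenated qualifier values
#' contain \code{qualifierSubstring} (case-sensitive; the empty string matches
#' everything). Coordinates convert from the flat-file 1-based inclusive
#' convention to 0-based half-open; compound (join/complement) locations are
#' flattened to their outer span, with strand kept only as the arrow
#' decoration. In multi-record files coordinates are offset by the
#' concatenated position of each record, mirroring multi-FASTA references.
#'
#' @param path GenBank or EMBL flat file.
#' @param featureKey feature table key to select (e.g. \code{"misc_feature"},
#'   \code{"CDS"}).
#' @param qualifierSubstring substring that must occur in the feature's
#'   qualifier values.
#' @param format \code{"genbank"} or \code{"embl"}.
#' @param color annotation fill color.
#' @param placement \code{"outside"} or \code{"inside"}.
#' @return data.frame of annotations, 0-based half-open.
#' @export
extractAnnotations <- function(path, featureKey, qualifierSubstring = "",
                               format = c("genbank", "embl"),
                               color = "#000080", placement = "outside") {
  format <- match.arg(format)
  if (!nzchar(featureKey)) stop("featureKey must be non-empty")
  records <- parseFlatFile(path, format)
  out <- list()
  offset <- 0
  for (r in records) {
    for (f in r$features) {
      if (f$key != featureKey) next
      quals <- paste(unlist(f$qualifiers), collapse = " ")
      if (nzchar(qualifierSubstring) &&
          !grepl(qualifierSubstring, quals, fixed = TRUE)) next
      lab <- if (!is.null(f$qualifiers$label)) f$qualifiers$label
             else if (!is.null(f$qualifiers$gene)) f$qualifiers$gene
             else if (!is.null(f$qualifiers$note)) f$qualifiers$note
             else ""
      out[[length(out) + 1L]] <- data.frame(
        start = offset + f$start - 1,          # 1-based inclusive -> 0-based
        end = offset + f$end,
        label = lab,
        color = color,
        decoration = if (f$complement) "arrow_ccw" else "arrow_cw",
        placement = placement,
        stringsAsFactors = FALSE
      )
    }
    offset <- offset + nchar(r$sequence)
  }
  if (length(out) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), color = character(0),
                      decoration = character(0), placement = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a custom annotation table
#'
#' Tab-delimited with columns start, end (1-based inclusive), label, and
#' optionally color, decoration, placement. Converted to the internal
#' 0-based half-open convention.
#'
#' @param path annotation table path.
#' @return data.frame of annotations.
#' @export
readAnnotationTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           fill = TRUE)
  if (ncol(tab) < 3L) stop("annotation table needs >= 3 columns")
  data.frame(
    start = as.numeric(tab[[1]]) - 1,
    end = as.numeric(tab[[2]]),
    label = as.character(tab[[3]]),
    color = if (ncol(tab) >= 4L && any(nzchar(tab[[4]]))) tab[[4]] else "#000080",
    decoration = if (ncol(tab) >= 5L && any(nzchar(tab[[5]]))) tab[[5]] else "arc",
    placement = if (ncol(tab) >= 6L && any(nzchar(tab[[6]]))) tab[[6]] else "outside",
    stringsAsFactors = FALSE
  )
}
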