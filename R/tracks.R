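asSequenceString <- function(seq) {
  if (methods::is(seq, "XStringSet")) {
    if (length(seq) != 1L)
      stop("expected a single sequence; got ", length(seq))
    return(as.character(seq[[1L]]))
  }
  if (methods::is(seq, "XString")) return(as.character(seq))
  if (is.character(seq) && length(seq) == 1L) return(seq)
  stop("seq must be a single sequence (character or Biostrings object)")
}

# Window starts for sliding-window statistics: every multiple of step below
# L; for linear sequences only starts with a full window are kept.
windowStarts <- function(L, window, step, circular) {
  if (step < 1 || step > window) stop("need 1 <= step <= window")
  if (window > L && !circular)
    stop("window (", window, ") exceeds sequence length (", L,
         ") on a non-circular sequence")
  starts <- seq(0, L - 1, by = step)
  if (!circular) starts <- starts[starts + window <= L]
  starts
}

# Shared sliding-window ratio machinery: numerator/denominator indicator
# vectors, windowed via cumulative sums, with circular wrap.
slidingRatio <- function(chars, starts, window, L, num, den) {
  if (any(starts + window > L)) {        # circular: extend by wrap
    ext <- c(chars, chars[seq_len(min(window - 1, L))])
  } else ext <- chars
  cnum <- cumsum(c(0, as.numeric(ext %in% num)))
  cden <- cumsum(c(0, as.numeric(ext %in% den)))
  n <- cnum[starts + window + 1] - cnum[starts + 1]
  d <- cden[starts + window + 1] - cden[starts + 1]
  ifelse(d == 0, 0, n / d)
}

#' GC content in sliding windows
#'
#' Fraction (G+C)/(A+C+G+T) per window; windows start at 0, step, 2*step...
#' Counting is case-insensitive; ambiguity codes and other non-ACGT
#' characters are excluded from both numerator and denominator, and an
#' all-ambiguous window takes value 0. On circular sequences windows wrap
#' past the end.
#'
#' @param seq a single sequence (character or Biostrings object).
#' @param window window size in bp.
#' @param step step between window starts in bp (default: \code{window},
#'   i.e. non-overlapping windows).
#' @param circular whether windows wrap around the origin.
#' @return A \linkS4class{ValueTrack} with one bin per window.
#' @export
gcContent <- function(seq, window = 10000, step = window, circular = FALSE) {
  s <- toupper(asSequenceString(seq))
  L <- nchar(s)
  starts <- windowStarts(L, window, step, circular)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  vals <- slidingRatio(chars, starts, window, L,
                       num = c("G", "C"), den = c("A", "C", "G", "T"))
  ValueTrack(data.frame(start = starts, end = pmin(starts + window, L),
                        value = vals), L)
}

#' GC skew in sliding windows
#'
#' (G - C)/(G + C) per window, the standard replication-strand skew whose
#' sign changes often mark the origin and terminus of replication in
#' prokaryote chromosomes. Windows with no G or C take value 0.
#'
#' @inheritParams gcContent
#' @return A \linkS4class{ValueTrack}.
#' @export
gcSkew <- function(seq, window = 10000, step = window, circular = FALSE) {
  s <- toupper(asSequenceString(seq))
  L <- nchar(s)
  starts <- windowStarts(L, window, step, circular)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (any(starts + window > L)) {
    ext <- c(chars, chars[seq_len(min(window - 1, L))])
  } else ext <- chars
  cg <- cumsum(c(0, as.numeric(ext == "G")))
  cc <- cumsum(c(0, as.numeric(ext == "C")))
  g <- cg[starts + window + 1] - cg[starts + 1]
  cn <- cc[starts + window + 1] - cc[starts + 1]
  vals <- ifelse(g + cn == 0, 0, (g - cn) / (g + cn))
  ValueTrack(data.frame(start = starts, end = pmin(starts + window, L),
                        value = vals), L)
}

#' Center a track on its mean
#'
#' Subtracts the length-weighted mean from every bin, the default graphing
#' transform: the resulting track has mean 0 and plots as signed deviation
#' around the ring midline.
#'
#' @param track a \linkS4class{ValueTrack}.
#' @return A \linkS4class{ValueTrack} with mean 0.
#' @export
skewFromMean <- function(track) {
  b <- trackBins(track)
  if (nrow(b) == 0L) stop("empty track")
  b$value <- b$value - lengthWeightedMean(b)
  ValueTrack(b, trackLength(track))
}

#' Scale a track between zero and a user-defined maximum
#'
#' Values are clamped to [0, userMax] and divided by userMax, giving renderer
#' heights in [0, 1]; negative values clamp to 0 and values above the
#' maximum saturate at 1.
#'
#' @param track a \linkS4class{ValueTrack}.
#' @param userMax positive scaling maximum (same units as the track values).
#' @return A \linkS4class{ValueTrack} with values in [0, 1].
#' @export
scaleZeroToMax <- function(track, userMax) {
  if (!is.numeric(userMax) || length(userMax) != 1L || userMax <= 0)
    stop("userMax must be a positive number")
  b <- trackBins(track)
  b$value <- pmin(pmax(b$value, 0), userMax) / userMax
  ValueTrack(b, trackLength(track))
}

#' Read a custom graph file
#'
#' Two space/tab-delimited dialects are accepted and auto-detected by column
#' count: three columns give 1-based inclusive (start, stop, value) regions;
#' one column gives a value for every base pair, one value per line, in
#' which case the line count must equal the reference length.
#'
#' @param path graph file path.
#' @param referenceLength reference length in bp.
#' @return A \linkS4class{ValueTrack}.
#' @export
readGraphFile <- function(path, referenceLength) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop("graph file '", path, "' has no data lines")
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L)
    stop("graph file '", path, "' mixes column counts: ",
         paste(ncols, collapse = ", "))
  if (ncols == 3L) {
    m <- do.call(rbind, fields)
    bins <- suppressWarnings(
      data.frame(start = as.numeric(m[, 1]) - 1,
                 end = as.numeric(m[, 2]),
                 value = as.numeric(m[, 3])))
    if (anyNA(bins)) stop("non-numeric value in graph file '", path, "'")
    if (any(bins$start < 0) || any(bins$end > referenceLength))
      stop("graph region outside [1, ", referenceLength, "] in '", path, "'")
    ValueTrack(bins, referenceLength)
  } else if (ncols == 1L) {
    v <- suppressWarnings(as.numeric(unlist(fields)))
    if (anyNA(v)) stop("non-numeric value in graph file '", path, "'")
    if (length(v) != referenceLength)
      stop("per-base graph file '", path, "' has ", length(v),
           " values but the reference is ", referenceLength, " bp")
    ValueTrack(compactRuns(v), referenceLength)
  } else {
    stop("graph file '", path, "' must have 1 or 3 columns, found ", ncols)
  }
}

## SAM coverage ---------------------------------------------------------

parseCigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (length(ops) == 0L || nchar(paste(ops, collapse = "")) != nchar(cigar))
    stop("malformed CIGAR '", cigar, "'")
  list(len = as.integer(sub("[A-Z=]", "", ops)),
       op = substring(ops, nchar(ops), nchar(ops)))
}

#' Per-base read coverage from a SAM file
#'
#' Counts, at every reference position, the reads whose alignment covers it:
#' CIGAR operations M, = and X consume reference and count as coverage; D
#' and N consume reference without counting; I/S/H/P consume none. Unmapped
#' (0x4), secondary (0x100) and supplementary (0x800) records are ignored.
#' Multi-segment references are concatenated through \code{refmap}; when
#' \code{refmap} is NULL the \code{@SQ} header lines define it.
#'
#' @param path plain-text SAM path.
#' @param refmap optional \linkS4class{ReferenceMap} giving segment offsets.
#' @return A \linkS4class{ValueTrack} of per-base coverage, run-length
#'   compacted.
#' @export
coverageFromSam <- function(path, refmap = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  recs <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (is.null(refmap)) {
    sq <- hdr[startsWith(hdr, "@SQ")]
    if (length(sq) == 0L)
      stop("SAM file has no @SQ header and no refmap was supplied")
    sn <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
    ln <- as.numeric(sub("^.*\tLN:([0-9]+).*$", "\\1", sq))
    seg <- data.frame(name = sn, offset = cumsum(c(0, ln))[seq_along(ln)],
                      length = ln, stringsAsFactors = FALSE)
    refmap <- new("ReferenceMap", segments = seg, totalLength = sum(ln),
                  circular = length(ln) == 1L)
  }
  seg <- refSegments(refmap)
  offsets <- stats::setNames(seg$offset, seg$name)
  seglen <- stats::setNames(seg$length, seg$name)
  L <- refLength(refmap)
  cov <- integer(L)
  for (line in recs) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("malformed SAM record: ", substr(line, 1, 60))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x4L) != 0L || bitwAnd(flag, 0x100L) != 0L ||
        bitwAnd(flag, 0x800L) != 0L) next
    rname <- f[3]
    if (identical(rname, "*")) next
    if (!rname %in% names(offsets))
      stop("SAM record '", f[1], "' maps to unknown reference '", rname, "'")
    pos <- as.integer(f[4])
    cig <- parseCigar(f[6])
    p <- offsets[[rname]] + pos - 1L          # 0-based within concatenation
    segEnd <- offsets[[rname]] + seglen[[rname]]
    for (i in seq_along(cig$op)) {
      op <- cig$op[i]; n <- cig$len[i]
      if (op %in% c("M", "=", "X")) {
        if (p + n > segEnd)
          stop("read '", f[1], "' extends past the end of reference '",
               rname, "'")
        cov[(p + 1L):(p + n)] <- cov[(p + 1L):(p + n)] + 1L
        p <- p + n
      } else if (op %in% c("D", "N")) {
        p <- p + n
      }
    }
  }
  ValueTrack(compactRuns(as.numeric(cov)), L)
}

## ACE coverage ---------------------------------------------------------

#' Per-contig read coverage from an ACE assembly file
#'
#' Parses CO (padded contig consensus), AF (read placements in padded contig
#' coordinates) and RD (padded read) sections of Consed/Phrap or GS De Novo
#' Assembler ACE files. Coverage is accumulated on padded coordinates — a
#' position is covered by every read whose padded placement spans it — and
#' then depadded by dropping consensus pad ('*') columns, so tracks are in
#' ungapped contig coordinates.
#'
#' @param path ACE file path.
#' @return list with \code{tracks} (named list of \linkS4class{ValueTrack},
#'   one per contig, in file order) and \code{contigs} (data.frame of contig
#'   name and depadded length).
#' @export
coverageFromAce <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  contigs <- list()
  readLens <- list()       # padded read lengths by read name
  placements <- list()     # per contig: data.frame(read, start)
  cur <- NULL
  i <- 1L
  readSeqBlock <- function(i) {
    block <- character(0)
    while (i <= length(lines) && nzchar(trimws(lines[i])) &&
           !grepl("^(CO|AF|RD|BQ|QA|DS|BS|WA|CT|RT)( |$)", lines[i])) {
      block <- c(block, trimws(lines[i])); i <- i + 1L
    }
    list(seq = paste(block, collapse = ""), nxt = i)
  }
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^CO ", ln)) {
      m <- strsplit(trimws(ln), "\\s+")[[1L]]
      blk <- readSeqBlock(i + 1L)
      cur <- m[2]
      contigs[[cur]] <- blk$seq
      placements[[cur]] <- data.frame(read = character(0), start = integer(0),
                                      stringsAsFactors = FALSE)
      i <- blk$nxt
    } else if (grepl("^AF ", ln)) {
      if (is.null(cur)) stop("AF section before any CO section")
      m <- strsplit(trimws(ln), "\\s+")[[1L]]
      placements[[cur]] <- rbind(placements[[cur]],
        data.frame(read = m[2], start = as.integer(m[4]),
                   stringsAsFactors = FALSE))
      i <- i + 1L
    } else if (grepl("^RD ", ln)) {
      m <- strsplit(trimws(ln), "\\s+")[[1L]]
      blk <- readSeqBlock(i + 1L)
      readLens[[m[2]]] <- nchar(blk$seq)
      i <- blk$nxt
    } else {
      i <- i + 1L
    }
  }
  if (length(contigs) == 0L) stop("no CO (contig) sections in '", path, "'")
  tracks <- list()
  info <- data.frame(name = character(0), length = numeric(0),
                     stringsAsFactors = FALSE)
  for (cname in names(contigs)) {
    cons <- contigs[[cname]]
    padLen <- nchar(cons)
    cov <- integer(padLen)
    pl <- placements[[cname]]
    for (j in seq_len(nrow(pl))) {
      rname <- pl$read[j]
      if (is.null(readLens[[rname]]))
        stop("AF placement of read '", rname, "' has no matching RD section")
      s <- pl$start[j]
      e <- s + readLens[[rname]] - 1L
      s <- max(s, 1L); e <- min(e, padLen)
      if (e >= s) cov[s:e] <- cov[s:e] + 1L
    }
    pads <- strsplit(cons, "", fixed = TRUE)[[1L]] == "*"
    depadded <- as.numeric(cov[!pads])
    tracks[[cname]] <- ValueTrack(compactRuns(depadded), length(depadded))
    info <- rbind(info, data.frame(name = cname, length = length(depadded),
                                   stringsAsFactors = FALSE))
  }
  list(tracks = tracks, contigs = info)
}

#' Contig-boundary segments for a draft reference
#'
#' One segment per contig of the concatenated reference, with alternating
#' color indices (0, 1, 0, ...) for the customary alternating red/blue
#' contig-boundary ring of draft assemblies.
#'
#' @param refmap a \linkS4class{ReferenceMap}.
#' @return data.frame with columns start, end, name, colorIndex; segments
#'   tile [0, totalLength).
#' @export
contigBoundaries <- function(refmap) {
  seg <- refSegments(refmap)
  data.frame(
    start = seg$offset,
    end = seg$offset + seg$length,
    name = seg$name,
    colorIndex = (seq_len(nrow(seg)) - 1L) %% 2L,
    stringsAsFactors = FALSE
  )
}

## Track remapping across assembly reorderings --------------------------

#' Interval mapping from a BLAST comparison
#'
#' After contigs of a draft genome are reordered, coverage computed on the
#' original assembly must be repositioned onto the reordered sequence. A
#' blastn run of the original assembly (query) against the reordered
#' reference (subject) yields one mapping entry per hit: the oriented query
#' interval maps to the oriented subject interval, orientation -1 when
#' exactly one of the two coordinate pairs is inverted, and both spans are
#' truncated (from their starts) to the shorter length so every entry is a
#' 1:1 base mapping. Scores carry the bitscore for conflict resolution.
#'
#' @param hits hit data.frame from \code{\link{parseBlastTabular}}.
#' @return data.frame with columns oldStart, oldEnd, newStart, newEnd,
#'   orientation, score; intervals 0-based half-open.
#' @export
mappingFromBlast <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(oldStart = numeric(0), oldEnd = numeric(0),
                      newStart = numeric(0), newEnd = numeric(0),
                      orientation = numeric(0), score = numeric(0)))
  qs <- pmin(hits$qstart, hits$qend) - 1
  qe <- pmax(hits$qstart, hits$qend)
  ss <- pmin(hits$sstart, hits$send) - 1
  se <- pmax(hits$sstart, hits$send)
  span <- pmin(qe - qs, se - ss)
  data.frame(
    oldStart = qs, oldEnd = qs + span,
    newStart = ss, newEnd = ss + span,
    orientation = ifelse(xor(hits$sstart > hits$send,
                             hits$qstart > hits$qend), -1, 1),
    score = hits$bitscore
  )
}

#' Transport a track through an interval mapping
#'
#' Per-base transport: each new-coordinate position takes the value of its
#' mapped old-coordinate position. Where several mapping entries cover the
#' same new position the entry with the highest score wins (the same
#' principle as z-order painting of hits); positions covered by no entry
#' get 0. Orientation -1 reverses the transported values within the entry.
#'
#' @param track a \linkS4class{ValueTrack} in old coordinates.
#' @param mapping data.frame from \code{\link{mappingFromBlast}}.
#' @param newLength length of the new coordinate system in bp.
#' @return A \linkS4class{ValueTrack} over the new coordinates.
#' @export
remapTrack <- function(track, mapping, newLength) {
  old <- expandBins(trackBins(track), trackLength(track))
  if (nrow(mapping)) {
    if (any(mapping$oldEnd > trackLength(track)) ||
        any(mapping$oldStart < 0) || any(mapping$newStart < 0) ||
        any(mapping$newEnd > newLength))
      stop("mapping entry outside old/new coordinate bounds")
    if (any(mapping$oldEnd - mapping$oldStart !=
            mapping$newEnd - mapping$newStart))
      stop("mapping entry old and new spans differ in length")
  }
  newv <- numeric(newLength)
  # apply in ascending score order so the highest-score entry overwrites
  for (j in order(mapping$score)) {
    os <- mapping$oldStart[j]; oe <- mapping$oldEnd[j]
    ns <- mapping$newStart[j]; ne <- mapping$newEnd[j]
    if (oe <= os) next
    vals <- old[(os + 1):oe]
    if (mapping$orientation[j] == -1) vals <- rev(vals)
    newv[(ns + 1):ne] <- vals
  }
  ValueTrack(compactRuns(newv), newLength)
}

#' Coverage anomaly intervals
#'
#' Maximal runs of positions whose value deviates from the track mean by
#' more than \code{k} population standard deviations (two-sided), merged
#' across adjacent bins — the "spikes" that flag collapsed repeats and
#' low-coverage regions in draft assemblies.
#'
#' @param track a \linkS4class{ValueTrack}.
#' @param k deviation threshold in standard deviations (> 0).
#' @return data.frame with columns start, end (0-based half-open); zero rows
#'   when nothing deviates (e.g. a constant track, whose sd is 0).
#' @export
coverageAnomalies <- function(track, k = 1) {
  if (!is.numeric(k) || k <= 0) stop("k must be positive")
  b <- trackBins(track)
  m <- trackMean(track); s <- trackSD(track)
  flag <- abs(b$value - m) > k * s
  out <- data.frame(start = numeric(0), end = numeric(0))
  i <- 1L
  while (i <= nrow(b)) {
    if (flag[i]) {
      s0 <- b$start[i]; e0 <- b$end[i]
      while (i + 1L <= nrow(b) && flag[i + 1L] && b$start[i + 1L] == e0) {
        i <- i + 1L; e0 <- b$end[i]
      }
      out <- rbind(out, data.frame(start = s0, end = e0))
    }
    i <- i + 1L
  }
  out
}

#' Write anomaly or annotation intervals as BED-like text
#'
#' Tab-delimited chrom/start/end (0-based half-open), one line per interval.
#'
#' @param intervals data.frame with start and end columns.
#' @param path output path.
#' @param chrom chromosome/reference name for the first column.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(intervals, path, chrom = "ref") {
  lines <- sprintf("%s\t%d\t%d", chrom, as.integer(intervals$start),
                   as.integer(intervals$end))
  writeLines(lines, path)
  invisible(path)
}
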