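#' Hit filter settings
#'
#' Thresholds applied to tabular BLAST hits before drawing: minimum percent
#' identity and maximum E-value (both boundaries inclusive), plus opaque
#' extra options passed verbatim to the BLAST command line. The defaults are
#' BLAST's own (keep everything); profiles state their thresholds explicitly.
#'
#' @param minIdentity minimum percent identity in [0, 100].
#' @param maxEvalue maximum E-value (> 0).
#' @param extraOptions character vector of additional BLAST arguments passed
#'   through verbatim (e.g. \code{c("-dust", "no")} to disable the
#'   low-complexity filter).
#' @return A list of class \code{HitFilter}.
#' @export
hitFilter <- function(minIdentity = 0, maxEvalue = 10,
                      extraOptions = character(0)) {
  if (minIdentity < 0 || minIdentity > 100)
    stop("minIdentity must lie in [0, 100]")
  if (maxEvalue <= 0) stop("maxEvalue must be positive")
  structure(list(minIdentity = minIdentity, maxEvalue = maxEvalue,
                 extraOptions = as.character(extraOptions)),
            class = "HitFilter")
}

blastColumns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

emptyHits <- function() {
  h <- data.frame(qseqid = character(0), sseqid = character(0),
                  pident = numeric(0), length = numeric(0),
                  mismatch = numeric(0), gapopen = numeric(0),
                  qstart = numeric(0), qend = numeric(0),
                  sstart = numeric(0), send = numeric(0),
                  evalue = numeric(0), bitscore = numeric(0),
                  stringsAsFactors = FALSE)
  h
}

externalToolError <- function(...) {
  stop(errorCondition(paste0(...), class = c("externalToolError", "error")))
}

requireExecutable <- function(name) {
  if (!nzchar(Sys.which(name)))
    externalToolError("external tool '", name, "' not found on PATH; ",
                      "install BLAST+ or supply precomputed tabular hits instead")
}

#' Create a BLAST database from a FASTA file
#'
#' Wraps \code{makeblastdb}. The reference is always the subject database;
#' queries are searched against it.
#'
#' @param referenceFasta FASTA path (non-empty).
#' @param dbtype \code{"nucl"} or \code{"prot"}.
#' @param out database path prefix; defaults to the FASTA path.
#' @return The database path prefix, with attribute \code{dbtype}.
#' @export
makeBlastDb <- function(referenceFasta, dbtype = c("nucl", "prot"),
                        out = referenceFasta) {
  dbtype <- match.arg(dbtype)
  requireExecutable("makeblastdb")
  if (!file.exists(referenceFasta) || file.size(referenceFasta) == 0)
    stop("reference FASTA '", referenceFasta, "' is missing or empty")
  log <- system2("makeblastdb",
                 c("-in", shQuote(referenceFasta), "-dbtype", dbtype,
                   "-out", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(log, "status")
  if (!is.null(status) && status != 0)
    externalToolError("makeblastdb failed (exit ", status, "):\n",
                      paste(log, collapse = "\n"))
  structure(out, dbtype = dbtype)
}

blastDbType <- function(db) {
  t <- attr(db, "dbtype")
  if (!is.null(t)) return(t)
  if (file.exists(paste0(db, ".nin")) || file.exists(paste0(db, ".nal")))
    return("nucl")
  if (file.exists(paste0(db, ".pin")) || file.exists(paste0(db, ".pal")))
    return("prot")
  stop("cannot determine database type of '", db, "'")
}

#' Run a BLAST comparison against the reference database
#'
#' Runs \code{blastn}, \code{blastx} or \code{tblastx} with the reference as
#' subject database and writes 12-column tabular output (outfmt 6). The
#' filter's \code{maxEvalue} is passed to BLAST as \code{-evalue}; identity
#' filtering is applied downstream by \code{\link{filterHits}} so the
#' thresholds act identically on live and precomputed tabular input. Extra
#' options are appended verbatim. For read sets, nucleotide reads are given
#' to \code{blastx} directly; the translation into peptides happens inside
#' BLAST.
#'
#' @param program \code{"blastn"} (nucl vs nucl db), \code{"blastx"}
#'   (nucl query vs prot db) or \code{"tblastx"} (nucl vs nucl db, both
#'   translated).
#' @param queryFasta query FASTA path.
#' @param db database path from \code{\link{makeBlastDb}}.
#' @param filter a \code{\link{hitFilter}}.
#' @param out output tabular path; default is a tempfile.
#' @return Path of the tabular file.
#' @export
runComparison <- function(program = c("blastn", "blastx", "tblastx"),
                          queryFasta, db, filter = hitFilter(),
                          out = tempfile(fileext = ".tab")) {
  program <- match.arg(program)
  requireExecutable(program)
  if (!file.exists(queryFasta) || file.size(queryFasta) == 0)
    stop("query FASTA '", queryFasta, "' is missing or empty")
  needed <- switch(program, blastn = "nucl", blastx = "prot", tblastx = "nucl")
  have <- blastDbType(db)
  if (!identical(have, needed))
    stop(program, " requires a ", needed, " database but '", db,
         "' is ", have)
  args <- c("-query", shQuote(queryFasta), "-db", shQuote(as.character(db)),
            "-outfmt", "6", "-evalue", format(filter$maxEvalue),
            "-out", shQuote(out), filter$extraOptions)
  log <- system2(program, args, stdout = TRUE, stderr = TRUE)
  status <- attr(log, "status")
  if (!is.null(status) && status != 0)
    externalToolError(program, " failed (exit ", status, "):\n",
                      paste(log, collapse = "\n"))
  out
}

#' Parse 12-column BLAST tabular output
#'
#' One hit per non-comment line, order preserved. Lines must carry at least
#' the 12 standard fields (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore); extra fields are ignored.
#'
#' @param path tabular file path.
#' @return data.frame of hits with the standard column names; zero rows for
#'   an empty file.
#' @export
parseBlastTabular <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad))
    stop("malformed BLAST tabular line ", lineNo[bad[1]], " in '", path,
         "': expected >= 12 tab-separated fields, got ",
         lengths(fields)[bad[1]])
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  h <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                  pident = as.numeric(m[, 3]), length = as.numeric(m[, 4]),
                  mismatch = as.numeric(m[, 5]), gapopen = as.numeric(m[, 6]),
                  qstart = as.numeric(m[, 7]), qend = as.numeric(m[, 8]),
                  sstart = as.numeric(m[, 9]), send = as.numeric(m[, 10]),
                  evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                  stringsAsFactors = FALSE)
  if (anyNA(h$pident) || anyNA(h$evalue) || anyNA(h$bitscore))
    stop("non-numeric field in BLAST tabular file '", path, "'")
  h
}

#' Filter hits by identity and E-value
#'
#' Keeps hits with \code{pident >= minIdentity} and
#' \code{evalue <= maxEvalue}; both boundaries are inclusive, so a hit at
#' exactly the identity cut-off is kept.
#'
#' @param hits hit data.frame from \code{\link{parseBlastTabular}}.
#' @param filter a \code{\link{hitFilter}}.
#' @return The kept subset, input order preserved.
#' @export
filterHits <- function(hits, filter) {
  keep <- hits$pident >= filter$minIdentity & hits$evalue <= filter$maxEvalue
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orient hits onto the reference
#'
#' BLAST reports subject coordinates 1-based inclusive and inverted
#' (\code{sstart > send}) for minus-strand matches. This returns the
#' forward-strand interval on the reference in 0-based half-open form:
#' \code{start = min(sstart, send) - 1}, \code{end = max(sstart, send)}.
#'
#' @param hits hit data.frame.
#' @return data.frame with columns \code{start}, \code{end} (plus
#'   \code{strand}: -1 where subject coordinates were inverted, else 1),
#'   one row per hit.
#' @export
orientToReference <- function(hits) {
  data.frame(
    start = pmin(hits$sstart, hits$send) - 1,
    end = pmax(hits$sstart, hits$send),
    strand = ifelse(hits$sstart > hits$send, -1, 1)
  )
}

#' Sort hits into drawing order
#'
#' Stable ascending sort by bitscore, so the highest-scoring hits are drawn
#' last and painted on top of weaker overlapping matches.
#'
#' @param hits hit data.frame.
#' @return The same rows reordered; ties keep input order.
#' @export
sortForDrawing <- function(hits) {
  out <- hits[order(hits$bitscore), , drop = FALSE]   # order() is stable
  rownames(out) <- NULL
  out
}

#' Reference intervals not covered by any hit
#'
#' The complement, within [0, L), of the union of the oriented hit
#' intervals: the blank/white regions of a ring, which signal sequence
#' absent from the query. Interval algebra is done with IRanges.
#'
#' @param hits hit data.frame (already filtered).
#' @param L reference length in bp.
#' @return data.frame with columns start, end (0-based half-open); zero
#'   rows when the hits tile the whole reference.
#' @export
uncoveredIntervals <- function(hits, L) {
  if (nrow(hits) == 0L)
    return(data.frame(start = 0, end = L))
  iv <- orientToReference(hits)
  ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)  # 1-based
  gaps <- IRanges::gaps(IRanges::reduce(ir), start = 1L, end = L)
  data.frame(start = BiocGenerics::start(gaps) - 1L,
             end = BiocGenerics::end(gaps))
}
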