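# Synthetic-data generators: deterministic stand-ins for the sequencing and
# assembly inputs the pipeline consumes (genomes, mutated variants with a
# known truth, read sets, SAM alignments, BLAST tabular hits). Every
# generator is a pure function of its arguments including the seed: the
# global RNG state is saved and restored around each call.

#' Generate a random genome
#'
#' I.i.d. bases with P(G) = P(C) = gcFraction/2 and
#' P(A) = P(T) = (1 - gcFraction)/2.
#'
#' @param length genome length in bp (>= 1).
#' @param gcFraction target GC fraction in [0, 1].
#' @param seed integer seed; the same seed always gives the same genome.
#' @param name sequence id.
#' @return A \code{DNAStringSet} of one sequence.
#' @export
synthGenome <- function(length, gcFraction = 0.5, seed = 1,
                        name = "synthetic_genome") {
  if (length < 1) stop("length must be >= 1")
  if (gcFraction < 0 || gcFraction > 1) stop("gcFraction must be in [0, 1]")
  s <- withSeed(seed, {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - gcFraction) / 2, (1 - gcFraction) / 2,
                          gcFraction / 2, gcFraction / 2)),
          collapse = "")
  })
  x <- Biostrings::DNAStringSet(s)
  names(x) <- name
  x
}

#' Mutate a genome with known deletions and SNPs
#'
#' Applies the given deletions (non-overlapping, 0-based half-open intervals
#' on the base genome) and then substitutes bases at Bernoulli(snpRate)
#' positions outside the deletions; substitutions are never silent (the new
#' base always differs). The returned truth records the deleted intervals
#' and the SNP positions, both in base-genome coordinates.
#'
#' @param base a single-sequence \code{DNAStringSet} (or character).
#' @param deletions data.frame with columns \code{start} (0-based) and
#'   \code{length} (bp), or NULL for none.
#' @param snpRate per-base substitution probability outside deletions.
#' @param seed integer seed.
#' @param name variant sequence id.
#' @return list with \code{variant} (a \code{DNAStringSet}) and \code{truth}
#'   (list: \code{deletions} data.frame with start/end 0-based half-open,
#'   \code{snpPositions} 0-based base-genome positions, \code{seed}).
#' @export
mutateGenome <- function(base, deletions = NULL, snpRate = 0, seed = 1,
                         name = "variant") {
  s <- toupper(asSequenceString(base))
  L <- nchar(s)
  if (is.null(deletions) || nrow(deletions) == 0L) {
    deletions <- data.frame(start = numeric(0), length = numeric(0))
  }
  del <- data.frame(start = deletions$start,
                    end = deletions$start + deletions$length)
  del <- del[order(del$start), , drop = FALSE]
  if (any(del$start < 0) || any(del$end > L))
    stop("deletion outside the base genome")
  if (nrow(del) > 1L && any(del$start[-1L] < del$end[-nrow(del)]))
    stop("overlapping deletions")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  keep <- rep(TRUE, L)
  for (i in seq_len(nrow(del))) keep[(del$start[i] + 1):del$end[i]] <- FALSE
  snpPos <- integer(0)
  chars <- withSeed(seed, {
    if (snpRate > 0) {
      cand <- which(keep)
      hit <- cand[stats::runif(length(cand)) < snpRate]
      snpPos <- hit - 1L                        # 0-based, base coordinates
      for (p in hit) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
    }
    chars
  })
  variant <- Biostrings::DNAStringSet(paste(chars[keep], collapse = ""))
  names(variant) <- name
  list(variant = variant,
       truth = list(deletions = del, snpPositions = snpPos, seed = seed))
}

#' Simulate a read set with known placements
#'
#' Uniform start positions, uniform strand, substitution errors at
#' Bernoulli(errorRate) per base (no indels: identity degradation is the
#' point, not alignment complexity). Placements are returned as truth so
#' coverage oracles can be built without parsing anything.
#'
#' @param genome single-sequence \code{DNAStringSet} (or character).
#' @param nReads number of reads.
#' @param readLength read length in bp (<= genome length).
#' @param errorRate per-base substitution probability.
#' @param seed integer seed.
#' @return list with \code{reads} (a \code{DNAStringSet}; reverse-strand
#'   reads are reverse-complemented as a sequencer would emit them) and
#'   \code{placements} (data.frame: id, start 0-based on the forward
#'   genome, length, strand +1/-1).
#' @export
synthReads <- function(genome, nReads, readLength = 100, errorRate = 0,
                       seed = 1) {
  s <- toupper(asSequenceString(genome))
  L <- nchar(s)
  if (readLength > L) stop("readLength exceeds genome length")
  if (nReads == 0L) {
    return(list(reads = Biostrings::DNAStringSet(character(0)),
                placements = data.frame(id = character(0), start = integer(0),
                                        length = integer(0), strand = integer(0),
                                        stringsAsFactors = FALSE)))
  }
  res <- withSeed(seed, {
    starts <- sample.int(L - readLength + 1L, nReads, replace = TRUE) - 1L
    strands <- sample(c(1L, -1L), nReads, replace = TRUE)
    seqs <- substring(s, starts + 1L, starts + readLength)
    if (errorRate > 0) {
      seqs <- vapply(seqs, function(x) {
        ch <- strsplit(x, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(ch)) < errorRate)
        for (p in hit)
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    list(starts = starts, strands = strands, seqs = seqs)
  })
  reads <- Biostrings::DNAStringSet(res$seqs)
  rc <- res$strands == -1L
  if (any(rc)) reads[rc] <- Biostrings::reverseComplement(reads[rc])
  ids <- sprintf("read_%06d", seq_len(nReads))
  names(reads) <- ids
  list(reads = reads,
       placements = data.frame(id = ids, start = res$starts,
                               length = readLength, strand = res$strands,
                               stringsAsFactors = FALSE))
}

#' Write a SAM file for known read placements
#'
#' One primary alignment per placement with an all-M CIGAR, the strand bit
#' (0x10) set for minus-strand placements, and an \code{@SQ} header carrying
#' the reference length. The pileup of this file equals the
#' placement-derived coverage oracle exactly.
#'
#' @param placements data.frame from \code{\link{synthReads}}.
#' @param genome the reference genome the placements refer to.
#' @param path output SAM path.
#' @param refName reference name for RNAME/@SQ.
#' @return \code{path}, invisibly.
#' @export
synthSam <- function(placements, genome, path, refName = "ref") {
  s <- toupper(asSequenceString(genome))
  L <- nchar(s)
  if (nrow(placements) &&
      any(placements$start < 0 | placements$start + placements$length > L))
    stop("placement outside the genome")
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", refName, L))
  if (nrow(placements)) {
    flag <- ifelse(placements$strand == -1L, 16L, 0L)
    seqs <- substring(s, placements$start + 1L,
                      placements$start + placements$length)
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
      placements$id, flag, refName, placements$start + 1L,
      placements$length, seqs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write BLAST tabular rows for known reference intervals
#'
#' Fixture mode for the whole downstream pipeline: each truth interval
#' (0-based half-open on the reference, with a percent identity and a
#' bitscore) becomes one well-formed 12-column row whose oriented subject
#' interval reproduces the truth exactly. Minus-orientation intervals get
#' inverted subject coordinates (sstart > send).
#'
#' @param truth data.frame with columns \code{start}, \code{end},
#'   \code{pident}, \code{bitscore} and optionally \code{orientation}
#'   (+1/-1, default +1) and \code{qseqid}.
#' @param path output tabular path.
#' @param subjectId subject (reference) id for column 2.
#' @return \code{path}, invisibly.
#' @export
synthBlastTabular <- function(truth, path, subjectId = "ref") {
  if (nrow(truth) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (any(truth$end <= truth$start)) stop("truth intervals must be non-empty")
  orient <- if ("orientation" %in% names(truth)) truth$orientation else
    rep(1, nrow(truth))
  qid <- if ("qseqid" %in% names(truth)) truth$qseqid else
    sprintf("q%04d", seq_len(nrow(truth)))
  len <- truth$end - truth$start
  sstart <- ifelse(orient == 1, truth$start + 1, truth$end)
  send <- ifelse(orient == 1, truth$end, truth$start + 1)
  mism <- round(len * (1 - truth$pident / 100))
  lines <- sprintf(
    "%s\t%s\t%.2f\t%d\t%d\t0\t1\t%d\t%d\t%d\t%.2e\t%.1f",
    qid, subjectId, truth$pident, as.integer(len), as.integer(mism),
    as.integer(len), as.integer(sstart), as.integer(send),
    1e-30, truth$bitscore)
  writeLines(lines, path)
  invisible(path)
}
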