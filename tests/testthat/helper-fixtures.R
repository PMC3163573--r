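# Fixtures built in code: flat-file records, a mini ACE assembly, and the
# brute-force pileup oracle used to check coverage computations.

genbankFixture <- function() {
  c("LOCUS       mini                8 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  tiny test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..8",
    '                     /organism="synthetic"',
    "     misc_feature    2..5",
    '                     /note="Sp 1"',
    "     misc_feature    3..6",
    '                     /note="SpLE 4"',
    "     misc_feature    complement(4..7)",
    '                     /note="other"',
    "ORIGIN",
    "        1 acgtacgt",
    "//")
}

emblFixture <- function() {
  c("ID   emini; SV 1; linear; DNA; STD; PRO; 8 BP.",
    "DE   tiny embl record",
    "FH   Key             Location/Qualifiers",
    "FT   misc_feature    2..5",
    'FT                   /note="Sp 1"',
    "SQ   Sequence 8 BP;",
    "     acgtacgt                                                        8",
    "//")
}

# 1 contig of 20 bases, 2 reads of 12 bases at padded offsets 1 and 9:
# hand-computed pileup is 1 on [0,8), 2 on [8,12), 1 on [12,20).
aceFixture <- function(consensus = strrep("A", 20)) {
  c("AS 1 2",
    "",
    sprintf("CO contig1 %d 2 0 U", nchar(consensus)),
    consensus,
    "",
    "AF read1 U 1",
    "AF read2 U 9",
    "",
    "RD read1 12 0 0",
    strrep("A", 12),
    "",
    "RD read2 12 0 0",
    strrep("A", 12),
    "")
}

writeTempLines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent per-base pileup oracle from truth placements.
placementPileup <- function(placements, L) {
  cov <- integer(L)
  for (i in seq_len(nrow(placements))) {
    s <- placements$start[i]
    e <- s + placements$length[i]
    cov[(s + 1):e] <- cov[(s + 1):e] + 1L
  }
  cov
}

trackPerBase <- function(track) {
  GenomeRings:::expandBins(trackBins(track), trackLength(track))
}

randomHits <- function(n, L = 10000, seed = 1) {
  if (n == 0L) return(GenomeRings:::emptyHits())
  set.seed(seed)
  start <- sample.int(L - 200L, n, replace = TRUE)
  len <- sample(50:200, n, replace = TRUE)
  minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
  data.frame(
    qseqid = sprintf("q%03d", seq_len(n)), sseqid = "ref",
    pident = round(runif(n, 60, 100), 2), length = len,
    mismatch = 0, gapopen = 0, qstart = 1, qend = len,
    sstart = ifelse(minus, start + len, start + 1L),
    send = ifelse(minus, start + 1L, start + len),
    evalue = 10^-runif(n, 5, 50), bitscore = round(runif(n, 40, 400), 1),
    stringsAsFactors = FALSE
  )
}
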