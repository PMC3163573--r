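test_that("GC content windows count G+C over unambiguous bases", {
  expect_equal(trackBins(gcContent("GGCC", 4, 4))$value, 1.0)
  expect_equal(trackBins(gcContent("ATAT", 4, 4))$value, 0.0)
  expect_equal(trackBins(gcContent("ACGT", 2, 2))$value, c(0.5, 0.5))
  # ambiguity codes drop from numerator and denominator
  expect_equal(trackBins(gcContent("GCNN", 4, 4))$value, 1.0)
  expect_equal(trackBins(gcContent("NNNN", 4, 4))$value, 0.0)
  expect_error(gcContent("ACGT", 8, 8), "exceeds sequence length")
})

test_that("circular windows wrap past the origin", {
  # GGAT circular, window 2 step 2: [GG]=1, [AT]=0; linear identical here,
  # so use step 3 to force a wrapping window: start 3 covers T+G
  tr <- gcContent("GGAT", 2, 2, circular = TRUE)
  expect_equal(trackBins(tr)$value, c(1, 0))
  tr2 <- gcContent("GGGA", 3, 3, circular = TRUE)  # [GGG]=1, [A|GG]=2/3
  expect_equal(trackBins(tr2)$value, c(1, 2 / 3))
  expect_true(all(trackBins(tr2)$end <= 4))
})

test_that("GC skew follows (G-C)/(G+C) with a zero-denominator convention", {
  expect_equal(trackBins(gcSkew("GGGG", 4, 4))$value, 1.0)
  expect_equal(trackBins(gcSkew("GGCC", 4, 4))$value, 0.0)
  expect_equal(trackBins(gcSkew("ATAT", 4, 4))$value, 0.0)
})

test_that("GC skew negates under complementation", {
  g <- synthGenome(4000, 0.5, seed = 33)
  comp <- Biostrings::complement(g)
  s1 <- trackBins(gcSkew(g, 250, 250))$value
  s2 <- trackBins(gcSkew(comp, 250, 250))$value
  expect_equal(s1, -s2)
})

test_that("mean-centering gives a zero length-weighted mean and is idempotent", {
  tr <- ValueTrack(data.frame(start = c(0, 10, 20), end = c(10, 20, 30),
                              value = c(1, 2, 3)), 30)
  ctr <- skewFromMean(tr)
  expect_equal(trackBins(ctr)$value, c(-1, 0, 1))
  expect_equal(trackMean(ctr), 0)

  const <- ValueTrack(data.frame(start = 0, end = 50, value = 7), 50)
  expect_equal(trackBins(skewFromMean(const))$value, 0)

  set.seed(11)
  w <- sample(1:50, 100, replace = TRUE)
  bins <- data.frame(start = cumsum(c(0, w))[1:100],
                     end = cumsum(w), value = rnorm(100, 5, 2))
  rt <- ValueTrack(bins, sum(w))
  once <- skewFromMean(rt)
  expect_lt(abs(trackMean(once)), 1e-9)
  twice <- skewFromMean(once)
  expect_equal(trackBins(twice)$value, trackBins(once)$value,
               tolerance = 1e-9)
})

test_that("zero-to-max scaling clamps then normalises", {
  tr <- ValueTrack(data.frame(start = 0:3 * 10, end = 1:4 * 10,
                              value = c(0, 15, 30, 45)), 40)
  expect_equal(trackBins(scaleZeroToMax(tr, 30))$value, c(0, 0.5, 1, 1))
  neg <- ValueTrack(data.frame(start = 0, end = 10, value = -5), 10)
  expect_equal(trackBins(scaleZeroToMax(neg, 30))$value, 0)
  expect_error(scaleZeroToMax(tr, 0), "positive")
})

test_that("graph files parse in both dialects with strict validation", {
  p3 <- writeTempLines(c("1 100 5.0", "101 200 7.5"))
  tr <- readGraphFile(p3, 200)
  expect_equal(trackBins(tr),
               data.frame(start = c(0, 100), end = c(100, 200),
                          value = c(5.0, 7.5)))
  p1 <- writeTempLines(as.character(1:5))
  tr1 <- readGraphFile(p1, 5)
  expect_equal(trackLength(tr1), 5)
  expect_equal(trackPerBase(tr1), 1:5)

  expect_error(readGraphFile(writeTempLines(as.character(1:4)), 5),
               "4 values but the reference is 5")
  expect_error(readGraphFile(writeTempLines(c("1 100 5.0", "7.5")), 200),
               "mixes column counts")
  expect_error(readGraphFile(writeTempLines("1 100 abc"), 200),
               "non-numeric")
})

test_that("SAM pileup counts M/=/X and skips D, N and filtered flags", {
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:30",
           "r1\t0\tref\t5\t60\t10M\t*\t0\t0\t*\t*")
  cov <- coverageFromSam(writeTempLines(sam, ".sam"))
  pb <- trackPerBase(cov)
  expect_equal(which(pb == 1), 5:14)          # POS=5, 10M -> [4,14)

  sam2 <- c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:30",
            "r1\t0\tref\t1\t60\t10M\t*\t0\t0\t*\t*",
            "r2\t16\tref\t8\t60\t10M\t*\t0\t0\t*\t*")
  pb2 <- trackPerBase(coverageFromSam(writeTempLines(sam2, ".sam")))
  expect_equal(sum(pb2 == 2), 3)              # 3 bp overlap
  expect_equal(which(pb2 == 2), 8:10)

  # deletion spans consume reference without coverage; secondary and
  # unmapped records are ignored entirely
  sam3 <- c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:30",
            "r1\t0\tref\t1\t60\t5M2D3M\t*\t0\t0\t*\t*",
            "r2\t256\tref\t20\t60\t5M\t*\t0\t0\t*\t*",
            "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")
  pb3 <- trackPerBase(coverageFromSam(writeTempLines(sam3, ".sam")))
  expect_equal(which(pb3 == 1), c(1:5, 8:10))
  expect_equal(sum(pb3[20:24]), 0)
})

test_that("SAM pileup equals the brute-force placement oracle", {
  g <- synthGenome(20000, 0.5, seed = 21)
  rd <- synthReads(g, 1000, 100, errorRate = 0, seed = 22)
  sam <- tempfile(fileext = ".sam")
  synthSam(rd$placements, g, sam)
  cov <- coverageFromSam(sam)
  expect_identical(trackPerBase(cov),
                   as.numeric(placementPileup(rd$placements, 20000)))
})

test_that("ACE coverage matches the hand-computed pileup after depadding", {
  ace <- writeTempLines(aceFixture(), ".ace")
  res <- coverageFromAce(ace)
  expect_equal(res$contigs$name, "contig1")
  pb <- trackPerBase(res$tracks$contig1)
  expect_equal(pb, c(rep(1, 8), rep(2, 4), rep(1, 8)))

  # one consensus pad: depadded length is padded length minus one
  padded <- paste0(strrep("A", 10), "*", strrep("A", 10))
  res2 <- coverageFromAce(writeTempLines(aceFixture(padded), ".ace"))
  expect_equal(res2$contigs$length, 20)

  # contig with no reads is all zero
  noReads <- c("CO empty 10 0 0 U", strrep("C", 10), "")
  res3 <- coverageFromAce(writeTempLines(noReads, ".ace"))
  expect_equal(trackPerBase(res3$tracks$empty), rep(0, 10))

  orphan <- c("CO c 10 1 0 U", strrep("A", 10), "", "AF ghost U 1")
  expect_error(coverageFromAce(writeTempLines(orphan, ".ace")),
               "no matching RD")
})

test_that("contig boundary segments tile the reference with alternating colors", {
  recs <- Biostrings::BStringSet(c(c1 = "ACGTAC", c2 = "GGGG", c3 = "TTT"))
  seg <- contigBoundaries(buildReferenceMap(recs, circular = FALSE))
  expect_equal(seg$colorIndex, c(0, 1, 0))
  expect_equal(seg$start, c(0, 6, 10))
  expect_equal(seg$end, c(6, 10, 13))
  one <- contigBoundaries(buildReferenceMap(recs[1]))
  expect_equal(one$colorIndex, 0)
})

test_that("BLAST hits convert to truncated 1:1 interval mappings", {
  h <- data.frame(qstart = c(1, 1, 1), qend = c(100, 100, 100),
                  sstart = c(201, 300, 201), send = c(300, 201, 298),
                  bitscore = c(180, 170, 160))
  m <- mappingFromBlast(h)
  expect_equal(m$oldStart, c(0, 0, 0))
  expect_equal(m$newStart, c(200, 200, 200))
  expect_equal(m$orientation, c(1, -1, 1))
  # gapped hit: spans 100 vs 98 truncate to 98 from the interval starts
  expect_equal(m$oldEnd[3] - m$oldStart[3], 98)
  expect_equal(m$newEnd[3] - m$newStart[3], 98)
  expect_equal(m$score, h$bitscore)
})

test_that("track remapping transports values like the per-base oracle", {
  set.seed(13)
  L <- 1000
  vals <- round(runif(L, 0, 50))
  tr <- ValueTrack(GenomeRings:::compactRuns(vals), L)

  ident <- data.frame(oldStart = 0, oldEnd = L, newStart = 0, newEnd = L,
                      orientation = 1, score = 1)
  expect_equal(trackPerBase(remapTrack(tr, ident, L)), vals)

  # two-block swap: first half <-> second half
  swap <- data.frame(oldStart = c(0, 500), oldEnd = c(500, 1000),
                     newStart = c(500, 0), newEnd = c(1000, 500),
                     orientation = 1, score = c(1, 1))
  got <- trackPerBase(remapTrack(tr, swap, L))
  oracle <- numeric(L)
  for (p in 0:499) oracle[p + 500 + 1] <- vals[p + 1]
  for (p in 500:999) oracle[p - 500 + 1] <- vals[p + 1]
  expect_equal(got, oracle)
  expect_equal(sum(got), sum(vals))           # mass conserved, bijective map

  # reversed-orientation block reverses values within the block
  revmap <- data.frame(oldStart = 100, oldEnd = 200, newStart = 300,
                       newEnd = 400, orientation = -1, score = 1)
  got2 <- trackPerBase(remapTrack(tr, revmap, L))
  expect_equal(got2[301:400], rev(vals[101:200]))
  expect_equal(sum(got2[-(301:400)]), 0)

  # conflicting entries: the higher-score mapping wins
  conflict <- data.frame(oldStart = c(0, 10), oldEnd = c(10, 20),
                         newStart = c(0, 0), newEnd = c(10, 10),
                         orientation = 1, score = c(5, 50))
  got3 <- trackPerBase(remapTrack(tr, conflict, L))
  expect_equal(got3[1:10], vals[11:20])
})

test_that("coverage anomalies are maximal runs beyond k standard deviations", {
  const <- ValueTrack(data.frame(start = 0, end = 1000, value = 100), 1000)
  expect_equal(nrow(coverageAnomalies(const, 1)), 0L)

  vals <- rep(100, 10000)
  vals[4001:4500] <- 300
  tr <- ValueTrack(GenomeRings:::compactRuns(vals), 10000)
  an <- coverageAnomalies(tr, 1)
  expect_equal(nrow(an), 1L)
  expect_equal(c(an$start, an$end), c(4000, 4500))
  expect_equal(nrow(coverageAnomalies(tr, 100)), 0L)

  # adjacent deviating bins merge into one interval
  b <- data.frame(start = seq(0, 110, 10), end = seq(10, 120, 10),
                  value = c(rep(0, 10), 100, 100))
  an2 <- coverageAnomalies(ValueTrack(b, 120), 1)
  expect_equal(nrow(an2), 1L)
  expect_equal(c(an2$start, an2$end), c(100, 120))
})
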