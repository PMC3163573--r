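test_that("the identity gradient maps thresholds to opacity linearly", {
  expect_equal(identityToOpacity(100, 70, 100), 1.0)
  expect_equal(identityToOpacity(70, 70, 100), 0.1)
  expect_equal(identityToOpacity(85, 70, 100), 0.55)
  expect_true(is.na(identityToOpacity(69.9, 70, 100)))
  expect_equal(identityToOpacity(100, 100, 100), 1.0)
})

test_that("the identity gradient is monotone and continuous on [lower, 100]", {
  grid <- seq(70, 100, by = 0.25)
  ops <- identityToOpacity(grid, 70, 100)
  expect_true(all(diff(ops) >= 0))
  expect_lt(max(abs(diff(ops))), 0.01 * 2)   # no jumps on a 0.25% grid
  expect_equal(min(ops), 0.1)
  expect_equal(max(ops), 1.0)
})

test_that("blast rings pool, filter, orient and z-order hits", {
  recs <- Biostrings::BStringSet(c(ref = strrep("A", 1000)))
  rm <- buildReferenceMap(recs)
  spec <- RingSpec("blast", c("s1", "s2", "s3"), lowerIdentity = 70)

  expect_equal(nrow(buildBlastRing(list(s1 = randomHits(0)[0, ],
                                        s2 = randomHits(0)[0, ],
                                        s3 = randomHits(0)[0, ]),
                                   spec, rm)), 0L)

  full <- randomHits(1, seed = 2)
  full$sstart <- 1; full$send <- 1000; full$pident <- 100
  arcs1 <- buildBlastRing(list(s1 = full, s2 = full[0, ], s3 = full[0, ]),
                          RingSpec("blast", "s1"), rm)
  expect_equal(nrow(arcs1), 1L)
  expect_equal(c(arcs1$start, arcs1$end, arcs1$opacity), c(0, 1000, 1))

  mk <- function(seed) {
    h <- randomHits(10, L = 900, seed = seed)
    h$pident <- runif(10, 75, 100)       # all above the lower threshold
    h
  }
  sets <- list(s1 = mk(4), s2 = mk(5), s3 = mk(6))
  arcs <- buildBlastRing(sets, spec, rm)
  expect_equal(nrow(arcs), 30L)
  # z strictly increases with bitscore rank (oracle: plain sort)
  expect_true(!is.unsorted(arcs$bitscore[order(arcs$z)]))
  expect_equal(sort(arcs$bitscore),
               sort(c(sets$s1$bitscore, sets$s2$bitscore, sets$s3$bitscore)))
  expect_error(buildBlastRing(list(s1 = mk(4)), spec, rm),
               "no loaded data for ring member 's2'")

  # hits below the lower identity are omitted entirely, not drawn faint
  low <- mk(7); low$pident <- 50
  expect_equal(nrow(buildBlastRing(list(s1 = low, s2 = low[0, ],
                                        s3 = low[0, ]), spec, rm)), 0L)
})

test_that("arcs crossing the origin split without losing length", {
  arcs <- data.frame(start = c(900, 100), end = c(1100, 200),
                     color = "#000000", opacity = 1, z = 1:2,
                     bitscore = c(10, 20))
  split <- GenomeRings:::wrapSplitArcs(arcs, 1000)
  expect_equal(nrow(split), 3L)
  expect_true(all(split$start >= 0 & split$end <= 1000))
  crossing <- split[split$z == 1, ]
  expect_equal(sum(crossing$end - crossing$start), 200)
})

test_that("graph rings scale to renderer heights", {
  const <- ValueTrack(data.frame(start = 0, end = 100, value = 5), 100)
  spec <- RingSpec("graph", "t", graphMode = "mean_skew")
  expect_equal(buildGraphRing(const, spec)$height, 0)

  tr <- ValueTrack(data.frame(start = c(0, 10, 20), end = c(10, 20, 30),
                              value = c(-2, 0, 2) + 10), 30)
  expect_equal(buildGraphRing(tr, spec)$height, c(-1, 0, 1))

  zm <- RingSpec("graph", "t", graphMode = "zero_to_max", graphMax = 30)
  tr2 <- ValueTrack(data.frame(start = 0:3 * 10, end = 1:4 * 10,
                               value = c(0, 15, 30, 45)), 40)
  expect_equal(buildGraphRing(tr2, zm)$height, c(0, 0.5, 1, 1))
})

test_that("image assembly is structural, deterministic and shares sources", {
  recs <- Biostrings::BStringSet(c(ref = strrep("ACGT", 250)))
  rm <- buildReferenceMap(recs)

  bare <- assembleImage(rm, title = "empty")
  expect_length(bare@rings, 0L)
  expect_gt(bare@tickMajor, 0)

  # a full-feature model: GC rings, coverage ring, contig ring, blast
  # rings from several query sets, annotation ring
  g <- synthGenome(1000, 0.5, seed = 77)
  hits <- lapply(1:4, function(i) randomHits(8, L = 900, seed = 40 + i))
  names(hits) <- paste0("q", 1:4)
  tracks <- list(gc = gcContent(g, 100, 100), skew = gcSkew(g, 100, 100),
                 cov = ValueTrack(data.frame(start = 0, end = 1000,
                                             value = 10), 1000))
  rings <- list(
    RingSpec("graph", "skew", graphMode = "mean_skew"),
    RingSpec("graph", "gc", graphMode = "mean_skew"),
    RingSpec("graph", "cov", graphMode = "zero_to_max", graphMax = 30),
    RingSpec("contigs", "ref"),
    RingSpec("blast", "q1"),
    RingSpec("blast", c("q2", "q3"), legendText = "collated"),
    RingSpec("blast", "q4"),
    RingSpec("annotations", "ann")
  )
  ann <- list(ann = headerAnnotations(rm))
  model <- assembleImage(rm, rings, hits, tracks, ann, title = "fixture")
  expect_length(model@rings, 8L)
  expect_equal(vapply(model@rings, function(r) r$spec@kind, character(1)),
               c("graph", "graph", "graph", "contigs", "blast", "blast",
                 "blast", "annotations"))
  expect_equal(nrow(model@legend), 3L)

  # sharing one source between two rings is allowed
  shared <- assembleImage(rm, list(RingSpec("blast", "q1"),
                                   RingSpec("blast", "q1")), hits)
  expect_equal(nrow(shared@rings[[1]]$arcs), nrow(shared@rings[[2]]$arcs))

  expect_error(assembleImage(rm, list(RingSpec("graph", "nope")), hits,
                             tracks), "no loaded track")
})
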