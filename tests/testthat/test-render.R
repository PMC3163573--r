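test_that("base positions map to clockwise-from-top angles", {
  L <- 12345
  expect_equal(bpToAngle(0, L), 0)
  expect_equal(bpToAngle(L / 2, L), pi)
  expect_equal(bpToAngle(L, L), 2 * pi)
  # a full-length feature sweeps the whole circle
  expect_equal(bpToAngle(L, L) - bpToAngle(0, L), 2 * pi, tolerance = 1e-9)
  # sweep is proportional to length
  expect_equal(bpToAngle(400, 1000) - bpToAngle(150, 1000),
               2 * pi * 250 / 1000, tolerance = 1e-12)
  expect_error(bpToAngle(-1, L), "outside")
})

test_that("ring layout stacks widths and spacing from the inner radius", {
  specs <- list(RingSpec("blast", "a", width = 10),
                RingSpec("blast", "b", width = 10))
  ly <- layoutRings(specs, innerRadius = 100, spacing = 2,
                    imageSize = 3000)
  expect_equal(ly$radii$inner, c(100, 112))
  expect_equal(ly$radii$outer, c(110, 122))
  expect_equal(ly$scale, 1)

  empty <- layoutRings(list(), 100, 2, 3000)
  expect_equal(nrow(empty$radii), 0L)

  many <- replicate(30, RingSpec("blast", "a", width = 10),
                    simplify = FALSE)
  expect_warning(ly2 <- layoutRings(many, 100, 2, 600), "scaled")
  expect_lt(max(ly2$radii$outer), 300)
  expect_lt(ly2$scale, 1)
})

test_that("tick positions match the closed-form counts", {
  t <- tickPositions(10000, 1000, 200)
  expect_length(t$major, 10L)
  expect_equal(t$major, seq(0, 9000, 1000))
  expect_length(t$minor, 40L)
  expect_true(all(t$minor %% 200 == 0))
  expect_true(all(t$minor %% 1000 != 0))

  short <- tickPositions(500, 1000, 200)
  expect_equal(short$major, 0)
  expect_error(tickPositions(10, 5, 6), "minor")
})

test_that("annular sector paths hit the analytic corner coordinates", {
  # quarter sweep at radii (100, 110), centered at origin
  d <- arcPath(100, 110, 0, pi / 2, cx = 0, cy = 0)
  nums <- as.numeric(regmatches(d, gregexpr("-?\\d+\\.\\d+", d))[[1]])
  # M x0 y0 A r r 0 f 1 x1 y1 L x2 y2 A r r 0 f 0 x3 y3 Z
  corner <- function(r, t) c(r * sin(t), -r * cos(t))
  expect_equal(nums[1:2], corner(110, 0), tolerance = 1e-6)
  expect_equal(nums[5:6], corner(110, pi / 2), tolerance = 1e-6)
  expect_equal(nums[7:8], corner(100, pi / 2), tolerance = 1e-6)
  expect_equal(nums[11:12], corner(100, 0), tolerance = 1e-6)

  # zero sweep is widened to the minimum visible sweep, not dropped
  d0 <- arcPath(100, 110, 1, 1)
  expect_match(d0, "^M ")
  n0 <- as.numeric(regmatches(d0, gregexpr("-?\\d+\\.\\d+", d0))[[1]])
  expect_false(isTRUE(all.equal(n0[1:2], n0[5:6])))

  # full circle: two joined half-annuli
  dF <- arcPath(100, 110, 0, 2 * pi)
  expect_equal(lengths(regmatches(dF, gregexpr("M ", dF))), 2L)
  expect_error(arcPath(110, 100, 0, 1), "rInner")
})

makeFixtureModel <- function(bitscores = c(50, 100, 200)) {
  rm <- buildReferenceMap(Biostrings::BStringSet(c(ref = strrep("A", 1000))))
  h <- randomHits(length(bitscores), L = 900, seed = 8)
  h$pident <- 90
  h$bitscore <- bitscores
  spec <- RingSpec("blast", "q", lowerIdentity = 70)
  assembleImage(rm, list(spec), list(q = h), title = "fixture")
}

test_that("rendered SVG is well-formed XML with arcs in z order", {
  skip_if_not_installed("xml2")
  model <- makeFixtureModel(c(200, 50, 100))   # permuted input
  svg <- tempfile(fileext = ".svg")
  renderSVG(model, svg, imageSize = 800)
  doc <- xml2::read_xml(svg)                   # errors if malformed
  hits <- xml2::xml_find_all(doc, "//*[@class='hit']")
  expect_length(hits, 3L)
  # opacity encodes identity here, but order must follow bitscore
  ops <- as.numeric(xml2::xml_attr(hits, "fill-opacity"))
  arcs <- model@rings[[1]]$arcs
  expect_equal(ops, arcs$opacity[order(arcs$z)])
  expect_equal(arcs$bitscore[order(arcs$z)], c(50, 100, 200))
})

test_that("an empty model still renders the backbone, ticks and title", {
  skip_if_not_installed("xml2")
  rm <- buildReferenceMap(Biostrings::BStringSet(c(ref = strrep("A", 500))))
  model <- assembleImage(rm, title = "bare")
  svg <- tempfile(fileext = ".svg")
  renderSVG(model, svg, imageSize = 600)
  doc <- xml2::read_xml(svg)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='circle']"), 1L)
  expect_gt(length(xml2::xml_find_all(doc, "//*[local-name()='line']")), 0L)
  txt <- xml2::xml_text(xml2::xml_find_all(doc, "//*[local-name()='text']"))
  expect_true("bare" %in% txt)
})

test_that("rendering is byte-deterministic and svgz matches the svg bytes", {
  model <- makeFixtureModel()
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  renderSVG(model, p1, imageSize = 800)
  renderSVG(model, p2, imageSize = 800)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  pz <- tempfile(fileext = ".svgz")
  renderSVG(model, pz, "svgz", imageSize = 800)
  expect_identical(readSvgz(pz),
                   rawToChar(readBin(p1, "raw", file.size(p1))))
})

test_that("graph, contig and annotation rings render their elements", {
  skip_if_not_installed("xml2")
  recs <- Biostrings::BStringSet(c(c1 = strrep("AG", 150),
                                   c2 = strrep("CT", 100)))
  rm <- buildReferenceMap(recs, circular = FALSE)
  tr <- ValueTrack(data.frame(start = c(0, 250), end = c(250, 500),
                              value = c(1, 3)), 500)
  rings <- list(RingSpec("graph", "t", graphMode = "mean_skew"),
                RingSpec("contigs", "c"),
                RingSpec("annotations", "h", width = 6))
  model <- assembleImage(rm, rings, tracks = list(t = tr),
                         annotationSets = list(h = headerAnnotations(rm)))
  svg <- tempfile(fileext = ".svg")
  renderSVG(model, svg, imageSize = 700)
  doc <- xml2::read_xml(svg)
  expect_length(xml2::xml_find_all(doc, "//*[@class='contig']"), 2L)
  expect_length(xml2::xml_find_all(doc, "//*[@class='feature']"), 2L)
  expect_gt(length(xml2::xml_find_all(doc, "//*[@class='bar']")), 0L)
  labels <- xml2::xml_text(xml2::xml_find_all(doc,
    "//*[local-name()='g'][@id='labels']/*[local-name()='text']"))
  expect_setequal(labels, c("c1", "c2"))
})
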