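# Polar geometry convention (the single coordinate contract of the
# renderer): position 0 sits at 12 o'clock and angles increase clockwise,
# so a point at radius r and angle theta is (cx + r*sin(theta),
# cy - r*cos(theta)) in SVG pixel coordinates.

#' Map a base-pair position to its angle on the circle
#'
#' theta = 2*pi*p/L radians, measured clockwise from 12 o'clock (position 0
#' at the top of the image).
#'
#' @param p position in bp, 0 <= p <= L (vectorised).
#' @param L reference length in bp.
#' @return angle(s) in radians.
#' @export
bpToAngle <- function(p, L) {
  if (L <= 0) stop("L must be positive")
  if (any(p < 0 | p > L)) stop("position outside [0, L]")
  2 * pi * p / L
}

polarX <- function(cx, r, theta) cx + r * sin(theta)
polarY <- function(cy, r, theta) cy - r * cos(theta)

#' Lay out ring radii
#'
#' Ring i occupies [innerRadius + sum_{j<i}(width_j*scale + spacing),
#' ... + width_i*scale]. When the outermost ring plus the label margin
#' would not fit inside the image, widths are scaled down uniformly (with a
#' warning) rather than erroring.
#'
#' @param specs ordered list of \linkS4class{RingSpec} (innermost first).
#' @param innerRadius radius of the innermost ring's inner edge, px.
#' @param spacing radial gap between rings, px.
#' @param imageSize image width/height in px.
#' @param labelMargin px reserved outside the outermost ring for labels.
#' @return list with \code{center}, \code{radii} (data.frame inner/outer),
#'   \code{labelRadius}, \code{imageSize} and the applied \code{scale}.
#' @export
layoutRings <- function(specs, innerRadius, spacing = 2,
                        imageSize = 3000, labelMargin = 0.08 * imageSize) {
  if (innerRadius <= 0) stop("innerRadius must be positive")
  if (spacing < 0) stop("spacing must be non-negative")
  n <- length(specs)
  widths <- vapply(specs, function(s) s@width, numeric(1))
  available <- imageSize / 2 - labelMargin - innerRadius
  scale <- 1
  if (n > 0) {
    need <- sum(widths) + spacing * (n - 1)
    if (need > available) {
      if (available - spacing * (n - 1) <= 0)
        stop("image too small for ", n, " rings at spacing ", spacing)
      scale <- (available - spacing * (n - 1)) / sum(widths)
      warning(sprintf(
        "ring stack (%.0f px) exceeds available %.0f px; widths scaled by %.3f",
        need, available, scale))
    }
  }
  inner <- numeric(n); outer <- numeric(n)
  r <- innerRadius
  for (i in seq_len(n)) {
    inner[i] <- r
    outer[i] <- r + widths[i] * scale
    r <- outer[i] + spacing
  }
  top <- if (n > 0) outer[n] else innerRadius
  list(center = c(imageSize / 2, imageSize / 2),
       radii = data.frame(inner = inner, outer = outer),
       labelRadius = top + 0.25 * labelMargin,
       imageSize = imageSize, scale = scale)
}

#' Tick mark positions
#'
#' Major ticks at every multiple of \code{major} below L (including 0);
#' minor ticks at multiples of \code{minor} below L that do not coincide
#' with a major tick.
#'
#' @param L reference length in bp.
#' @param major major tick interval in bp.
#' @param minor minor tick interval in bp (\code{0 < minor <= major}).
#' @return list with numeric vectors \code{major} and \code{minor}.
#' @export
tickPositions <- function(L, major, minor = major / 5) {
  if (minor <= 0 || minor > major) stop("need 0 < minor <= major")
  majors <- major * (0:max(0, floor((L - 1e-9) / major)))
  cand <- minor * (0:max(0, floor((L - 1e-9) / minor)))
  onMajor <- abs(cand / major - round(cand / major)) < 1e-9
  list(major = majors, minor = cand[!onMajor])
}

#' Annular sector path
#'
#' The SVG path of the annulus sector between radii \code{rInner} and
#' \code{rOuter} sweeping clockwise from \code{theta1} to \code{theta2}.
#' Sweeps narrower than the minimum visible sweep (by default the angle
#' subtending one pixel at the outer radius, so single genes on megabase
#' circles do not vanish) are widened symmetrically about their midpoint.
#' Full-circle sweeps are emitted as two joined half-annulus subpaths, since
#' a single SVG arc command cannot draw a closed 2*pi sweep.
#'
#' @param rInner,rOuter radii in px, \code{0 < rInner < rOuter}.
#' @param theta1,theta2 angles in radians,
#'   \code{theta1 <= theta2 <= theta1 + 2*pi}.
#' @param cx,cy circle center in px.
#' @param minSweep minimum visible sweep in radians; default 1px at
#'   \code{rOuter}.
#' @return a single SVG path \code{d} string (two subpaths for a full
#'   circle).
#' @export
arcPath <- function(rInner, rOuter, theta1, theta2, cx = 0, cy = 0,
                    minSweep = 1 / rOuter) {
  if (rInner <= 0 || rOuter <= rInner) stop("need 0 < rInner < rOuter")
  if (theta2 < theta1 || theta2 > theta1 + 2 * pi + 1e-12)
    stop("need theta1 <= theta2 <= theta1 + 2*pi")
  sweep <- theta2 - theta1
  if (sweep >= 2 * pi - 1e-9) {
    mid <- theta1 + pi
    return(paste(sectorPath(rInner, rOuter, theta1, mid, cx, cy),
                 sectorPath(rInner, rOuter, mid, theta1 + 2 * pi, cx, cy)))
  }
  if (sweep < minSweep) {
    c0 <- (theta1 + theta2) / 2
    theta1 <- c0 - minSweep / 2
    theta2 <- c0 + minSweep / 2
  }
  sectorPath(rInner, rOuter, theta1, theta2, cx, cy)
}

sectorPath <- function(rInner, rOuter, t1, t2, cx, cy) {
  large <- if ((t2 - t1) > pi) 1 else 0
  p <- function(r, t) paste(fmtNum(polarX(cx, r, t)), fmtNum(polarY(cy, r, t)))
  sprintf("M %s A %s %s 0 %d 1 %s L %s A %s %s 0 %d 0 %s Z",
          p(rOuter, t1), fmtNum(rOuter), fmtNum(rOuter), large, p(rOuter, t2),
          p(rInner, t2), fmtNum(rInner), fmtNum(rInner), large, p(rInner, t1))
}

svgEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

formatBpLabel <- function(pos, L) {
  if (L >= 2e6) sprintf("%g Mbp", pos / 1e6)
  else if (L >= 2e3) sprintf("%g kbp", pos / 1e3)
  else sprintf("%g bp", pos)
}

contigRingColors <- c("#CC0000", "#0000CC")

#' Render an image model to SVG or SVGZ
#'
#' Deterministic renderer: the same model always produces byte-identical
#' SVG (fixed number formatting, fixed element order, no timestamps). Arcs
#' are emitted in z order within each ring so the highest-scoring hits are
#' painted last; graph rings are drawn as radial bars (positive heights
#' outward and negative inward of the ring midline in \code{mean_skew}
#' mode, upward from the inner edge in \code{zero_to_max} mode); contig
#' rings alternate red/blue; annotation labels sit at the feature midpoint
#' angle, nudged apart by a deterministic greedy pass, with leader lines
#' when placed outside. The legend shows each BLAST ring's color at the
#' opacities of its lower, midpoint and upper identity. SVGZ output is the
#' gzip stream of the identical SVG bytes.
#'
#' @param model an \linkS4class{ImageModel}.
#' @param path output file path.
#' @param format \code{"svg"} or \code{"svgz"}.
#' @param imageSize image width/height in px.
#' @param innerRadius inner radius of the ring stack in px; default 25% of
#'   the half-width.
#' @param spacing radial gap between rings in px.
#' @return \code{path}, invisibly.
#' @export
renderSVG <- function(model, path, format = c("svg", "svgz"),
                      imageSize = 3000, innerRadius = 0.25 * imageSize / 2,
                      spacing = 2) {
  format <- match.arg(format)
  stopifnot(is(model, "ImageModel"))
  svg <- composeSVG(model, imageSize, innerRadius, spacing)
  bytes <- charToRaw(svg)
  if (format == "svgz") {
    con <- gzfile(path, "wb")
    writeBin(bytes, con)
    close(con)
  } else {
    con <- file(path, "wb")
    writeBin(bytes, con)
    close(con)
  }
  invisible(path)
}

composeSVG <- function(model, imageSize, innerRadius, spacing) {
  L <- refLength(model@refmap)
  specs <- lapply(model@rings, function(r) r$spec)
  layout <- layoutRings(specs, innerRadius, spacing, imageSize)
  cx <- layout$center[1]; cy <- layout$center[2]
  out <- character(0)
  add <- function(...) out <<- c(out, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
    imageSize, imageSize, imageSize, imageSize))
  add(sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>',
              imageSize, imageSize))
  if (nzchar(model@title))
    add(sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="middle">%s</text>',
      fmtNum(cx), fmtNum(0.035 * imageSize), fmtNum(0.025 * imageSize),
      svgEscape(model@title)))
  # reference backbone circle at the inner edge of the ring stack
  add(sprintf(
    '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#000000" stroke-width="%s"/>',
    fmtNum(cx), fmtNum(cy), fmtNum(innerRadius - 0.006 * imageSize),
    fmtNum(0.0012 * imageSize)))
  # rings
  for (i in seq_along(model@rings)) {
    ring <- model@rings[[i]]
    rIn <- layout$radii$inner[i]; rOut <- layout$radii$outer[i]
    kind <- ring$spec@kind
    add(sprintf('<g id="ring-%d" class="ring-%s">', i, kind))
    if (kind == "blast") {
      arcs <- ring$arcs
      if (nrow(arcs)) {
        for (j in order(arcs$z)) {
          d <- arcPath(rIn, rOut, bpToAngle(arcs$start[j], L),
                       bpToAngle(arcs$end[j], L), cx, cy)
          add(sprintf('<path class="hit" d="%s" fill="%s" fill-opacity="%s"/>',
                      d, arcs$color[j], fmtNum(arcs$opacity[j])))
        }
      }
    } else if (kind == "graph") {
      h <- ring$heights
      mode <- ring$spec@graphMode
      mid <- (rIn + rOut) / 2
      half <- (rOut - rIn) / 2
      if (mode == "mean_skew")
        add(sprintf(
          '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#888888" stroke-width="%s"/>',
          fmtNum(cx), fmtNum(cy), fmtNum(mid), fmtNum(0.0004 * imageSize)))
      for (j in seq_len(nrow(h))) {
        if (h$height[j] == 0) next
        if (mode == "mean_skew") {
          r0 <- mid; r1 <- mid + h$height[j] * half
        } else {
          r0 <- rIn; r1 <- rIn + h$height[j] * (rOut - rIn)
        }
        lo <- min(r0, r1); hi <- max(r0, r1)
        if (hi - lo < 1e-9) next
        d <- arcPath(lo, hi, bpToAngle(h$start[j], L),
                     bpToAngle(h$end[j], L), cx, cy)
        add(sprintf('<path class="bar" d="%s" fill="%s"/>',
                    d, ring$spec@color))
      }
    } else if (kind == "contigs") {
      seg <- ring$segments
      for (j in seq_len(nrow(seg))) {
        d <- arcPath(rIn, rOut, bpToAngle(seg$start[j], L),
                     bpToAngle(seg$end[j], L), cx, cy)
        add(sprintf('<path class="contig" d="%s" fill="%s"/>',
                    d, contigRingColors[seg$colorIndex[j] + 1L]))
      }
    } else if (kind == "annotations") {
      ann <- ring$annotations
      for (j in seq_len(nrow(ann))) {
        d <- arcPath(rIn, rOut, bpToAngle(ann$start[j], L),
                     bpToAngle(ann$end[j], L), cx, cy)
        add(sprintf('<path class="feature" d="%s" fill="%s"/>',
                    d, ann$color[j]))
      }
    }
    add('</g>')
  }
  out <- c(out, renderTicks(model, layout, L, imageSize))
  out <- c(out, renderLabels(model, layout, L, imageSize))
  out <- c(out, renderLegend(model, imageSize))
  out <- c(out, '</svg>')
  paste0(paste(out, collapse = "\n"), "\n")
}

renderTicks <- function(model, layout, L, imageSize) {
  cx <- layout$center[1]; cy <- layout$center[2]
  rT <- if (nrow(layout$radii)) max(layout$radii$outer) else
    layout$labelRadius
  ticks <- tickPositions(L, model@tickMajor, model@tickMinor)
  out <- c('<g id="ticks">')
  lenMajor <- 0.01 * imageSize
  lenMinor <- 0.005 * imageSize
  sw <- fmtNum(0.0008 * imageSize)
  for (p in ticks$minor) {
    t <- bpToAngle(p, L)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="%s"/>',
      fmtNum(polarX(cx, rT, t)), fmtNum(polarY(cy, rT, t)),
      fmtNum(polarX(cx, rT + lenMinor, t)), fmtNum(polarY(cy, rT + lenMinor, t)),
      sw))
  }
  for (p in ticks$major) {
    t <- bpToAngle(p, L)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="%s"/>',
      fmtNum(polarX(cx, rT, t)), fmtNum(polarY(cy, rT, t)),
      fmtNum(polarX(cx, rT + lenMajor, t)), fmtNum(polarY(cy, rT + lenMajor, t)),
      sw))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="middle">%s</text>',
      fmtNum(polarX(cx, rT + 2.2 * lenMajor, t)),
      fmtNum(polarY(cy, rT + 2.2 * lenMajor, t)),
      fmtNum(0.009 * imageSize), svgEscape(formatBpLabel(p, L))))
  }
  c(out, '</g>')
}

# Deterministic greedy label anti-collision: labels sorted by angle; any
# label closer to its predecessor than the minimum separation is nudged
# clockwise.
nudgeAngles <- function(angles, minSep) {
  ord <- order(angles)
  a <- angles[ord]
  for (i in seq_along(a)[-1]) {
    if (a[i] - a[i - 1] < minSep) a[i] <- a[i - 1] + minSep
  }
  angles[ord] <- a
  angles
}

renderLabels <- function(model, layout, L, imageSize) {
  ann <- model@annotations
  ann <- ann[nzchar(ann$label), , drop = FALSE]
  if (nrow(ann) == 0L) return(character(0))
  cx <- layout$center[1]; cy <- layout$center[2]
  fs <- 0.009 * imageSize
  rLab <- layout$labelRadius + 0.035 * imageSize
  rEdge <- if (nrow(layout$radii)) max(layout$radii$outer) else rLab
  mids <- bpToAngle((ann$start + ann$end) / 2, L)
  lab <- nudgeAngles(mids, minSep = 1.1 * fs / rLab)
  out <- c('<g id="labels">')
  for (j in seq_len(nrow(ann))) {
    t0 <- mids[j]; t1 <- lab[j]
    if (identical(ann$placement[j], "outside")) {
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#555555" stroke-width="%s"/>',
        fmtNum(polarX(cx, rEdge, t0)), fmtNum(polarY(cy, rEdge, t0)),
        fmtNum(polarX(cx, rLab - 0.004 * imageSize, t1)),
        fmtNum(polarY(cy, rLab - 0.004 * imageSize, t1)),
        fmtNum(0.0004 * imageSize)))
      r <- rLab
      anchor <- if (sin(t1) >= 0) "start" else "end"
    } else {
      r <- max(0.3 * rEdge, rEdge - 0.08 * imageSize)
      anchor <- "middle"
    }
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="%s" fill="%s">%s</text>',
      fmtNum(polarX(cx, r, t1)), fmtNum(polarY(cy, r, t1)), fmtNum(fs),
      anchor, ann$color[j], svgEscape(ann$label[j])))
  }
  c(out, '</g>')
}

renderLegend <- function(model, imageSize) {
  lg <- model@legend
  if (nrow(lg) == 0L) return(character(0))
  out <- c('<g id="legend">')
  x0 <- 0.02 * imageSize
  y <- 0.05 * imageSize
  sw <- 0.014 * imageSize
  fs <- 0.011 * imageSize
  for (i in seq_len(nrow(lg))) {
    mid <- (lg$lower[i] + lg$upper[i]) / 2
    ops <- identityToOpacity(c(lg$lower[i], mid, lg$upper[i]),
                             lg$lower[i], lg$upper[i])
    labels <- sprintf("%g%%", c(lg$lower[i], mid, lg$upper[i]))
    for (k in 1:3) {
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" fill-opacity="%s" stroke="#000000" stroke-width="0.5"/>',
        fmtNum(x0 + (k - 1) * 1.1 * sw), fmtNum(y), fmtNum(sw), fmtNum(sw),
        lg$color[i], fmtNum(ops[k])))
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="middle">%s</text>',
        fmtNum(x0 + (k - 0.5) * 1.1 * sw), fmtNum(y + sw + fs),
        fmtNum(0.8 * fs), labels[k]))
    }
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="start">%s</text>',
      fmtNum(x0 + 3.5 * 1.1 * sw), fmtNum(y + 0.75 * sw), fmtNum(fs),
      svgEscape(lg$text[i])))
    y <- y + 2.2 * sw
  }
  c(out, '</g>')
}

#' Read an SVGZ file back to its SVG text
#'
#' @param path .svgz path.
#' @return the decompressed SVG as a single string.
#' @export
readSvgz <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = 64 * 1024 * 1024)
  rawToChar(raw)
}
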