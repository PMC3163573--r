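#' Map percent identity to drawing opacity
#'
#' The identity gradient of BLAST rings: hits below \code{lower} are omitted
#' (returned as \code{NA}), hits at or above \code{upper} are fully opaque,
#' and in between the opacity rises linearly from a minimum visible opacity
#' of 0.1 at \code{lower} to 1 at \code{upper}, so the faintest kept match
#' remains visible.
#'
#' @param pident percent identity (vectorised).
#' @param lower,upper gradient thresholds in percent, \code{lower <= upper}.
#' @param opacityMin opacity assigned at the lower threshold.
#' @return numeric vector of opacities in (0, 1]; \code{NA} marks omitted
#'   hits.
#' @export
identityToOpacity <- function(pident, lower, upper, opacityMin = 0.1) {
  if (any(lower > upper)) stop("need lower <= upper")
  ifelse(pident < lower, NA_real_,
    ifelse(pident >= upper, 1,
      opacityMin + (1 - opacityMin) * (pident - lower) / (upper - lower)))
}

# Split an arc crossing the origin of a circular reference into two pieces.
wrapSplitArcs <- function(arcs, L) {
  if (nrow(arcs) == 0L) return(arcs)
  over <- arcs$end > L
  if (!any(over)) return(arcs)
  first <- arcs
  first$end[over] <- L
  second <- arcs[over, , drop = FALSE]
  second$end <- second$end - L
  second$start <- 0
  out <- rbind(first, second)
  out <- out[order(out$z, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve a BLAST ring into drawable arcs
#'
#' Pools the hits of all member sources of a (possibly collated) ring,
#' applies the ring's identity thresholds through the opacity gradient
#' (hits below the lower threshold are omitted entirely, leaving the
#' blank/white regions that signal absence), orients hits onto the
#' reference, sorts ascending by bitscore and assigns increasing z so the
#' highest-scoring hits are drawn last and painted on top. Arcs crossing
#' the origin of a circular reference are split in two.
#'
#' @param hitSets named list of hit data.frames, one per data source.
#' @param spec the ring's \linkS4class{RingSpec} (kind \code{"blast"}).
#' @param refmap the \linkS4class{ReferenceMap}.
#' @return data.frame of arcs: start, end, color, opacity, z, bitscore.
#' @export
buildBlastRing <- function(hitSets, spec, refmap) {
  stopifnot(is(spec, "RingSpec"))
  if (spec@kind != "blast") stop("spec kind must be 'blast'")
  missing <- setdiff(spec@members, names(hitSets))
  if (length(missing))
    stop("no loaded data for ring member '", missing[1], "'")
  pooled <- do.call(rbind, c(lapply(spec@members, function(m) hitSets[[m]]),
                             list(emptyHits())))
  rownames(pooled) <- NULL
  emptyArcs <- data.frame(start = numeric(0), end = numeric(0),
                          color = character(0), opacity = numeric(0),
                          z = numeric(0), bitscore = numeric(0),
                          stringsAsFactors = FALSE)
  if (nrow(pooled) == 0L) return(emptyArcs)
  op <- identityToOpacity(pooled$pident, spec@lowerIdentity,
                          spec@upperIdentity)
  keep <- !is.na(op)
  pooled <- pooled[keep, , drop = FALSE]
  op <- op[keep]
  if (nrow(pooled) == 0L) return(emptyArcs)
  iv <- orientToReference(pooled)
  L <- refLength(refmap)
  if (any(iv$end > L))
    stop("hit subject coordinates exceed the reference length")
  ord <- order(pooled$bitscore)           # stable ascending draw order
  arcs <- data.frame(
    start = iv$start[ord], end = iv$end[ord],
    color = spec@color, opacity = op[ord],
    z = seq_along(ord), bitscore = pooled$bitscore[ord],
    stringsAsFactors = FALSE
  )
  wrapSplitArcs(arcs, L)
}

#' Resolve a graph ring into renderer heights
#'
#' \code{mean_skew} mode centres the track on its mean and scales it so the
#' largest absolute deviation reaches height 1 (an all-constant track gives
#' a flat zero profile); heights are signed and drawn around the ring
#' midline. \code{zero_to_max} mode clamps to [0, graphMax] and scales to
#' [0, 1], drawn from the ring's inner edge.
#'
#' @param track a \linkS4class{ValueTrack}.
#' @param spec the ring's \linkS4class{RingSpec} (kind \code{"graph"}).
#' @return data.frame with columns start, end, height.
#' @export
buildGraphRing <- function(track, spec) {
  stopifnot(is(spec, "RingSpec"))
  if (spec@kind != "graph") stop("spec kind must be 'graph'")
  b <- trackBins(track)
  if (spec@graphMode == "mean_skew") {
    centered <- b$value - lengthWeightedMean(b)
    mx <- max(abs(centered))
    h <- if (mx == 0) rep(0, length(centered)) else centered / mx
  } else {
    h <- pmin(pmax(b$value, 0), spec@graphMax) / spec@graphMax
  }
  data.frame(start = b$start, end = b$end, height = h)
}

#' Assemble the renderer-ready image model
#'
#' Resolves every ring specification against the loaded data, in declared
#' (innermost-first) order, into a deterministic \linkS4class{ImageModel}:
#' the same profile and data always produce the identical model, and hence
#' byte-identical SVG. Blast rings resolve via \code{\link{buildBlastRing}},
#' graph rings via \code{\link{buildGraphRing}} (applied to the member
#' track), contig rings via \code{\link{contigBoundaries}}, annotation rings
#' collect their member annotation tables. Sources may be shared between
#' rings.
#'
#' @param refmap the \linkS4class{ReferenceMap}.
#' @param rings ordered list of \linkS4class{RingSpec}.
#' @param hitSets named list of hit data.frames (blast ring members).
#' @param tracks named list of \linkS4class{ValueTrack} (graph ring members).
#' @param annotationSets named list of annotation data.frames.
#' @param tickMajor,tickMinor tick intervals in bp (defaults chosen from the
#'   reference length: major = a round tenth, minor = major/5).
#' @param title image title.
#' @return An \linkS4class{ImageModel}.
#' @export
assembleImage <- function(refmap, rings = list(), hitSets = list(),
                          tracks = list(), annotationSets = list(),
                          tickMajor = NULL, tickMinor = NULL, title = "") {
  stopifnot(is(refmap, "ReferenceMap"))
  L <- refLength(refmap)
  if (is.null(tickMajor)) tickMajor <- defaultTickInterval(L)
  if (is.null(tickMinor)) tickMinor <- tickMajor / 5
  resolved <- list()
  legend <- data.frame(text = character(0), color = character(0),
                       lower = numeric(0), upper = numeric(0),
                       stringsAsFactors = FALSE)
  annotations <- data.frame(start = numeric(0), end = numeric(0),
                            label = character(0), color = character(0),
                            decoration = character(0),
                            placement = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(rings)) {
    spec <- rings[[i]]
    stopifnot(is(spec, "RingSpec"))
    entry <- list(spec = spec)
    if (spec@kind == "blast") {
      entry$arcs <- buildBlastRing(hitSets, spec, refmap)
      legend <- rbind(legend, data.frame(
        text = if (nzchar(spec@legendText)) spec@legendText
               else paste(spec@members, collapse = "+"),
        color = spec@color, lower = spec@lowerIdentity,
        upper = spec@upperIdentity, stringsAsFactors = FALSE))
    } else if (spec@kind == "graph") {
      m <- spec@members[1]
      if (is.null(tracks[[m]]))
        stop("no loaded track for ring member '", m, "'")
      entry$heights <- buildGraphRing(tracks[[m]], spec)
    } else if (spec@kind == "contigs") {
      entry$segments <- contigBoundaries(refmap)
    } else if (spec@kind == "annotations") {
      m <- spec@members[1]
      if (is.null(annotationSets[[m]]))
        stop("no loaded annotations for ring member '", m, "'")
      ann <- annotationSets[[m]]
      annotations <- rbind(annotations, ann)
      entry$annotations <- ann
    }
    resolved[[i]] <- entry
  }
  new("ImageModel", refmap = refmap, rings = resolved,
      annotations = annotations, tickMajor = as.numeric(tickMajor),
      tickMinor = as.numeric(tickMinor), title = as.character(title),
      legend = legend)
}

# A round tick interval: the largest power-of-ten step giving >= 5 major
# ticks, halved or fifthed to land between 5 and 20 ticks.
defaultTickInterval <- function(L) {
  raw <- L / 10
  mag <- 10^floor(log10(raw))
  for (m in c(1, 2, 5, 10)) {
    if (raw <= m * mag) return(m * mag)
  }
  10 * mag
}
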