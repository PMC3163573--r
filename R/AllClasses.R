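#' ReferenceMap: the concatenated central coordinate system
#'
#' One or more reference sequences are concatenated, in input order, into a
#' single circular coordinate system: the central ring of the image. Each
#' segment keeps its name, its 0-based offset into the concatenated
#' coordinates and its length.
#'
#' @slot segments data.frame with columns \code{name}, \code{offset} (0-based
#'   bp), \code{length} (bp), one row per input sequence in input order.
#' @slot totalLength total concatenated length in bp.
#' @slot circular whether the coordinate system wraps at \code{totalLength}.
#' @export
setClass("ReferenceMap",
  representation(
    segments = "data.frame",
    totalLength = "numeric",
    circular = "logical"
  )
)

setValidity("ReferenceMap", function(object) {
  seg <- object@segments
  msgs <- character(0)
  if (!all(c("name", "offset", "length") %in% names(seg)))
    return("segments must have columns name, offset, length")
  if (nrow(seg) == 0L)
    msgs <- c(msgs, "at least one segment required")
  if (nrow(seg) > 0L) {
    if (any(seg$length <= 0))
      msgs <- c(msgs, "segment lengths must be positive")
    expOff <- cumsum(c(0, seg$length))[seq_len(nrow(seg))]
    if (!isTRUE(all.equal(as.numeric(seg$offset), as.numeric(expOff))))
      msgs <- c(msgs, "offsets must be the cumulative sum of preceding lengths")
    if (!isTRUE(all.equal(object@totalLength, sum(seg$length))))
      msgs <- c(msgs, "totalLength must equal the sum of segment lengths")
  }
  if (length(msgs)) msgs else TRUE
})

#' ValueTrack: a numeric track over the reference
#'
#' A piecewise-constant numeric signal over reference coordinates, stored as
#' run-length-compacted bins so multi-megabase per-base tracks stay small.
#' Bins are 0-based half-open, sorted and non-overlapping. The length-weighted
#' mean and population standard deviation are precomputed at construction.
#'
#' @slot bins data.frame with columns \code{start}, \code{end}, \code{value}.
#' @slot referenceLength bp length of the coordinate system the track covers.
#' @slot trackMean length-weighted mean of the bin values.
#' @slot trackSD length-weighted population standard deviation.
#' @export
setClass("ValueTrack",
  representation(
    bins = "data.frame",
    referenceLength = "numeric",
    trackMean = "numeric",
    trackSD = "numeric"
  )
)

setValidity("ValueTrack", function(object) {
  b <- object@bins
  if (!all(c("start", "end", "value") %in% names(b)))
    return("bins must have columns start, end, value")
  if (nrow(b) == 0L) return(TRUE)
  if (any(b$end <= b$start)) return("bin end must exceed bin start")
  if (is.unsorted(b$start)) return("bins must be sorted by start")
  if (any(b$start[-1L] < b$end[-nrow(b)])) return("bins must not overlap")
  if (b$start[1L] < 0 || any(b$end > object@referenceLength))
    return("bins must lie within [0, referenceLength]")
  TRUE
})

#' Construct a ValueTrack from bins
#'
#' @param bins data.frame with columns \code{start}, \code{end} (0-based
#'   half-open bp) and \code{value}.
#' @param referenceLength length in bp of the underlying coordinate system.
#' @return A \linkS4class{ValueTrack}.
#' @export
ValueTrack <- function(bins, referenceLength) {
  bins <- as.data.frame(bins)[, c("start", "end", "value")]
  if (nrow(bins)) bins <- bins[order(bins$start), , drop = FALSE]
  rownames(bins) <- NULL
  m <- if (nrow(bins)) lengthWeightedMean(bins) else NA_real_
  s <- if (nrow(bins)) lengthWeightedSD(bins) else NA_real_
  new("ValueTrack", bins = bins, referenceLength = as.numeric(referenceLength),
      trackMean = m, trackSD = s)
}

#' RingSpec: the declarative description of one ring
#'
#' @slot kind one of \code{"blast"}, \code{"graph"}, \code{"contigs"},
#'   \code{"annotations"}.
#' @slot members data-source ids drawn in this ring; more than one only for
#'   collated \code{blast} rings.
#' @slot color hex \code{"#RRGGBB"} fill color of the ring.
#' @slot width relative radial width (arbitrary units, scaled at layout).
#' @slot lowerIdentity,upperIdentity percent-identity thresholds of the
#'   opacity gradient; hits below \code{lowerIdentity} are omitted.
#' @slot legendText legend label for the ring.
#' @slot graphMode \code{"mean_skew"} (signed deviation from the mean) or
#'   \code{"zero_to_max"} (clamped to \code{[0, graphMax]}).
#' @slot graphMax user-defined maximum for \code{zero_to_max} scaling.
#' @export
setClass("RingSpec",
  representation(
    kind = "character",
    members = "character",
    color = "character",
    width = "numeric",
    lowerIdentity = "numeric",
    upperIdentity = "numeric",
    legendText = "character",
    graphMode = "character",
    graphMax = "numeric"
  )
)

setValidity("RingSpec", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("blast", "graph", "contigs", "annotations"))
    msgs <- c(msgs, "kind must be blast, graph, contigs or annotations")
  if (length(object@members) < 1L)
    msgs <- c(msgs, "at least one member required")
  if (length(object@members) > 1L && object@kind != "blast")
    msgs <- c(msgs, "only blast rings may collate multiple members")
  if (!isHexColor(object@color))
    msgs <- c(msgs, "color must be #RRGGBB")
  if (object@width <= 0) msgs <- c(msgs, "width must be positive")
  if (object@lowerIdentity < 0 || object@upperIdentity > 100 ||
      object@lowerIdentity > object@upperIdentity)
    msgs <- c(msgs, "need 0 <= lowerIdentity <= upperIdentity <= 100")
  if (!object@graphMode %in% c("mean_skew", "zero_to_max"))
    msgs <- c(msgs, "graphMode must be mean_skew or zero_to_max")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RingSpec
#'
#' @param kind ring kind: \code{"blast"}, \code{"graph"}, \code{"contigs"} or
#'   \code{"annotations"}.
#' @param members character vector of data-source ids.
#' @param color hex fill color.
#' @param width relative radial width.
#' @param lowerIdentity,upperIdentity identity gradient thresholds (percent).
#' @param legendText legend label.
#' @param graphMode graph scaling mode for \code{kind = "graph"}.
#' @param graphMax maximum for \code{zero_to_max} scaling.
#' @return A \linkS4class{RingSpec}.
#' @export
RingSpec <- function(kind, members, color = "#0000CC", width = 10,
                     lowerIdentity = 70, upperIdentity = 100,
                     legendText = "", graphMode = "mean_skew",
                     graphMax = 1) {
  new("RingSpec", kind = kind, members = as.character(members), color = color,
      width = as.numeric(width), lowerIdentity = as.numeric(lowerIdentity),
      upperIdentity = as.numeric(upperIdentity),
      legendText = as.character(legendText), graphMode = graphMode,
      graphMax = as.numeric(graphMax))
}

#' ImageModel: the renderer-ready resolved image
#'
#' The output of \code{\link{assembleImage}}: every ring specification has
#' been resolved against loaded data into arcs (with color, opacity and
#' z-order), graph profiles or contig segments, annotations have been
#' collected, and tick intervals fixed. Rendering an ImageModel is a pure
#' function: identical models give byte-identical SVG.
#'
#' @slot refmap the \linkS4class{ReferenceMap}.
#' @slot rings list of resolved rings, innermost first; each element is a list
#'   with the originating \code{spec} and its resolved payload (\code{arcs},
#'   \code{heights}, or \code{segments}).
#' @slot annotations data.frame of feature annotations.
#' @slot tickMajor,tickMinor tick intervals in bp.
#' @slot title image title.
#' @slot legend data.frame of legend entries.
#' @export
setClass("ImageModel",
  representation(
    refmap = "ReferenceMap",
    rings = "list",
    annotations = "data.frame",
    tickMajor = "numeric",
    tickMinor = "numeric",
    title = "character",
    legend = "data.frame"
  )
)

#' RingProfile: a persistable session description
#'
#' Everything needed to regenerate an image: the reference descriptor, the
#' declared data sources, the ordered ring specifications, BLAST settings and
#' image settings. Profiles serialise losslessly to JSON with an explicit
#' \code{formatVersion}.
#'
#' @slot formatVersion profile format version token.
#' @slot reference list with \code{path}, \code{format}, \code{circular}.
#' @slot sources named list, id -> list(path, format, role).
#' @slot rings ordered list of \linkS4class{RingSpec}.
#' @slot blast list with \code{program}, \code{minIdentity},
#'   \code{maxEvalue}, \code{extraOptions}.
#' @slot image list with \code{size}, \code{tickMajor}, \code{tickMinor},
#'   \code{title}, \code{format}.
#' @export
setClass("RingProfile",
  representation(
    formatVersion = "character",
    reference = "list",
    sources = "list",
    rings = "list",
    blast = "list",
    image = "list"
  )
)

setValidity("RingProfile", function(object) {
  msgs <- character(0)
  if (!identical(object@formatVersion, profileFormatVersion()))
    msgs <- c(msgs, sprintf("unknown formatVersion '%s'", object@formatVersion))
  ids <- names(object@sources)
  for (r in object@rings) {
    bad <- setdiff(r@members, ids)
    if (length(bad))
      msgs <- c(msgs, sprintf("ring member id '%s' is not a declared source", bad[1]))
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname RingProfile-class
#' @export
profileFormatVersion <- function() "1.0"

## Accessors ------------------------------------------------------------

#' @describeIn ReferenceMap-class total concatenated length in bp.
#' @param x a ReferenceMap.
#' @export
refLength <- function(x) x@totalLength

#' @describeIn ReferenceMap-class segment table (name, offset, length).
#' @export
refSegments <- function(x) x@segments

#' @describeIn ReferenceMap-class whether coordinates wrap at totalLength.
#' @export
isCircular <- function(x) x@circular

#' @describeIn ValueTrack-class bin table (start, end, value).
#' @param x a ValueTrack.
#' @export
trackBins <- function(x) x@bins

#' @describeIn ValueTrack-class length-weighted mean of the track.
#' @export
trackMean <- function(x) x@trackMean

#' @describeIn ValueTrack-class length-weighted population SD of the track.
#' @export
trackSD <- function(x) x@trackSD

#' @describeIn ValueTrack-class reference length the track covers (bp).
#' @export
trackLength <- function(x) x@referenceLength

## show methods ---------------------------------------------------------

setMethod("show", "ReferenceMap", function(object) {
  cat(sprintf("ReferenceMap: %d segment(s), %s bp total, %s\n",
              nrow(object@segments),
              format(object@totalLength, big.mark = ","),
              if (object@circular) "circular" else "linear"))
  print(utils::head(object@segments, 5L))
  if (nrow(object@segments) > 5L)
    cat(sprintf("... and %d more segments\n", nrow(object@segments) - 5L))
})

setMethod("show", "ValueTrack", function(object) {
  cat(sprintf(
    "ValueTrack: %d bin(s) over %s bp; mean %.4g, sd %.4g\n",
    nrow(object@bins), format(object@referenceLength, big.mark = ","),
    object@trackMean, object@trackSD))
})

setMethod("show", "RingSpec", function(object) {
  cat(sprintf("RingSpec<%s>: members [%s], color %s, width %g",
              object@kind, paste(object@members, collapse = ", "),
              object@color, object@width))
  if (object@kind == "blast")
    cat(sprintf(", identity %g-%g%%", object@lowerIdentity,
                object@upperIdentity))
  cat("\n")
})

setMethod("show", "ImageModel", function(object) {
  cat(sprintf("ImageModel: %s bp reference, %d ring(s), %d annotation(s)\n",
              format(object@refmap@totalLength, big.mark = ","),
              length(object@rings), nrow(object@annotations)))
})

setMethod("show", "RingProfile", function(object) {
  cat(sprintf("RingProfile v%s: %d source(s), %d ring(s)\n",
              object@formatVersion, length(object@sources),
              length(object@rings)))
})
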