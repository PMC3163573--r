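#' Construct a session profile
#'
#' @param reference list with \code{path}, \code{format} (fasta/genbank/
#'   embl) and \code{circular} flag describing the reference sequence(s).
#' @param sources named list; each element a list with \code{path},
#'   \code{format} and \code{role}. Roles: \code{"query"} (FASTA queried
#'   with BLAST), \code{"tabular"} (precomputed BLAST tabular),
#'   \code{"graph"} (custom graph file), \code{"sam"}, \code{"ace"}
#'   (coverage sources), \code{"annotations"} (tab-delimited annotation
#'   table), \code{"features"} (GenBank/EMBL feature extraction; add
#'   \code{featureKey} and \code{qualifierSubstring}), \code{"headers"}
#'   (annotations from the reference segment names; path unused).
#' @param rings ordered list of \linkS4class{RingSpec}, innermost first.
#' @param blast list: \code{program}, \code{minIdentity}, \code{maxEvalue},
#'   \code{extraOptions}.
#' @param image list: \code{size}, \code{tickMajor}, \code{tickMinor},
#'   \code{title}, \code{format}.
#' @return A \linkS4class{RingProfile}.
#' @export
ringProfile <- function(reference, sources = list(), rings = list(),
                        blast = list(), image = list()) {
  blastDefaults <- list(program = "blastn", minIdentity = 0, maxEvalue = 10,
                        extraOptions = character(0))
  imageDefaults <- list(size = 3000, tickMajor = NULL, tickMinor = NULL,
                        title = "", format = "svg")
  blast <- utils::modifyList(blastDefaults, blast)
  image <- utils::modifyList(imageDefaults, image,
                             keep.null = TRUE)
  new("RingProfile", formatVersion = profileFormatVersion(),
      reference = reference, sources = sources, rings = rings,
      blast = blast, image = image)
}

ringSpecToList <- function(s) {
  list(kind = s@kind, members = as.list(s@members), color = s@color,
       width = s@width, lowerIdentity = s@lowerIdentity,
       upperIdentity = s@upperIdentity, legendText = s@legendText,
       graphMode = s@graphMode, graphMax = s@graphMax)
}

ringSpecFromList <- function(x) {
  RingSpec(kind = x$kind, members = unlist(x$members), color = x$color,
           width = x$width, lowerIdentity = x$lowerIdentity,
           upperIdentity = x$upperIdentity, legendText = x$legendText,
           graphMode = x$graphMode, graphMax = x$graphMax)
}

#' Save and load profiles
#'
#' Profiles serialise to JSON with an explicit \code{formatVersion};
#' \code{loadProfile(saveProfile(p))} reproduces the profile field for
#' field. Loading validates the version and that every ring member id is a
#' declared source, reporting the offending id otherwise.
#'
#' @param profile a \linkS4class{RingProfile}.
#' @param path JSON file path.
#' @return \code{saveProfile}: \code{path}, invisibly. \code{loadProfile}:
#'   the \linkS4class{RingProfile}.
#' @export
saveProfile <- function(profile, path) {
  stopifnot(is(profile, "RingProfile"))
  methods::validObject(profile)
  obj <- list(
    formatVersion = profile@formatVersion,
    reference = profile@reference,
    sources = profile@sources,
    rings = lapply(profile@rings, ringSpecToList),
    blast = profile@blast,
    image = profile@image
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname saveProfile
#' @export
loadProfile <- function(path) {
  if (!file.exists(path)) stop("cannot read profile '", path, "'")
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$formatVersion) ||
      !identical(obj$formatVersion, profileFormatVersion()))
    stop("unknown profile formatVersion '", obj$formatVersion %||% "<none>",
         "'; this build reads version ", profileFormatVersion())
  asChr <- function(x) if (is.null(x)) character(0) else
    as.character(unlist(x))
  blast <- obj$blast
  blast$extraOptions <- asChr(blast$extraOptions)
  image <- obj$image
  p <- ringProfile(
    reference = lapply(obj$reference, identity),
    sources = lapply(obj$sources, function(s) lapply(s, identity)),
    rings = lapply(obj$rings, ringSpecFromList),
    blast = blast,
    image = image
  )
  methods::validObject(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in template profiles
#'
#' Named starting points with size and identity-gradient settings tuned for
#' the common use cases: \code{"small-genome"} (a single plasmid-to-small
#' chromosome reference, fine ticks), \code{"large-genome"} (a megabase
#' chromosome, coarse ticks, 3000 px canvas) and \code{"gene-panel"} (a
#' concatenated multi-gene reference with header labels and tblastx-friendly
#' thresholds).
#'
#' @param name template name.
#' @return A \linkS4class{RingProfile} with placeholder source paths.
#' @export
templateProfile <- function(name = c("small-genome", "large-genome",
                                     "gene-panel")) {
  name <- match.arg(name)
  ring1 <- RingSpec("blast", "query1", color = "#CC0000", width = 20,
                    lowerIdentity = 70, upperIdentity = 100,
                    legendText = "query1")
  base <- switch(name,
    "small-genome" = ringProfile(
      reference = list(path = "reference.fasta", format = "fasta",
                       circular = TRUE),
      sources = list(query1 = list(path = "query1.fasta", format = "fasta",
                                   role = "query")),
      rings = list(ring1),
      blast = list(program = "blastn", minIdentity = 70, maxEvalue = 1e-5),
      image = list(size = 2000, title = "small genome comparison")),
    "large-genome" = ringProfile(
      reference = list(path = "reference.fasta", format = "fasta",
                       circular = TRUE),
      sources = list(query1 = list(path = "query1.fasta", format = "fasta",
                                   role = "query")),
      rings = list(ring1),
      blast = list(program = "blastn", minIdentity = 70, maxEvalue = 1e-10),
      image = list(size = 3000, title = "whole genome comparison")),
    "gene-panel" = ringProfile(
      reference = list(path = "panel.fasta", format = "fasta",
                       circular = FALSE),
      sources = list(query1 = list(path = "query1.fasta", format = "fasta",
                                   role = "query"),
                     headers = list(path = "", format = "fasta",
                                    role = "headers")),
      rings = list(RingSpec("blast", "query1", color = "#CC0000", width = 20,
                            lowerIdentity = 50, upperIdentity = 100,
                            legendText = "query1"),
                   RingSpec("annotations", "headers", color = "#000000",
                            width = 8)),
      blast = list(program = "tblastx", minIdentity = 50, maxEvalue = 1e-5),
      image = list(size = 2000, title = "gene panel"))
  )
  base
}
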