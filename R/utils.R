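#' @import methods
#' @importFrom stats runif rbinom
#' @importFrom utils head tail
NULL

# Run code with a private RNG stream: the global .Random.seed is saved and
# restored so generators are pure functions of their explicit seed.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fixed-format number for SVG output; byte-determinism depends on this.
fmtNum <- function(x) sprintf("%.4f", x)

isHexColor <- function(x) {
  is.character(x) & grepl("^#[0-9A-Fa-f]{6}$", x)
}

# Run-length compact a per-base numeric vector into (start, end, value) bins,
# 0-based half-open. Zero-valued runs are kept so tracks tile their reference.
compactRuns <- function(values) {
  if (length(values) == 0L)
    return(data.frame(start = integer(0), end = integer(0), value = numeric(0)))
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts, end = ends, value = r$values)
}

# Expand a binned track to a per-base vector of length L (gaps filled with 0).
expandBins <- function(bins, L) {
  v <- numeric(L)
  if (nrow(bins)) {
    for (i in seq_len(nrow(bins))) {
      s <- bins$start[i]; e <- min(bins$end[i], L)
      if (e > s) v[(s + 1L):e] <- bins$value[i]
    }
  }
  v
}

lengthWeightedMean <- function(bins) {
  w <- bins$end - bins$start
  sum(bins$value * w) / sum(w)
}

lengthWeightedSD <- function(bins) {
  w <- bins$end - bins$start
  m <- sum(bins$value * w) / sum(w)
  sqrt(sum(w * (bins$value - m)^2) / sum(w))
}
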