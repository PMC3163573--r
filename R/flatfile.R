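# Minimal GenBank/EMBL flat-file reader: ids, descriptions, feature table
# (key, outer span, strand, qualifiers) and the ORIGIN/SQ sequence. Compound
# locations (join/complement/order) are flattened to their outer span; fuzzy
# end markers (< >) are ignored. Multi-record files split on '//'.

parseFlatFile <- function(path, format = c("genbank", "embl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  # split into records on terminator lines
  term <- grep("^//\\s*$", lines)
  if (length(term) == 0L && length(lines) > 0L) term <- length(lines) + 1L
  records <- list()
  from <- 1L
  for (t in term) {
    chunk <- lines[seq(from, min(t - 1L, length(lines)))]
    if (any(nzchar(trimws(chunk)))) {
      records[[length(records) + 1L]] <-
        if (format == "genbank") parseGenbankRecord(chunk)
        else parseEmblRecord(chunk)
    }
    from <- t + 1L
  }
  records
}

parseGenbankRecord <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("GenBank record lacks a LOCUS line")
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  desc <- ""
  di <- grep("^DEFINITION", lines)
  if (length(di)) {
    j <- di[1]
    parts <- sub("^DEFINITION\\s*", "", lines[j])
    j <- j + 1L
    while (j <= length(lines) && grepl("^\\s{2,}\\S", lines[j]) &&
           !grepl("^\\s{5}\\S", lines[j])) {
      parts <- c(parts, trimws(lines[j])); j <- j + 1L
    }
    desc <- sub("\\.$", "", paste(parts, collapse = " "))
  }
  fi <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|BASE COUNT|CONTIG)", lines)
  features <- list()
  if (length(fi)) {
    stopAt <- if (length(fend)) min(fend[fend > fi[1]]) else length(lines) + 1L
    if (fi[1] + 1L <= stopAt - 1L)
      features <- parseFeatureBlock(lines[(fi[1] + 1L):(stopAt - 1L)],
                                    keyPattern = "^\\s{1,10}(\\S+)\\s+(\\S.*)$")
  }
  seq <- ""
  oi <- grep("^ORIGIN", lines)
  if (length(oi)) {
    body <- lines[seq(oi[1] + 1L, length(lines))]
    seq <- toupper(gsub("[^A-Za-z*]", "", paste(body, collapse = "")))
  }
  list(id = id, description = desc, sequence = seq, features = features)
}

parseEmblRecord <- function(lines) {
  idl <- grep("^ID\\s", lines, value = TRUE)
  if (length(idl) == 0L) stop("EMBL record lacks an ID line")
  id <- sub(";$", "", strsplit(trimws(sub("^ID\\s+", "", idl[1])), "\\s+")[[1]][1])
  del <- grep("^DE\\s", lines, value = TRUE)
  desc <- sub("\\.$", "", paste(trimws(sub("^DE\\s+", "", del)), collapse = " "))
  ft <- grep("^FT", lines, value = TRUE)
  features <- list()
  if (length(ft)) {
    # strip the FT tag; keep the column structure so key detection works
    body <- sub("^FT", "  ", ft)
    features <- parseFeatureBlock(body,
                                  keyPattern = "^\\s{1,10}(\\S+)\\s+(\\S.*)$")
  }
  seq <- ""
  si <- grep("^SQ", lines)
  if (length(si)) {
    body <- gsub("\\d+\\s*$", "", lines[seq(si[1] + 1L, length(lines))])
    seq <- toupper(gsub("[^A-Za-z*]", "", paste(body, collapse = "")))
  }
  list(id = id, description = desc, sequence = seq, features = features)
}

# Feature table parsing shared by both formats. A new feature starts on a
# line whose key sits in the left indent region; qualifier/location
# continuations are more deeply indented or begin with '/'.
parseFeatureBlock <- function(lines, keyPattern) {
  feats <- list()
  cur <- NULL
  curQualLines <- character(0)
  flush <- function() {
    if (is.null(cur)) return()
    cur$qualifiers <- parseQualifiers(curQualLines)
    span <- parseLocation(cur$location)
    cur$start <- span$start; cur$end <- span$end
    cur$complement <- span$complement
    feats[[length(feats) + 1L]] <<- cur
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    trimmed <- trimws(ln)
    indent <- attr(regexpr("^\\s*", ln), "match.length")
    isNew <- indent <= 10L && !startsWith(trimmed, "/") &&
      grepl("^\\S+\\s+\\S", trimmed)
    if (isNew) {
      flush()
      m <- regmatches(trimmed, regexec("^(\\S+)\\s+(\\S.*)$", trimmed))[[1]]
      cur <- list(key = m[2], location = m[3])
      curQualLines <- character(0)
    } else if (!is.null(cur)) {
      if (startsWith(trimmed, "/") || length(curQualLines) > 0L) {
        curQualLines <- c(curQualLines, trimmed)
      } else {
        cur$location <- paste0(cur$location, trimmed)  # wrapped location
      }
    }
  }
  flush()
  feats
}

parseQualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  # rejoin multi-line quoted values: a new qualifier starts at '/' when we
  # are not inside an open quote
  entries <- character(0)
  open <- FALSE
  for (ln in lines) {
    if (startsWith(ln, "/") && !open) {
      entries <- c(entries, ln)
    } else if (length(entries)) {
      sep <- if (grepl("^\\w", ln)) " " else ""
      entries[length(entries)] <- paste0(entries[length(entries)], sep, ln)
    }
    open <- (lengths(regmatches(entries[length(entries)],
                                gregexpr('"', entries[length(entries)]))) %% 2) == 1
  }
  quals <- list()
  for (e in entries) {
    m <- regmatches(e, regexec('^/([A-Za-z_0-9]+)(=(.*))?$', e))[[1]]
    if (length(m) == 0L) next
    key <- m[2]
    val <- if (nzchar(m[3])) gsub('^"|"$', "", m[4]) else TRUE
    if (!is.null(quals[[key]])) {
      quals[[key]] <- c(quals[[key]], val)
    } else {
      quals[[key]] <- val
    }
  }
  quals
}

parseLocation <- function(loc) {
  nums <- as.numeric(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) == 0L) stop("unparseable feature location: ", loc)
  list(start = min(nums), end = max(nums),
       complement = grepl("complement", loc, fixed = TRUE))
}
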