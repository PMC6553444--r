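#' Polarize an indel event against outgroup taxa
#'
#' The ancestral condition of the character is the outgroup condition over
#' the event span: all outgroups gapped across the span -> span_absent; all
#' outgroups carrying the span -> span_present; disagreement or a partial
#' outgroup -> the character is dropped (NULL, with a warning) rather than
#' guessed. Each taxon then scores 0 when it matches the ancestral
#' condition, 1 when it shows the full opposite condition, and ? when its
#' state over the span is partial. Polarity is deletion when the ancestral
#' span is present, insertion when absent.
#'
#' @param event one-row event data.frame.
#' @param aln an \linkS4class{RgcAlignment}.
#' @param outgroups character vector of outgroup taxon labels (non-empty).
#' @param nested_gap_tol tolerance for small nested gaps when reading a
#'   span as present (see \code{\link{rgcConfig}}).
#' @return list with \code{event_id}, \code{states} (named "0"/"1"/"?"
#'   vector over all alignment taxa), \code{ancestral_condition},
#'   \code{polarity}; or NULL when the outgroups conflict.
#' @export
polarizeEvent <- function(event, aln, outgroups, nested_gap_tol = 0.25) {
  stopifnot(nrow(event) == 1L, length(outgroups) >= 1L)
  missing_og <- setdiff(outgroups, taxa(aln))
  if (length(missing_og))
    stop("outgroup taxon missing from alignment: ",
         paste(missing_og, collapse = ", "))
  rows <- alnRows(aln)
  st <- vapply(taxa(aln), function(tx)
    .spanState(rows[[tx]], event$start, event$end, nested_gap_tol),
    character(1L))
  og <- st[outgroups]
  if (all(og == "absent")) ancestral <- "span_absent"
  else if (all(og == "present")) ancestral <- "span_present"
  else {
    warning("outgroup conflict over span of event ", event$id,
            "; character dropped")
    return(NULL)
  }
  anc_state <- if (ancestral == "span_present") "present" else "absent"
  opp_state <- if (ancestral == "span_present") "absent" else "present"
  states <- ifelse(st == anc_state, "0",
                   ifelse(st == opp_state, "1", "?"))
  names(states) <- taxa(aln)
  list(event_id = event$id, states = states,
       ancestral_condition = ancestral,
       polarity = if (ancestral == "span_present") "deletion"
                  else "insertion")
}

#' Assemble polarized characters into a binary matrix
#'
#' Characters that became invariant (no taxon in state 1) after
#' polarization are dropped with a message: they are detectable events
#' whose derived state is absent from the sample.
#'
#' @param chars list of results of \code{\link{polarizeEvent}} (NULL
#'   entries, from dropped characters, are ignored).
#' @return an \linkS4class{RgcBinaryMatrix} (possibly with 0 characters).
#' @export
buildBinaryMatrix <- function(chars) {
  chars <- Filter(Negate(is.null), chars)
  if (!length(chars)) {
    return(new("RgcBinaryMatrix",
               states = matrix(character(), 0L, 0L),
               info = data.frame(event_id = character(),
                                 ancestral_condition = character(),
                                 polarity = character(),
                                 stringsAsFactors = FALSE)))
  }
  tx <- names(chars[[1L]]$states)
  for (ch in chars)
    if (!identical(names(ch$states), tx))
      stop("characters do not share a taxa universe")
  keep <- vapply(chars, function(ch) any(ch$states == "1"), logical(1L))
  if (any(!keep))
    message(sum(!keep), " invariant (all-ancestral) character(s) dropped")
  chars <- chars[keep]
  st <- vapply(chars, `[[`, character(length(tx)), "states")
  st <- matrix(st, nrow = length(tx),
               dimnames = list(tx, vapply(chars, `[[`, character(1L),
                                          "event_id")))
  info <- data.frame(
    event_id = colnames(st),
    ancestral_condition = vapply(chars, `[[`, character(1L),
                                 "ancestral_condition"),
    polarity = vapply(chars, `[[`, character(1L), "polarity"),
    row.names = NULL, stringsAsFactors = FALSE)
  new("RgcBinaryMatrix", states = st, info = info)
}

# quote a NEXUS label when it needs it
.nexusLabel <- function(x) {
  needs <- grepl("[][ \t'(){}/\\,;:=*\"`+<>-]", x)
  ifelse(needs, paste0("'", gsub("'", "''", x), "'"), x)
}

#' Write a binary matrix as restriction-datatype NEXUS
#'
#' Emits a DATA block with \code{FORMAT DATATYPE=RESTRICTION MISSING=?
#' SYMBOLS="01"} -- the datatype used for binary presence/absence
#' partitions in Bayesian analyses -- plus a CHARLABELS line carrying the
#' event ids so the matrix round-trips. Labels needing quoting are
#' single-quoted per NEXUS rules.
#'
#' @param m an \linkS4class{RgcBinaryMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRestrictionNexus <- function(m, path) {
  stopifnot(is(m, "RgcBinaryMatrix"))
  st <- binaryStates(m)
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
    "  FORMAT DATATYPE=RESTRICTION MISSING=? SYMBOLS=\"01\";",
    if (ncol(st)) sprintf("  CHARLABELS %s;",
                          paste(.nexusLabel(colnames(st)), collapse = " ")),
    "  MATRIX")
  labs <- .nexusLabel(rownames(st))
  wid <- max(nchar(labs), 0L)
  for (i in seq_len(nrow(st)))
    lines <- c(lines, sprintf("    %-*s  %s", wid, labs[i],
                              paste(st[i, ], collapse = "")))
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

# split a NEXUS label list honoring single quotes
.splitNexusLabels <- function(s) {
  out <- character()
  s <- trimws(s)
  while (nzchar(s)) {
    if (startsWith(s, "'")) {
      mtch <- regmatches(s, regexpr("^'([^']|'')*'", s))
      lab <- gsub("''", "'", substr(mtch, 2L, nchar(mtch) - 1L))
      s <- trimws(substr(s, nchar(mtch) + 1L, nchar(s)))
    } else {
      mtch <- regmatches(s, regexpr("^\\S+", s))
      lab <- mtch
      s <- trimws(substr(s, nchar(mtch) + 1L, nchar(s)))
    }
    out <- c(out, lab)
  }
  out
}

#' Read back a restriction-datatype NEXUS matrix
#'
#' Inverse of \code{\link{writeRestrictionNexus}}: recovers taxa order,
#' character ids (from CHARLABELS, or generated \code{char1..charK} when
#' absent) and 0/1/? states. Polarity metadata is not carried by NEXUS and
#' is reported as "unknown".
#'
#' @param path path to a NEXUS file written by this package (or an
#'   equivalent single DATA block).
#' @return an \linkS4class{RgcBinaryMatrix}.
#' @export
readRestrictionNexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^#NEXUS", lines[1L])) stop("not a NEXUS file: ", path)
  dim_ln <- grep("DIMENSIONS", lines, ignore.case = TRUE, value = TRUE)[1L]
  ntax <- as.integer(sub(".*NTAX=([0-9]+).*", "\\1", dim_ln,
                         ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR=([0-9]+).*", "\\1", dim_ln,
                           ignore.case = TRUE))
  cl_ln <- grep("CHARLABELS", lines, ignore.case = TRUE)
  ids <- if (length(cl_ln)) {
    s <- sub(";\\s*$", "", sub("^\\s*CHARLABELS\\s+", "", lines[cl_ln[1L]],
                               ignore.case = TRUE))
    .splitNexusLabels(s)
  } else if (nchar_ > 0L) paste0("char", seq_len(nchar_)) else character()
  mat_ln <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)[1L]
  end_ln <- grep("^\\s*;\\s*$", lines)
  end_ln <- end_ln[end_ln > mat_ln][1L]
  body <- lines[(mat_ln + 1L):(end_ln - 1L)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != ntax) stop("matrix rows do not match NTAX")
  labs <- character(ntax)
  st <- matrix("?", ntax, nchar_)
  for (i in seq_along(body)) {
    s <- trimws(body[i])
    if (startsWith(s, "'")) {
      mtch <- regmatches(s, regexpr("^'([^']|'')*'", s))
      labs[i] <- gsub("''", "'", substr(mtch, 2L, nchar(mtch) - 1L))
      rest <- trimws(substr(s, nchar(mtch) + 1L, nchar(s)))
    } else {
      mtch <- regmatches(s, regexpr("^\\S+", s))
      labs[i] <- mtch
      rest <- trimws(substr(s, nchar(mtch) + 1L, nchar(s)))
    }
    rest <- gsub("\\s", "", rest)
    if (nchar(rest) != nchar_) stop("row width does not match NCHAR for ",
                                    labs[i])
    if (nchar_ > 0L) st[i, ] <- strsplit(rest, "")[[1L]]
  }
  dimnames(st) <- list(labs, if (length(ids)) ids else NULL)
  new("RgcBinaryMatrix", states = st,
      info = data.frame(event_id = ids,
                        ancestral_condition = rep(NA_character_, nchar_),
                        polarity = rep("unknown", nchar_),
                        row.names = NULL, stringsAsFactors = FALSE))
}

#' Write a combined nucleotide + binary matrix with a partition file
#'
#' Emits a relaxed PHYLIP matrix whose columns are the (stripped)
#' nucleotide alignment followed by the binary characters, plus a
#' RAxML-style partition file naming the DNA and BIN ranges by 1-based
#' inclusive column spans. Taxa sets and order must match exactly.
#'
#' @param aln an \linkS4class{RgcAlignment} (typically gap-stripped).
#' @param m an \linkS4class{RgcBinaryMatrix}.
#' @param path_prefix output prefix; writes \code{<prefix>.phy} and
#'   \code{<prefix>.partitions}.
#' @return character vector of the two paths, invisibly.
#' @export
writeCombined <- function(aln, m, path_prefix) {
  stopifnot(is(aln, "RgcAlignment"), is(m, "RgcBinaryMatrix"))
  st <- binaryStates(m)
  if (ncol(st) && !identical(taxa(aln), rownames(st))) {
    d1 <- setdiff(taxa(aln), rownames(st))
    d2 <- setdiff(rownames(st), taxa(aln))
    stop("taxa mismatch between alignment and binary matrix;",
         if (length(d1)) paste0(" only in alignment: ",
                                paste(d1, collapse = ", ")),
         if (length(d2)) paste0(" only in matrix: ",
                                paste(d2, collapse = ", ")))
  }
  nb <- ncol(st)
  w <- alnWidth(aln)
  labs <- gsub("\\s+", "_", taxa(aln))
  phy <- file.path(paste0(path_prefix, ".phy"))
  part <- file.path(paste0(path_prefix, ".partitions"))
  rows <- vapply(seq_along(labs), function(i) {
    bin <- if (nb) paste(st[i, ], collapse = "") else ""
    sprintf("%-*s  %s%s", max(nchar(labs)), labs[i],
            alnRows(aln)[[i]], bin)
  }, character(1L))
  writeLines(c(sprintf("%d %d", length(labs), w + nb), rows), phy)
  plines <- sprintf("DNA, seq = 1-%d", w)
  if (nb) plines <- c(plines, sprintf("BIN, rgc = %d-%d", w + 1L, w + nb))
  writeLines(plines, part)
  invisible(c(phy, part))
}
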