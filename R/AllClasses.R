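#' @import methods
NULL

.ALN_ALPHABET <- c("A", "C", "G", "T", "U", "N", "-",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Multiple sequence alignment of plastome (or other DNA) sequences
#'
#' A thin container for an aligned set of residue strings over the alphabet
#' \{A,C,G,T,U,N, IUPAC ambiguity codes, '-'\}. Rows are stored uppercase;
#' all rows have identical width and taxon labels are unique and non-empty.
#'
#' @slot rows named character vector, one aligned residue string per taxon.
#' @export
setClass("RgcAlignment", representation(rows = "character"))

setValidity("RgcAlignment", function(object) {
  rows <- object@rows
  labs <- names(rows)
  if (is.null(labs) || any(is.na(labs)) || any(!nzchar(labs)))
    return("all rows must carry non-empty taxon labels")
  if (anyDuplicated(labs))
    return(sprintf("duplicate taxon label: %s",
                   labs[duplicated(labs)][1L]))
  w <- nchar(rows)
  if (length(rows) && length(unique(w)) > 1L) {
    bad <- labs[w != w[1L]][1L]
    return(sprintf("unequal alignment lengths (taxon '%s')", bad))
  }
  chars <- unique(strsplit(paste(rows, collapse = ""), "")[[1L]])
  illegal <- setdiff(chars, .ALN_ALPHABET)
  if (length(illegal))
    return(sprintf("illegal character(s) in alignment: %s",
                   paste(illegal, collapse = ", ")))
  TRUE
})

#' Construct an RgcAlignment from a named character vector of rows
#'
#' Input is uppercased; the gap dialects '.' and '?' are normalized to '-'
#' and 'N' respectively (with a warning), so that '-' is the only gap
#' character downstream.
#'
#' @param rows named character vector of aligned residue strings.
#' @return an \linkS4class{RgcAlignment}.
#' @examples
#' aln <- RgcAlignment(c(A = "AC-T", B = "ACGT"))
#' alnWidth(aln)
#' @export
RgcAlignment <- function(rows) {
  labs <- names(rows)
  rows <- toupper(as.character(rows))
  names(rows) <- labs
  if (any(grepl(".", rows, fixed = TRUE))) {
    warning("'.' characters normalized to '-'")
    rows <- gsub(".", "-", rows, fixed = TRUE)
  }
  if (any(grepl("?", rows, fixed = TRUE))) {
    warning("'?' characters normalized to 'N'")
    rows <- gsub("?", "N", rows, fixed = TRUE)
  }
  new("RgcAlignment", rows = rows)
}

setMethod("show", "RgcAlignment", function(object) {
  cat(sprintf("RgcAlignment: %d taxa x %d columns\n",
              length(object@rows), alnWidth(object)))
  n <- min(6L, length(object@rows))
  for (i in seq_len(n)) {
    r <- object@rows[i]
    disp <- if (nchar(r) > 60) paste0(substr(r, 1, 57), "...") else r
    cat(sprintf("  %-28s %s\n", names(object@rows)[i], disp))
  }
  if (length(object@rows) > n) cat(sprintf("  ... and %d more taxa\n",
                                           length(object@rows) - n))
})

#' @describeIn RgcAlignment-class taxon labels, in row order
#' @param x,object an \code{RgcAlignment}
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname RgcAlignment-class
#' @export
setMethod("taxa", "RgcAlignment", function(x) names(x@rows))

#' @describeIn RgcAlignment-class number of alignment columns
#' @export
setGeneric("alnWidth", function(x) standardGeneric("alnWidth"))

#' @rdname RgcAlignment-class
#' @export
setMethod("alnWidth", "RgcAlignment", function(x)
  if (length(x@rows)) nchar(x@rows[[1L]]) else 0L)

#' @describeIn RgcAlignment-class named character vector of aligned rows
#' @export
setGeneric("alnRows", function(x) standardGeneric("alnRows"))

#' @rdname RgcAlignment-class
#' @export
setMethod("alnRows", "RgcAlignment", function(x) x@rows)

#' A single gap-free genome record with optional features
#'
#' @slot id accession-like identifier.
#' @slot sequence gap-free residue string.
#' @slot features data.frame with columns \code{type}, \code{start},
#'   \code{end} (1-based closed), \code{strand}, \code{qualifiers}.
#' @export
setClass("GenomeRecord",
         representation(id = "character", sequence = "character",
                        features = "data.frame"))

setValidity("GenomeRecord", function(object) {
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    return("sequence must be a single non-empty string")
  if (grepl("-", object@sequence, fixed = TRUE))
    return("sequence must be gap-free")
  if (nrow(object@features)) {
    n <- nchar(object@sequence)
    if (any(object@features$start < 1L) || any(object@features$end > n))
      return("feature interval outside [1, sequence length]")
  }
  TRUE
})

#' @rdname GenomeRecord-class
#' @param id,sequence,features see slots.
#' @export
GenomeRecord <- function(id, sequence, features = NULL) {
  if (is.null(features))
    features <- data.frame(type = character(), start = integer(),
                           end = integer(), strand = character(),
                           qualifiers = character(),
                           stringsAsFactors = FALSE)
  new("GenomeRecord", id = as.character(id),
      sequence = toupper(as.character(sequence)), features = features)
}

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord %s: %d bp, %d feature(s)\n",
              object@id, nchar(object@sequence), nrow(object@features)))
})

#' Quadripartite partition of a circular plastome
#'
#' Intervals (1-based, closed, in the linear coordinates of the input
#' orientation) of the four canonical plastome regions. On a circular
#' molecule one region may wrap around the origin; a wrapped region is
#' represented with \code{start > end}.
#'
#' @slot lsc,irb,ssc,ira integer(2) intervals c(start, end).
#' @slot ir_length,lsc_length,ssc_length region lengths in bp.
#' @export
setClass("QuadripartitePartition",
         representation(lsc = "integer", irb = "integer", ssc = "integer",
                        ira = "integer", ir_length = "integer",
                        lsc_length = "integer", ssc_length = "integer"))

setMethod("show", "QuadripartitePartition", function(object) {
  fmt <- function(iv) sprintf("[%d, %d]", iv[1L], iv[2L])
  cat("QuadripartitePartition\n")
  cat(sprintf("  LSC %s (%d bp)\n", fmt(object@lsc), object@lsc_length))
  cat(sprintf("  IRb %s (%d bp)\n", fmt(object@irb), object@ir_length))
  cat(sprintf("  SSC %s (%d bp)\n", fmt(object@ssc), object@ssc_length))
  cat(sprintf("  IRa %s (%d bp)\n", fmt(object@ira), object@ir_length))
})

#' Binary RGC character matrix
#'
#' Taxa-by-characters matrix of "0" (ancestral condition, as defined by the
#' outgroup), "1" (derived condition) and "?" (partial/uncertain), together
#' with per-character metadata (event id, ancestral condition, polarity).
#'
#' @slot states character matrix, rownames = taxa, colnames = event ids.
#' @slot info data.frame with one row per character: \code{event_id},
#'   \code{ancestral_condition} (span_present/span_absent), \code{polarity}
#'   (deletion/insertion/unknown).
#' @export
setClass("RgcBinaryMatrix",
         representation(states = "matrix", info = "data.frame"))

setValidity("RgcBinaryMatrix", function(object) {
  st <- object@states
  if (ncol(st) != nrow(object@info))
    return("one info row required per character column")
  if (ncol(st) && !identical(colnames(st), object@info$event_id))
    return("column names must equal info$event_id")
  if (length(st) && !all(st %in% c("0", "1", "?")))
    return("states must be '0', '1' or '?'")
  if (anyDuplicated(colnames(st)))
    return("character ids must be unique")
  TRUE
})

setMethod("show", "RgcBinaryMatrix", function(object) {
  cat(sprintf("RgcBinaryMatrix: %d taxa x %d character(s)\n",
              nrow(object@states), ncol(object@states)))
  if (ncol(object@states))
    cat("  polarity:", paste(sprintf("%s(%s)", object@info$event_id,
                                     object@info$polarity),
                             collapse = ", "), "\n")
})

#' @describeIn RgcBinaryMatrix-class the taxa-by-characters state matrix
#' @param x an \code{RgcBinaryMatrix}
#' @export
setGeneric("binaryStates", function(x) standardGeneric("binaryStates"))

#' @rdname RgcBinaryMatrix-class
#' @export
setMethod("binaryStates", "RgcBinaryMatrix", function(x) x@states)

#' @describeIn RgcBinaryMatrix-class per-character metadata
#' @export
setGeneric("characterInfo", function(x) standardGeneric("characterInfo"))

#' @rdname RgcBinaryMatrix-class
#' @export
setMethod("characterInfo", "RgcBinaryMatrix", function(x) x@info)

#' @rdname RgcBinaryMatrix-class
#' @export
setMethod("taxa", "RgcBinaryMatrix", function(x) rownames(x@states))
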