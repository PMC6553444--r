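#' Read an aligned FASTA file
#'
#' Reads an aligned FASTA file into an \linkS4class{RgcAlignment}. Row order
#' is preserved from the file; labels are the full FASTA description lines.
#' Ragged rows, duplicate labels and illegal characters are errors.
#'
#' @param path path to an aligned FASTA file.
#' @return an \linkS4class{RgcAlignment}.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">A", "AC-T", ">B", "ACGT"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  rows <- as.character(ss)
  names(rows) <- names(ss)
  RgcAlignment(rows)
}

#' Write an alignment as FASTA
#'
#' Sequences are wrapped at 70 columns and the file ends with a newline.
#'
#' @param aln an \linkS4class{RgcAlignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "RgcAlignment"))
  ss <- Biostrings::BStringSet(alnRows(aln))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Remove gap-containing columns from an alignment
#'
#' Implements the post-characterization stripping step: with
#' \code{mode = "any_gap"} (the default) every column in which any taxon has
#' a \code{'-'} is removed, leaving a gap-free matrix; with
#' \code{mode = "all_gap"} only columns that are gaps in every taxon are
#' removed. The input is not modified.
#'
#' @param aln an \linkS4class{RgcAlignment}.
#' @param mode \code{"any_gap"} or \code{"all_gap"}.
#' @return a new \linkS4class{RgcAlignment} (possibly of width zero).
#' @examples
#' aln <- RgcAlignment(c(A = "AC-T", B = "ACGT"))
#' alnRows(stripGapColumns(aln))
#' @export
stripGapColumns <- function(aln, mode = c("any_gap", "all_gap")) {
  mode <- match.arg(mode)
  stopifnot(is(aln, "RgcAlignment"))
  rows <- alnRows(aln)
  if (!length(rows) || alnWidth(aln) == 0L) return(aln)
  m <- .alnMatrix(aln)
  gap <- m == "-"
  keep <- if (mode == "any_gap") !apply(gap, 2L, any) else !apply(gap, 2L, all)
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (!sum(keep)) out <- setNames(rep("", length(rows)), names(rows))
  RgcAlignment(setNames(out, names(rows)))
}

#' Excise a column (or base) interval
#'
#' Removes a 1-based closed interval of alignment columns from an
#' \linkS4class{RgcAlignment}, or of bases from a
#' \linkS4class{GenomeRecord} sequence (record features are dropped after
#' excision since their coordinates would no longer apply). Used e.g. to
#' remove the second inverted-repeat copy (IRa) before RGC analysis.
#'
#' @param x an \code{RgcAlignment} or \code{GenomeRecord}.
#' @param start,end 1-based closed interval bounds; \code{end = start - 1}
#'   (width zero) is the identity.
#' @return object of the same class with the interval removed.
#' @examples
#' r <- GenomeRecord("x", "ACGTAC")
#' exciseInterval(r, 3, 4)  # "ACAC"
#' @export
exciseInterval <- function(x, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (end == start - 1L) return(x)  # empty interval: identity
  drop1 <- function(s, n) {
    if (start < 1L || end > n || end < start)
      stop(sprintf("interval [%d, %d] out of range 1..%d", start, end, n))
    paste0(substr(s, 1L, start - 1L), substr(s, end + 1L, n))
  }
  if (is(x, "RgcAlignment")) {
    n <- alnWidth(x)
    RgcAlignment(vapply(alnRows(x), drop1, character(1L), n = n))
  } else if (is(x, "GenomeRecord")) {
    GenomeRecord(x@id, drop1(x@sequence, nchar(x@sequence)))
  } else stop("unsupported type")
}

#' Read and write newick trees
#'
#' Thin wrappers over \pkg{ape} that enforce unique leaf labels. Round-trips
#' preserve topology and labels (bipartition-set equality).
#'
#' @param path file path.
#' @return \code{readNewick}: an \code{ape::phylo} tree.
#' @export
readNewick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: no tree in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ",
         tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' @rdname readNewick
#' @param tree an \code{ape::phylo} tree.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal reader for GenBank flat files: parses LOCUS/ACCESSION, the
#' FEATURES table (simple \code{a..b} and \code{complement(a..b)} locations;
#' compound locations are stored by their outer span) and the ORIGIN
#' sequence block. Intervals are 1-based closed as printed in the file.
#'
#' @param path path to a GenBank flat file.
#' @return a \linkS4class{GenomeRecord}.
#' @export
readGenBank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
             grep("^ACCESSION", lines, value = TRUE)[1L])
  if (is.na(acc))
    acc <- sub("^LOCUS\\s+(\\S+).*$", "\\1",
               grep("^LOCUS", lines, value = TRUE)[1L])
  if (is.na(acc)) acc <- "unknown"
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("missing sequence: no ORIGIN block in ", path)
  endl <- grep("^//", lines)
  endl <- if (length(endl)) endl[endl > ori[1L]][1L] else length(lines) + 1L
  seqlines <- lines[(ori[1L] + 1L):(endl - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nzchar(seq)) stop("missing sequence: empty ORIGIN block in ", path)

  feat <- data.frame(type = character(), start = integer(), end = integer(),
                     strand = character(), qualifiers = character(),
                     stringsAsFactors = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
    hdr <- grep("^\\s{5}\\S", block)
    for (i in hdr) {
      type <- sub("^\\s+(\\S+).*$", "\\1", block[i])
      loc <- sub("^\\s+\\S+\\s+(\\S+).*$", "\\1", block[i])
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
      if (length(nums) < 1L) next
      quals <- character()
      j <- i + 1L
      while (j <= length(block) && !grepl("^\\s{5}\\S", block[j])) {
        q <- trimws(block[j])
        if (startsWith(q, "/")) quals <- c(quals, q)
        j <- j + 1L
      }
      feat <- rbind(feat, data.frame(
        type = type, start = min(nums), end = max(nums), strand = strand,
        qualifiers = paste(quals, collapse = " "),
        stringsAsFactors = FALSE))
    }
  }
  GenomeRecord(acc, seq, feat)
}

#' Path to a bundled example alignment
#'
#' Two small intergenic-spacer alignment windows ship with the package:
#' \describe{
#'   \item{"psbE_petL"}{17 Poeae plastomes over an 80-column window of the
#'     psbE-petL intergenic spacer, containing the 63 bp intrastrand
#'     deletion unique to \emph{Polypogon fugax}.}
#'   \item{"psaJ_rpl33"}{5 \emph{Festuca} plastomes over a 93-column window
#'     of the psaJ-rpl33 intergenic spacer, containing the 78 bp intrastrand
#'     deletion in the NC_019649 accession of \emph{F. ovina}.}
#' }
#'
#' @param which \code{"psbE_petL"} or \code{"psaJ_rpl33"}.
#' @return file path of the bundled aligned FASTA.
#' @examples
#' aln <- readAlignment(rgcExample("psbE_petL"))
#' @export
rgcExample <- function(which = c("psbE_petL", "psaJ_rpl33")) {
  which <- match.arg(which)
  fn <- c(psbE_petL = "psbE_petL_poeae17.fasta",
          psaJ_rpl33 = "psaJ_rpl33_festuca5.fasta")[[which]]
  system.file("extdata", fn, package = "rgcscan", mustWork = TRUE)
}

# taxa x columns character matrix view of an alignment
.alnMatrix <- function(aln) {
  rows <- alnRows(aln)
  m <- matrix("", nrow = length(rows), ncol = alnWidth(aln),
              dimnames = list(names(rows), NULL))
  for (i in seq_along(rows)) m[i, ] <- strsplit(rows[[i]], "")[[1L]]
  m
}
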