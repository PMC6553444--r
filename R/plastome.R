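# reverse complement of an IUPAC DNA/RNA string (returns DNA alphabet)
.revcomp <- function(s) {
  comp <- chartr("ACGTUNRYSWKMBDHVacgtunryswkmbdhv",
                 "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb", s)
  rawToChar(rev(charToRaw(comp)))
}

# round half-up to one decimal (Table-style rounding; base round() is
# round-half-even)
.round1 <- function(x) floor(x * 10 + 0.5) / 10

#' AT content of a gap-free sequence
#'
#' Percentage of A+T(+U) among unambiguous bases; N and IUPAC ambiguity
#' codes are excluded from numerator and denominator. Rounded half-up to
#' one decimal, matching the convention of published plastome tables.
#'
#' @param seq gap-free residue string, or a \linkS4class{GenomeRecord}.
#' @return percent AT, one decimal.
#' @examples
#' atContent("ACGT")  # 50.0
#' @export
atContent <- function(seq) {
  if (is(seq, "GenomeRecord")) seq <- seq@sequence
  s <- toupper(seq)
  if (grepl("-", s, fixed = TRUE)) stop("sequence must be gap-free")
  counts <- table(strsplit(s, "")[[1L]])
  at <- sum(counts[names(counts) %in% c("A", "T", "U")])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T", "U")])
  if (acgt == 0L) stop("no unambiguous bases")
  .round1(100 * at / acgt)
}

#' Locate the inverted-repeat pair of a plastome sequence
#'
#' Finds the maximal pair of non-overlapping intervals whose sequences are
#' exact reverse complements of each other, both of length at least
#' \code{min_len}. Search is by k-mer seeding of the forward strand against
#' the reverse complement of the sequence, followed by exact bidirectional
#' extension along each seed diagonal; plastid IRs are near-identical, so
#' exact matching is appropriate and keeps the search verifiable against an
#' exhaustive oracle.
#'
#' @param seq gap-free residue string or \linkS4class{GenomeRecord}.
#' @param min_len minimum repeat length in bp (default 1000, plastome-scale;
#'   lower it for small test sequences).
#' @param k seed k-mer size (default 21).
#' @return list with integer(2) intervals \code{irb} (leftmost copy) and
#'   \code{ira}, both 1-based closed, and \code{length}.
#' @export
findInvertedRepeat <- function(seq, min_len = 1000L, k = 21L) {
  if (is(seq, "GenomeRecord")) seq <- seq@sequence
  s <- toupper(seq)
  n <- nchar(s)
  min_len <- as.integer(min_len)
  if (n < 2L * min_len)
    stop("sequence shorter than 2*min_len")
  k <- min(as.integer(k), min_len)
  rc <- .revcomp(s)
  sraw <- charToRaw(s)
  rraw <- charToRaw(rc)

  kf <- substring(s, 1:(n - k + 1L), k:n)
  kr <- substring(rc, 1:(n - k + 1L), k:n)
  idx <- split(seq_along(kr), kr)
  hits <- which(kf %in% names(idx))

  best <- NULL
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in hits) {
    for (p in idx[[kf[i]]]) {
      d <- as.character(i - p)
      if (!is.null(seen[[d]])) next
      seen[[d]] <- TRUE
      # extend along diagonal i - p: compare s[i+t] with rc[p+t]
      lo <- max(1L - i, 1L - p)
      hi <- min(n - i, n - p)
      t <- lo:hi
      eq <- sraw[i + t] == rraw[p + t]
      # maximal TRUE run containing t == 0 (the seed start)
      z <- which(t == 0L)
      if (!eq[z]) next
      a <- z; while (a > 1L && eq[a - 1L]) a <- a - 1L
      b <- z; while (b < length(eq) && eq[b + 1L]) b <- b + 1L
      ia <- i + t[a]; ib <- i + t[b]
      pa <- p + t[a]; pb <- p + t[b]
      # map rc interval back to original coordinates
      ja <- n - pb + 1L; jb <- n - pa + 1L
      A <- c(ia, ib); B <- c(ja, jb)
      if (A[1L] > B[1L]) { tmp <- A; A <- B; B <- tmp }
      if (A[2L] >= B[1L]) {           # overlapping self-palindrome: trim
        tr <- (A[2L] - B[1L]) %/% 2L + 1L
        A[2L] <- A[2L] - tr
        B[1L] <- B[1L] + tr
      }
      len <- A[2L] - A[1L] + 1L
      if (len >= min_len && (is.null(best) || len > best$length ||
                             (len == best$length && A[1L] < best$irb[1L])))
        best <- list(irb = A, ira = B, length = len)
    }
  }
  if (is.null(best))
    stop(sprintf("no inverted repeat >= %d bp", min_len))
  best
}

#' Partition a plastome into LSC / IRb / SSC / IRa
#'
#' Given the inverted-repeat pair of a circular plastome (in linear
#' coordinates of the input orientation), assigns the longer inter-IR
#' segment as the large single-copy region (LSC) and the shorter as the
#' small single-copy region (SSC). One segment may wrap around the
#' sequence origin; wrapped intervals are reported with start > end.
#'
#' @param seq gap-free residue string or \linkS4class{GenomeRecord}.
#' @param ir_pair result of \code{\link{findInvertedRepeat}}.
#' @return a \linkS4class{QuadripartitePartition}.
#' @export
partitionQuadripartite <- function(seq, ir_pair) {
  if (is(seq, "GenomeRecord")) seq <- seq@sequence
  n <- nchar(seq)
  A <- as.integer(ir_pair$irb); B <- as.integer(ir_pair$ira)
  if (A[2L] >= B[1L]) stop("IR pair intervals overlap")
  ir_len <- A[2L] - A[1L] + 1L

  # segment between the copies, and the segment wrapping the origin
  mid_len <- B[1L] - A[2L] - 1L
  wrap_len <- n - B[2L] + A[1L] - 1L
  if (mid_len <= 0L || wrap_len <= 0L)
    stop("degenerate partition: empty single-copy segment")
  mid <- c(A[2L] + 1L, B[1L] - 1L)
  wrap <- if (B[2L] == n) c(1L, A[1L] - 1L)
          else if (A[1L] == 1L) c(B[2L] + 1L, n)
          else c(B[2L] + 1L, A[1L] - 1L)   # wrapped: start > end

  if (mid_len > wrap_len) {
    lsc <- mid; ssc <- wrap; lsc_len <- mid_len; ssc_len <- wrap_len
  } else if (wrap_len > mid_len) {
    lsc <- wrap; ssc <- mid; lsc_len <- wrap_len; ssc_len <- mid_len
  } else {
    warning("inter-IR segments of equal length; taking the segment ",
            "containing coordinate 1 as LSC")
    contains1 <- wrap[1L] > wrap[2L] || wrap[1L] == 1L
    if (contains1) { lsc <- wrap; ssc <- mid }
    else { lsc <- mid; ssc <- wrap }
    lsc_len <- ssc_len <- mid_len
  }
  new("QuadripartitePartition", lsc = lsc, irb = A, ssc = ssc, ira = B,
      ir_length = ir_len, lsc_length = lsc_len, ssc_length = ssc_len)
}

#' Summarize a plastome record
#'
#' One summary row per record: total length, inverted-repeat length, LSC
#' and SSC lengths, and percent AT. If no qualifying inverted repeat is
#' found the partition fields are reported as NA (with a warning) and
#' length and %AT are still computed.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param min_ir_len minimum IR length for detection (bp).
#' @return one-row data.frame with columns id, plastome_length, ir_length,
#'   lsc_length, ssc_length, at_percent.
#' @export
summarizePlastome <- function(record, min_ir_len = 1000L) {
  stopifnot(is(record, "GenomeRecord"))
  s <- record@sequence
  part <- tryCatch(partitionQuadripartite(
    s, findInvertedRepeat(s, min_len = min_ir_len)),
    error = function(e) {
      warning("partition failed for ", record@id, ": ",
              conditionMessage(e))
      NULL
    })
  data.frame(
    id = record@id,
    plastome_length = nchar(s),
    ir_length = if (is.null(part)) NA_integer_ else part@ir_length,
    lsc_length = if (is.null(part)) NA_integer_ else part@lsc_length,
    ssc_length = if (is.null(part)) NA_integer_ else part@ssc_length,
    at_percent = atContent(s),
    stringsAsFactors = FALSE)
}

#' Plastome summary table for several records or files
#'
#' @param x list of \linkS4class{GenomeRecord}s, or character vector of
#'   file paths (GenBank flat files or single-record FASTA, by extension).
#' @param min_ir_len minimum IR length (bp).
#' @return data.frame, one row per record.
#' @export
plastomeStats <- function(x, min_ir_len = 1000L) {
  if (is.character(x)) {
    x <- lapply(x, function(p) {
      if (grepl("\\.(gb|gbk|genbank)$", p, ignore.case = TRUE))
        readGenBank(p)
      else {
        ss <- Biostrings::readBStringSet(p)
        GenomeRecord(names(ss)[1L], as.character(ss[[1L]]))
      }
    })
  }
  if (is(x, "GenomeRecord")) x <- list(x)
  do.call(rbind, lapply(x, summarizePlastome, min_ir_len = min_ir_len))
}
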