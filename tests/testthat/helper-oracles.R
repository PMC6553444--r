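# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results from first principles (exhaustive
# enumeration / per-cell scans) rather than calling package internals.

rand_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1L]])), collapse = "")
}

# random gapped alignment as a named character vector of rows
rand_gapped_rows <- function(ntaxa, ncol, gap_p = 0.15) {
  rows <- vapply(seq_len(ntaxa), function(i) {
    ch <- sample(c("A", "C", "G", "T", "-"), ncol, replace = TRUE,
                 prob = c(rep((1 - gap_p) / 4, 4L), gap_p))
    paste(ch, collapse = "")
  }, character(1L))
  names(rows) <- paste0("t", seq_len(ntaxa))
  rows
}

# per-column brute-force gap stripping
oracle_strip <- function(rows, mode) {
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- vapply(seq_len(ncol(m)), function(j) {
    g <- m[, j] == "-"
    if (mode == "any_gap") !any(g) else !all(g)
  }, logical(1L))
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (!sum(keep)) out <- rep("", length(rows))
  names(out) <- names(rows)
  out
}

# exhaustive small-parsimony minimum over all 0/1 labelings of the free
# nodes (internal nodes, plus leaves with '?')
oracle_parsimony <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  fixed <- rep(NA_integer_, nnode)
  for (i in seq_len(ntip)) {
    s <- states[[tree$tip.label[i]]]
    if (s %in% c("0", "1")) fixed[i] <- as.integer(s)
  }
  free <- which(is.na(fixed))
  best <- Inf
  for (code in 0:(2^length(free) - 1L)) {
    lab <- fixed
    if (length(free))
      lab[free] <- as.integer(intToBits(code))[seq_along(free)]
    cost <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
    if (cost < best) best <- cost
  }
  as.integer(best)
}

# brute-force longest flanking direct repeat around a deletion junction in
# an ungapped sequence: all (a, b, L) triples with copy starts within `off`
# of the boundaries (or copy ends, mirror arrangement), exact equality,
# disjoint copies, and copies not part of a single periodic (tandem) run
oracle_flank <- function(useq, b5, b3, min_len = 8L, off = 5L,
                         max_len = 60L) {
  n <- nchar(useq)
  is_tandem <- function(from, to, maxp) {
    w <- substr(useq, from, to)
    len <- nchar(w)
    for (p in seq_len(min(maxp, len - 1L))) {
      if (substr(w, p + 1L, len) == substr(w, 1L, len - p)) return(TRUE)
    }
    FALSE
  }
  best <- 0L
  best_seq <- NULL
  consider <- function(c1s, c1e, c2s, c2e) {
    L <- c1e - c1s + 1L
    if (L < min_len || L <= best) return()
    if (c1e >= c2s) return()
    if (c1s < 1L || c2e > n) return()
    if (substr(useq, c1s, c1e) != substr(useq, c2s, c2e)) return()
    if (is_tandem(c1s, c2e, L)) return()
    best <<- L
    best_seq <<- substr(useq, c1s, c1e)
  }
  for (L in min_len:max_len) {
    for (a in (b5 - off):(b5 + off)) {
      for (b in (b3 - off):(b3 + off)) {
        consider(a, a + L - 1L, b, b + L - 1L)          # copies begin at bounds
        consider(a - L, a - 1L, b - L, b - 1L)          # copies end at bounds
      }
    }
  }
  if (best == 0L) NULL else list(length = best, sequence = best_seq)
}

# exhaustive longest non-overlapping inverted-repeat pair by scanning every
# diagonal of the sequence against its reverse complement
oracle_inverted_repeat <- function(s, min_len) {
  n <- nchar(s)
  sv <- strsplit(s, "")[[1L]]
  rv <- strsplit(revcomp_chr(s), "")[[1L]]
  best <- NULL
  for (d in (1L - n):(n - 1L)) {
    i0 <- max(1L, 1L + d); i1 <- min(n, n + d)
    idx <- i0:i1
    eq <- sv[idx] == rv[idx - d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      ia <- idx[starts[k]]; ib <- idx[ends[k]]
      p_a <- ia - d; p_b <- ib - d
      ja <- n - p_b + 1L; jb <- n - p_a + 1L
      A <- c(ia, ib); B <- c(ja, jb)
      if (A[1L] > B[1L]) { tmp <- A; A <- B; B <- tmp }
      if (A[2L] >= B[1L]) {
        tr <- (A[2L] - B[1L]) %/% 2L + 1L
        A[2L] <- A[2L] - tr; B[1L] <- B[1L] + tr
      }
      len <- A[2L] - A[1L] + 1L
      if (len >= min_len && (is.null(best) || len > best$length ||
                             (len == best$length && A[1L] < best$irb[1L])))
        best <- list(irb = A, ira = B, length = len)
    }
  }
  best
}

psbE_petL_aln <- function() readAlignment(rgcExample("psbE_petL"))
psaJ_rpl33_aln <- function() readAlignment(rgcExample("psaJ_rpl33"))
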