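#' Configuration for RGC detection
#'
#' @param min_rgc_len minimum event length (alignment columns) for an event
#'   to count as a rare genomic change rather than a microstructural change.
#'   The default 50 is inclusive: observed RGC length distributions start at
#'   50 bp.
#' @param include_terminal_runs treat gap runs touching the first or last
#'   alignment column as events (default FALSE: terminal runs are missing
#'   data, the standard convention in indel coding; alignment windows would
#'   otherwise create artifactual edge events).
#' @param boundary_slop columns of boundary tolerance when clustering runs
#'   into shared events (default 0: shared-event homology requires identical
#'   boundaries, the strictest defensible criterion).
#' @param ambiguous_gap_density an event is ambiguous when the fraction of
#'   gap characters among non-member cells inside its interval exceeds this
#'   (a region riddled with independent indels; default 0.5).
#' @param nested_gap_tol a taxon still reads as carrying the full span
#'   ("present") when at most this fraction of the span is gapped by small
#'   nested indels (default 0.25).
#' @return a classed list of settings.
#' @export
rgcConfig <- function(min_rgc_len = 50L, include_terminal_runs = FALSE,
                      boundary_slop = 0L, ambiguous_gap_density = 0.5,
                      nested_gap_tol = 0.25) {
  stopifnot(min_rgc_len >= 1L, boundary_slop >= 0L,
            ambiguous_gap_density >= 0, ambiguous_gap_density <= 1,
            nested_gap_tol >= 0, nested_gap_tol < 1)
  structure(list(min_rgc_len = as.integer(min_rgc_len),
                 include_terminal_runs = isTRUE(include_terminal_runs),
                 boundary_slop = as.integer(boundary_slop),
                 ambiguous_gap_density = ambiguous_gap_density,
                 nested_gap_tol = nested_gap_tol),
            class = "rgcConfig")
}

#' Extract per-taxon gap runs from an alignment
#'
#' Every maximal run of '-' in every row is reported exactly once, with a
#' flag marking runs that touch the first or last alignment column.
#'
#' @param aln an \linkS4class{RgcAlignment}.
#' @return data.frame with columns taxon, start, end (1-based closed),
#'   length, terminal.
#' @examples
#' aln <- RgcAlignment(c(A = "AC--T", B = "ACGGT"))
#' extractGapRuns(aln)
#' @export
extractGapRuns <- function(aln) {
  stopifnot(is(aln, "RgcAlignment"))
  rows <- alnRows(aln)
  w <- alnWidth(aln)
  out <- lapply(names(rows), function(tx) {
    m <- gregexpr("-+", rows[[tx]])[[1L]]
    if (m[1L] == -1L) return(NULL)
    st <- as.integer(m)
    len <- attr(m, "match.length")
    data.frame(taxon = tx, start = st, end = st + len - 1L, length = len,
               terminal = st == 1L | (st + len - 1L) == w,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(taxon = character(), start = integer(),
                      end = integer(), length = integer(),
                      terminal = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# empty event table with the canonical columns
.emptyEvents <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             length = integer(), n_taxa = integer(),
             gap_taxa = I(list()), status = character(),
             ambiguity_reason = character(), stringsAsFactors = FALSE)
}

#' Cluster gap runs into candidate indel events
#'
#' Runs with identical column intervals (within \code{boundary_slop}) are
#' merged into one event whose member set is the union of their taxa.
#' Terminal runs are excluded unless configured otherwise. Events are
#' sorted by start column and get stable interval-derived ids.
#'
#' @param runs data.frame from \code{\link{extractGapRuns}}.
#' @param cfg an \code{\link{rgcConfig}}.
#' @return event data.frame with columns id, start, end, length, n_taxa,
#'   gap_taxa (list column), status ("candidate"), ambiguity_reason.
#' @export
clusterEvents <- function(runs, cfg = rgcConfig()) {
  if (!cfg$include_terminal_runs) runs <- runs[!runs$terminal, , drop = FALSE]
  if (!nrow(runs)) return(.emptyEvents())

  if (cfg$boundary_slop == 0L) {
    grp <- paste(runs$start, runs$end)
  } else {
    # single-linkage over runs whose start and end both differ by <= slop
    o <- order(runs$start, runs$end)
    runs <- runs[o, , drop = FALSE]
    grp_id <- integer(nrow(runs))
    grp_id[1L] <- 1L
    for (i in seq_len(nrow(runs))[-1L]) {
      prev <- which(grp_id[seq_len(i - 1L)] > 0L)
      match_prev <- prev[abs(runs$start[prev] - runs$start[i]) <= cfg$boundary_slop &
                         abs(runs$end[prev] - runs$end[i]) <= cfg$boundary_slop]
      grp_id[i] <- if (length(match_prev)) grp_id[match_prev[1L]]
                   else max(grp_id) + 1L
    }
    grp <- as.character(grp_id)
  }

  ev <- lapply(split(seq_len(nrow(runs)), grp), function(ix) {
    sub <- runs[ix, , drop = FALSE]
    # representative interval: the most frequent exact interval in the group
    key <- paste(sub$start, sub$end)
    rep <- sub[key == names(which.max(table(key)))[1L], , drop = FALSE][1L, ]
    data.frame(start = rep$start, end = rep$end,
               length = rep$end - rep$start + 1L,
               n_taxa = length(unique(sub$taxon)),
               gap_taxa = I(list(sort(unique(sub$taxon)))),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  ev$id <- sprintf("rgc_%06d_%06d", ev$start, ev$end)
  ev$status <- "candidate"
  ev$ambiguity_reason <- ""
  rownames(ev) <- NULL
  ev[, c("id", "start", "end", "length", "n_taxa", "gap_taxa",
         "status", "ambiguity_reason")]
}

# number of gap characters a row carries inside a column interval
.gapCount <- function(row, start, end) {
  seg <- substr(row, start, end)
  nchar(seg) - nchar(gsub("-", "", seg, fixed = TRUE))
}

# condition of a row over a column interval: "absent" (gap across the whole
# span), "present" (at most nested_gap_tol of the span gapped), or "partial"
.spanState <- function(row, start, end, tol = 0.25) {
  gf <- .gapCount(row, start, end) / (end - start + 1L)
  if (gf == 1) "absent" else if (gf <= tol) "present" else "partial"
}

#' Flag ambiguous events
#'
#' An event is marked ambiguous when homology or polarity cannot be read
#' from the alignment: (a) its interval overlaps another event's interval
#' partially (crossing, neither nested in the other) -- nested indels are
#' unproblematic and scored separately; (b) the density of gap characters
#' among non-member taxa inside the interval exceeds
#' \code{ambiguous_gap_density} (region riddled with independent indels);
#' or (c) a designated outgroup taxon shows a partial gap over the interval
#' so the ancestral condition is unreadable. All other events become
#' \code{non_ambiguous}.
#'
#' @param events event data.frame from \code{\link{clusterEvents}}.
#' @param aln the source \linkS4class{RgcAlignment}.
#' @param outgroups optional character vector of outgroup taxon labels.
#' @param cfg an \code{\link{rgcConfig}}.
#' @return the event data.frame with status and ambiguity_reason filled in.
#' @export
flagAmbiguous <- function(events, aln, outgroups = character(),
                          cfg = rgcConfig()) {
  if (!nrow(events)) return(events)
  stopifnot(all(outgroups %in% taxa(aln)))
  rows <- alnRows(aln)
  n_ev <- nrow(events)
  reason <- character(n_ev)

  crosses <- function(i, j) {
    s1 <- events$start[i]; e1 <- events$end[i]
    s2 <- events$start[j]; e2 <- events$end[j]
    overlap <- s1 <= e2 && s2 <= e1
    nested <- (s1 <= s2 && e1 >= e2) || (s2 <= s1 && e2 >= e1)
    overlap && !nested
  }
  for (i in seq_len(n_ev)) {
    # (a) crossing overlap with any other event
    for (j in seq_len(n_ev)) {
      if (j != i && crosses(i, j)) {
        reason[i] <- "crossing_overlap"
        break
      }
    }
    if (nzchar(reason[i])) next
    s <- events$start[i]; e <- events$end[i]
    nonmember <- setdiff(names(rows), events$gap_taxa[[i]])
    # (b) non-member gap density inside the interval
    if (length(nonmember)) {
      gaps <- sum(vapply(rows[nonmember], .gapCount, integer(1L),
                         start = s, end = e))
      if (gaps / (length(nonmember) * (e - s + 1L)) >
          cfg$ambiguous_gap_density) {
        reason[i] <- "gap_dense_region"
        next
      }
    }
    # (c) outgroup partial over the span
    for (og in outgroups) {
      if (.spanState(rows[[og]], s, e, cfg$nested_gap_tol) == "partial") {
        reason[i] <- "outgroup_partial"
        break
      }
    }
  }
  events$status <- ifelse(nzchar(reason), "ambiguous", "non_ambiguous")
  events$ambiguity_reason <- reason
  events
}

#' Apply the RGC size filter
#'
#' Retains non-ambiguous events of length >= \code{min_rgc_len} as RGC;
#' shorter non-ambiguous events are returned separately as microstructural
#' changes (reported, not analyzed further).
#'
#' @param events event data.frame with status set
#'   (\code{\link{flagAmbiguous}}).
#' @param cfg an \code{\link{rgcConfig}}.
#' @return list with elements \code{rgc} and \code{microstructural}, each
#'   an event data.frame.
#' @export
filterRgc <- function(events, cfg = rgcConfig()) {
  keep <- events$status == "non_ambiguous"
  big <- events$length >= cfg$min_rgc_len
  list(rgc = events[keep & big, , drop = FALSE],
       microstructural = events[keep & !big, , drop = FALSE])
}
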