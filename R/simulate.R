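# random DNA string with a target AT fraction
.randSeq <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

#' Specify one planted indel event for the simulator
#'
#' @param branch leaf label(s) identifying the tree edge whose subtended
#'   leaf set equals this set; the event arises on that branch.
#' @param kind "ISD", "SSM", "recombination_del", "recombination_ins" or
#'   "micro_indel".
#' @param length event length in bp. RGC kinds must be >= 50; micro_indel
#'   must be < 50.
#' @param repeat_len (ISD) length of the planted flanking direct repeat,
#'   >= 8 so the event is detectable at default settings.
#' @param unit_len,copy_delta (SSM) tandem unit length and number of unit
#'   copies removed; \code{length} must equal \code{unit_len * copy_delta}.
#'   Units shorter than 8 bp keep the slippage signature distinct from a
#'   dispersed-repeat (ISD) signature.
#' @return a classed list.
#' @export
simEvent <- function(branch, kind = c("ISD", "SSM", "recombination_del",
                                      "recombination_ins", "micro_indel"),
                     length, repeat_len = 10L, unit_len = NULL,
                     copy_delta = NULL) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (kind == "micro_indel") {
    if (length >= 50L) stop("micro_indel must be < 50 bp")
  } else if (length < 50L) stop(kind, " events must be >= 50 bp")
  if (kind == "ISD" && repeat_len < 8L)
    stop("ISD repeat_len must be >= 8 to be detectable at defaults")
  if (kind == "SSM") {
    if (is.null(unit_len) || is.null(copy_delta))
      stop("SSM events need unit_len and copy_delta")
    if (unit_len * copy_delta != length)
      stop("SSM length must equal unit_len * copy_delta")
  }
  structure(list(branch = sort(as.character(branch)), kind = kind,
                 length = length, repeat_len = as.integer(repeat_len),
                 unit_len = if (is.null(unit_len)) NA_integer_
                            else as.integer(unit_len),
                 copy_delta = if (is.null(copy_delta)) NA_integer_
                              else as.integer(copy_delta)),
            class = "simEvent")
}

#' Random quadripartite plastome-like root sequence
#'
#' Builds LSC + IRb + SSC + reverse-complement(IRb), so
#' \code{\link{findInvertedRepeat}} recovers the planted IR pair exactly.
#'
#' @param lsc,ir,ssc region lengths in bp (all > 0).
#' @param at_target target percent AT of the random sequence.
#' @param seed optional RNG seed for reproducibility.
#' @return list with \code{sequence} and the true \code{partition}
#'   (a \linkS4class{QuadripartitePartition}).
#' @export
makeQuadripartiteRoot <- function(lsc, ir, ssc, at_target = 50, seed = NULL) {
  stopifnot(lsc > 0L, ir > 0L, ssc > 0L)
  if (!is.null(seed)) set.seed(seed)
  at <- at_target / 100
  L <- .randSeq(lsc, at); R <- .randSeq(ir, at); S <- .randSeq(ssc, at)
  # pin the four IR-junction neighbours so the planted IR pair is exactly
  # maximal (no chance 1 bp extension across a junction, in any rotation)
  substr(L, 1L, 1L) <- "A"; substr(L, lsc, lsc) <- "A"
  substr(S, 1L, 1L) <- "A"; substr(S, ssc, ssc) <- "A"
  seqn <- paste0(L, R, S, .revcomp(R))
  lsc <- as.integer(lsc); ir <- as.integer(ir); ssc <- as.integer(ssc)
  part <- new("QuadripartitePartition",
              lsc = c(1L, lsc),
              irb = c(lsc + 1L, lsc + ir),
              ssc = c(lsc + ir + 1L, lsc + ir + ssc),
              ira = c(lsc + ir + ssc + 1L, lsc + 2L * ir + ssc),
              ir_length = ir, lsc_length = lsc, ssc_length = ssc)
  list(sequence = seqn, partition = part)
}

# map each edge to its sorted subtended leaf set
.edgeClades <- function(tree) {
  idx <- .treeIndex(tree)
  lapply(seq_len(nrow(tree$edge)), function(i)
    .cladeLeaves(tree, tree$edge[i, 2L], idx))
}

# JC69 substitutions over a branch of expected d substitutions/site
.jcMutate <- function(bases, d) {
  if (d <= 0 || !length(bases)) return(bases)
  p_change <- 3 / 4 * (1 - exp(-4 / 3 * d))
  hit <- which(stats::runif(length(bases)) < p_change)
  if (length(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    bases[hit] <- vapply(bases[hit], function(b) {
      j <- sample.int(3L, 1L)
      substr(alt[[b]], j, j)
    }, character(1L))
  }
  bases
}

# draw a tandem unit with no internal sub-period (keeps the smallest
# detected unit equal to the planted unit)
.drawUnit <- function(ul, at) {
  for (i in 1:50) {
    u <- .randSeq(ul, at)
    ok <- TRUE
    if (ul > 1L) for (d in seq_len(ul - 1L)) {
      if (ul %% d == 0L && strrep(substr(u, 1L, d), ul %/% d) == u) {
        ok <- FALSE; break
      }
    }
    if (ok) return(u)
  }
  u
}

#' Simulate plastome evolution with planted indel events of known mechanism
#'
#' Evolves a root sequence down a tree under JC69 substitutions and plants
#' indel events on chosen branches: ISD events write a direct repeat at
#' both ends of the chosen span in the parent and delete from the first
#' copy's start through the second copy's start in the child lineage
#' (leaving one copy, the classic intrastrand-deletion footprint); SSM
#' events seed a tandem array in the parent and contract it by
#' \code{copy_delta} units in the child; recombination events are plain
#' span deletions/insertions with junctions kept free of flanking repeats.
#' The true alignment is constructed from the known edit history, so
#' detection can be tested without running an aligner. Event positions are
#' drawn (seeded) in disjoint windows so the truth is unambiguous.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths (>= 0).
#' @param root_len root sequence length in bp (ignored if \code{root_seq}
#'   given).
#' @param rate substitution rate scaling: a branch of length t receives an
#'   expected \code{rate * t} substitutions per site (JC69, multiple hits
#'   included).
#' @param events list of \code{\link{simEvent}} specifications.
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @param at_target percent AT of the random root sequence.
#' @param root_seq optional explicit root sequence.
#' @return list with \code{sequences} (named ungapped leaf strings),
#'   \code{alignment} (the true \linkS4class{RgcAlignment}),
#'   \code{truth} (one row per planted event: event_id, branch, kind,
#'   affected_taxa, gap_taxa, aln_start, aln_end, length, repeat_seq) and
#'   \code{tree}.
#' @export
simulatePlastomeEvolution <- function(tree, root_len = 10000L, rate = 0,
                                      events = list(), seed = 1L,
                                      at_target = 62, root_seq = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  set.seed(as.integer(seed))
  at <- at_target / 100
  if (is.null(root_seq)) root_seq <- .randSeq(root_len, at)
  root_len <- nchar(root_seq)

  clades <- .edgeClades(tree)
  ev_edge <- vapply(events, function(e) {
    hit <- which(vapply(clades, identical, logical(1L), y = e$branch))
    if (!length(hit))
      stop("no branch subtends exactly {",
           paste(e$branch, collapse = ", "), "}")
    hit[1L]
  }, integer(1L))

  # one disjoint window per event, in root coordinates
  n_ev <- length(events)
  margin <- 50L
  if (n_ev) {
    ext <- vapply(events, function(e)
      e$length + (if (e$kind == "ISD") e$repeat_len else 0L), integer(1L))
    slot_w <- (root_len - 2L * margin) %/% n_ev
    if (any(ext + 2L * margin + 1L > slot_w))
      stop("root sequence too short for the requested events")
    slot_order <- sample.int(n_ev)
    pos <- integer(n_ev)
    for (i in seq_len(n_ev)) {
      s <- slot_order[i]
      base <- margin + (i - 1L) * slot_w
      pos[s] <- base + margin +
        sample.int(slot_w - 2L * margin - ext[s] + 1L, 1L) - 1L
    }
  } else pos <- integer(0L)

  idx <- .treeIndex(tree)
  ntip <- idx$ntip
  node_bases <- vector("list", idx$nnode)
  node_ids <- vector("list", idx$nnode)
  node_bases[[idx$root]] <- strsplit(root_seq, "")[[1L]]
  node_ids[[idx$root]] <- as.numeric(seq_len(root_len))
  truth_rows <- list()
  next_ins_id <- root_len + 1

  edge_of <- function(parent, child) {
    which(tree$edge[, 1L] == parent & tree$edge[, 2L] == child)
  }

  for (v in .preorderNodes(idx$children, idx$root)) {
    kids <- idx$children[[v]]
    if (!length(kids)) next
    # plant parental context (repeat copies / tandem arrays) for events on
    # edges out of v, before any child is derived
    for (k in which(ev_edge %in% vapply(kids, edge_of, integer(1L),
                                        parent = v))) {
      e <- events[[k]]
      bas <- node_bases[[v]]
      i <- findInterval(pos[k] - 0.5, node_ids[[v]]) + 1L
      if (e$kind == "ISD") {
        R <- strsplit(.randSeq(e$repeat_len, at), "")[[1L]]
        bas[i:(i + e$repeat_len - 1L)] <- R
        bas[(i + e$length):(i + e$length + e$repeat_len - 1L)] <- R
        attr(events[[k]], "repeat_seq") <- paste(R, collapse = "")
      } else if (e$kind == "SSM") {
        u <- .drawUnit(e$unit_len, at)
        arr <- strsplit(strrep(u, e$copy_delta + 1L), "")[[1L]]
        bas[i:(i + length(arr) - 1L)] <- arr
        attr(events[[k]], "repeat_seq") <- u
      } else if (e$kind %in% c("recombination_del", "micro_indel")) {
        # keep the junction free of flanking direct repeats so the event
        # cannot masquerade as an ISD
        cfg <- mechanismConfig()
        for (try in 1:25) {
          s_str <- paste(bas, collapse = "")
          hit <- .bestRepeatInRef(s_str, i, i + e$length, cfg)
          if (is.null(hit)) break
          w1 <- max(1L, i + e$length - 10L)
          w2 <- min(length(bas), i + e$length + 10L)
          bas[w1:w2] <- strsplit(.randSeq(w2 - w1 + 1L, at), "")[[1L]]
        }
      }
      attr(events[[k]], "anchor") <- i
      node_bases[[v]] <- bas
    }
    for (child in kids) {
      ed <- edge_of(v, child)
      bas <- node_bases[[v]]
      ids <- node_ids[[v]]
      for (k in which(ev_edge == ed)) {
        e <- events[[k]]
        i <- findInterval(pos[k] - 0.5, ids) + 1L
        if (e$kind == "recombination_ins") {
          ins <- strsplit(.randSeq(e$length, at), "")[[1L]]
          left_id <- if (i > 1L) ids[i - 1L] else 0
          right_id <- if (i <= length(ids)) ids[i] else left_id + 1
          new_ids <- left_id + seq_len(e$length) *
            (right_id - left_id) / (e$length + 1)
          bas <- append(bas, ins, after = i - 1L)
          ids <- append(ids, new_ids, after = i - 1L)
          attr(events[[k]], "column_ids") <- new_ids
        } else {
          del <- i:(i + e$length - 1L)
          attr(events[[k]], "column_ids") <- ids[del]
          bas <- bas[-del]
          ids <- ids[-del]
        }
      }
      bas <- .jcMutate(bas, rate * tree$edge.length[ed])
      node_bases[[child]] <- bas
      node_ids[[child]] <- ids
    }
  }

  # assemble the true alignment over the union of surviving column ids
  leaf_ids <- node_ids[seq_len(ntip)]
  all_ids <- sort(unique(c(unlist(leaf_ids),
                           unlist(lapply(events, attr, "column_ids")))))
  rows <- vapply(seq_len(ntip), function(i) {
    r <- rep("-", length(all_ids))
    r[match(leaf_ids[[i]], all_ids)] <- node_bases[[i]]
    paste(r, collapse = "")
  }, character(1L))
  names(rows) <- tree$tip.label
  aln <- RgcAlignment(rows)

  truth <- do.call(rbind, lapply(seq_along(events), function(k) {
    e <- events[[k]]
    cols <- match(attr(e, "column_ids"), all_ids)
    affected <- clades[[ev_edge[k]]]
    gap_taxa <- if (e$kind == "recombination_ins")
      sort(setdiff(tree$tip.label, affected)) else sort(affected)
    data.frame(event_id = sprintf("sim_%02d", k),
               branch = paste(e$branch, collapse = ","),
               kind = e$kind,
               affected_taxa = paste(affected, collapse = ","),
               gap_taxa = paste(gap_taxa, collapse = ","),
               aln_start = min(cols), aln_end = max(cols),
               length = e$length,
               repeat_seq = if (is.null(attr(e, "repeat_seq")))
                 NA_character_ else attr(e, "repeat_seq"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(event_id = character(), branch = character(),
                        kind = character(), affected_taxa = character(),
                        gap_taxa = character(), aln_start = integer(),
                        aln_end = integer(), length = integer(),
                        repeat_seq = character(), stringsAsFactors = FALSE)

  list(sequences = setNames(vapply(seq_len(ntip), function(i)
         paste(node_bases[[i]], collapse = ""), character(1L)),
         tree$tip.label),
       alignment = aln, truth = truth, tree = tree)
}
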