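# children list and a postorder of internal/leaf nodes for an ape phylo
.treeIndex <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  children <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    children[[p]] <- c(children[[p]], c)
  }
  list(ntip = ntip, nnode = nnode, root = ntip + 1L,
       children = children,
       postorder = rev(.preorderNodes(children, ntip + 1L)))
}

.preorderNodes <- function(children, root) {
  out <- integer(0L)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  out
}

# unit-cost small-parsimony DP over binary states; '?' = {0,1}
.parsimonyDP <- function(tree, states) {
  idx <- .treeIndex(tree)
  labs <- tree$tip.label
  miss <- setdiff(labs, names(states))
  if (length(miss))
    stop("leaf missing from character: ", paste(miss, collapse = ", "))
  cost <- matrix(Inf, nrow = idx$nnode, ncol = 2L)  # cols: state 0, state 1
  for (i in seq_len(idx$ntip)) {
    s <- states[[labs[i]]]
    if (s %in% c("0", "?")) cost[i, 1L] <- 0
    if (s %in% c("1", "?")) cost[i, 2L] <- 0
  }
  for (v in idx$postorder) {
    kids <- idx$children[[v]]
    if (!length(kids)) next
    for (s in 1:2) {
      tot <- 0
      for (k in kids) tot <- tot + min(cost[k, s], cost[k, 3L - s] + 1)
      cost[v, s] <- tot
    }
  }
  list(idx = idx, cost = cost)
}

#' Minimum number of state changes of a binary character on a tree
#'
#' Small-parsimony (Fitch) count of the minimum number of 0/1 state
#' changes needed to explain the leaf states on the tree, computed by
#' unit-cost dynamic programming so that polytomies are scored exactly.
#' '?' states are treated as the full state set \{0,1\}; the count is
#' independent of the root position.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param states named character vector ("0"/"1"/"?") covering all leaves
#'   (extra taxa are ignored); or a column of \code{\link{binaryStates}}.
#' @return integer minimum change count.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitchCount(tr, c(A = "1", B = "1", C = "0", D = "0"))  # 1
#' @export
fitchCount <- function(tree, states) {
  dp <- .parsimonyDP(tree, states)
  mc <- min(dp$cost[dp$idx$root, ])
  if (!is.finite(mc)) stop("character has no consistent assignment")
  as.integer(mc)
}

# one minimal reconstruction; ties resolve toward the parental state
# (changes placed as late as possible), so '?' leaves are never swept into
# a derived clade -- the conservative treatment of missing data. Root tie
# prefers the ancestral state 0.
.reconstructStates <- function(dp) {
  idx <- dp$idx; cost <- dp$cost
  assign <- integer(idx$nnode)
  root <- idx$root
  assign[root] <- if (cost[root, 1L] <= cost[root, 2L]) 0L else 1L
  for (v in .preorderNodes(idx$children, root)) {
    for (k in idx$children[[v]]) {
      ps <- assign[v]
      keep <- cost[k, ps + 1L]               # child stays
      flip <- cost[k, 2L - ps] + 1L          # child changes
      assign[k] <- if (flip < keep) 1L - ps else ps
    }
  }
  assign
}

# leaf label set below each node
.cladeLeaves <- function(tree, node, idx) {
  if (node <= idx$ntip) return(tree$tip.label[node])
  kids <- idx$children[[node]]
  sort(unlist(lapply(kids, .cladeLeaves, tree = tree, idx = idx)))
}

#' Classify a binary RGC character on a tree
#'
#' Maps the character by small parsimony and classifies it:
#' \emph{synapomorphy} (one change, on an internal edge: the derived state
#' defines a clade of two or more leaves), \emph{autapomorphy} (one change
#' on a terminal edge), \emph{homoplasy} (two or more changes required),
#' or \emph{invariant} (no change). Supporting edges are the edges where a
#' 0 to 1 change is reconstructed under a minimal reconstruction whose
#' ties resolve toward the parental state (so missing-data leaves are not
#' swept into derived clades), each reported as its subtended leaf set.
#'
#' @inheritParams fitchCount
#' @param outgroup optional taxon label(s); when given and present in the
#'   tree, the tree is (re)rooted on the outgroup before classification so
#'   the ancestral state sits at the root.
#' @return list with \code{event_id} (NA unless supplied downstream),
#'   \code{min_changes}, \code{marker_class}, \code{supporting_edges}
#'   (list of leaf-label vectors).
#' @export
classifyMarker <- function(tree, states, outgroup = NULL) {
  if (!is.null(outgroup) && any(outgroup %in% tree$tip.label))
    tree <- ape::root(tree, outgroup[outgroup %in% tree$tip.label][1L],
                      resolve.root = TRUE)
  if (all(states[tree$tip.label] == "?")) {
    warning("all-? character: invariant")
    return(list(min_changes = 0L, marker_class = "invariant",
                supporting_edges = list()))
  }
  dp <- .parsimonyDP(tree, states)
  mc <- as.integer(min(dp$cost[dp$idx$root, ]))
  if (mc == 0L)
    return(list(min_changes = 0L, marker_class = "invariant",
                supporting_edges = list()))
  assign <- .reconstructStates(dp)
  idx <- dp$idx
  gains <- list()
  for (v in seq_len(idx$nnode)) {
    for (k in idx$children[[v]]) {
      if (assign[v] == 0L && assign[k] == 1L)
        gains[[length(gains) + 1L]] <- .cladeLeaves(tree, k, idx)
    }
  }
  cls <- if (mc >= 2L) "homoplasy"
         else if (length(gains) == 1L && length(gains[[1L]]) >= 2L)
           "synapomorphy"
         else "autapomorphy"
  list(min_changes = mc, marker_class = cls, supporting_edges = gains)
}

#' Per-clade taxonomic-marker report for a binary matrix
#'
#' Classifies every character of the matrix on the tree and assembles the
#' marker report: synapomorphies grouped by the clade they define, with
#' sequential letter-number codes (letter = clade series in order of first
#' appearance, number = running index within the clade), plus the
#' autapomorphy and homoplasy lists and summary counts.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param m an \linkS4class{RgcBinaryMatrix}.
#' @param outgroup optional outgroup label(s) used to root the tree.
#' @return list with \code{markers} (one row per character: event_id,
#'   marker_class, min_changes, code, clade), \code{counts} (named integer
#'   vector) and \code{clades} (clade leaf sets by letter).
#' @export
markerReport <- function(tree, m, outgroup = NULL) {
  stopifnot(is(m, "RgcBinaryMatrix"))
  st <- binaryStates(m)
  if (!ncol(st)) {
    return(list(markers = data.frame(event_id = character(),
                                     marker_class = character(),
                                     min_changes = integer(),
                                     code = character(),
                                     clade = character(),
                                     stringsAsFactors = FALSE),
                counts = c(synapomorphy = 0L, autapomorphy = 0L,
                           homoplasy = 0L, invariant = 0L),
                clades = list()))
  }
  rows <- list()
  clade_keys <- character(0L)
  clade_n <- integer(0L)
  for (j in seq_len(ncol(st))) {
    res <- classifyMarker(tree, st[, j], outgroup = outgroup)
    clade <- if (length(res$supporting_edges) == 1L)
      paste(res$supporting_edges[[1L]], collapse = ",") else NA_character_
    code <- NA_character_
    if (res$marker_class == "synapomorphy") {
      k <- match(clade, clade_keys)
      if (is.na(k)) {
        clade_keys <- c(clade_keys, clade)
        clade_n <- c(clade_n, 0L)
        k <- length(clade_keys)
      }
      clade_n[k] <- clade_n[k] + 1L
      code <- paste0(LETTERS[(k - 1L) %% 26L + 1L], clade_n[k])
    }
    rows[[j]] <- data.frame(event_id = colnames(st)[j],
                            marker_class = res$marker_class,
                            min_changes = res$min_changes,
                            code = code, clade = clade,
                            stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, rows)
  counts <- vapply(c("synapomorphy", "autapomorphy", "homoplasy",
                     "invariant"),
                   function(k) sum(markers$marker_class == k), integer(1L))
  clades <- as.list(clade_keys)
  names(clades) <- LETTERS[seq_along(clade_keys)]
  list(markers = markers, counts = counts, clades = clades)
}
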