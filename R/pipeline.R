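#' @importFrom stats setNames runif
#' @importFrom utils write.table packageVersion
NULL

# event table -> flat TSV-ready data.frame
.eventsFlat <- function(events) {
  out <- events
  out$gap_taxa <- vapply(events$gap_taxa, paste, character(1L),
                         collapse = ",")
  out
}

#' Run the full RGC scan pipeline
#'
#' Executes the analysis in its canonical order: read the alignment,
#' optionally excise the IRa interval, extract gap runs and characterize
#' RGC on the \emph{unstripped} alignment (events must be characterized
#' before gap-column stripping, which destroys them), classify mechanisms,
#' polarize against the outgroups and build the binary matrix, then strip
#' gap columns for the sequence matrix and write the exports: event and
#' mechanism report (TSV), restriction-datatype NEXUS, combined relaxed
#' PHYLIP + partition file, stripped alignment, marker report (when a tree
#' is given) and a run manifest. Any stage error aborts with the stage
#' name and removes partial outputs.
#'
#' @param alignment path to an aligned FASTA, or an
#'   \linkS4class{RgcAlignment}.
#' @param outgroups character vector of outgroup taxon labels (non-empty).
#' @param out_dir output directory (created if needed).
#' @param tree optional newick path or \code{ape::phylo}; enables the
#'   marker-mapping step.
#' @param ira_interval optional integer(2): 1-based closed alignment-column
#'   interval of the second inverted-repeat copy to excise first.
#' @param rgc_cfg an \code{\link{rgcConfig}}.
#' @param mech_cfg a \code{\link{mechanismConfig}}.
#' @param strip_mode gap-column stripping mode for the exported sequence
#'   matrix (see \code{\link{stripGapColumns}}).
#' @return (invisibly) a list with the event tables (\code{events},
#'   \code{rgc}, \code{microstructural}), the \code{matrix}
#'   (\linkS4class{RgcBinaryMatrix}), the \code{markers} report (or NULL),
#'   the stripped alignment, and \code{paths} of all written files.
#' @export
runScan <- function(alignment, outgroups, out_dir,
                    tree = NULL, ira_interval = NULL,
                    rgc_cfg = rgcConfig(), mech_cfg = mechanismConfig(),
                    strip_mode = "any_gap") {
  if (!length(outgroups)) stop("config error: outgroups must be non-empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0L)
  stage <- "read_alignment"
  res <- tryCatch({
    aln <- if (is(alignment, "RgcAlignment")) alignment
           else readAlignment(alignment)
    miss <- setdiff(outgroups, taxa(aln))
    if (length(miss))
      stop("outgroup taxon missing from alignment: ",
           paste(miss, collapse = ", "))

    if (!is.null(ira_interval)) {
      stage <- "excise_ira"
      aln <- exciseInterval(aln, ira_interval[1L], ira_interval[2L])
    }

    stage <- "detect"
    runs <- extractGapRuns(aln)
    events <- clusterEvents(runs, rgc_cfg)
    events <- flagAmbiguous(events, aln, outgroups, rgc_cfg)

    stage <- "mechanism"
    events <- classifyMechanisms(aln, events, mech_cfg)
    flt <- filterRgc(events, rgc_cfg)

    stage <- "polarize"
    chars <- lapply(seq_len(nrow(flt$rgc)), function(i)
      polarizeEvent(flt$rgc[i, , drop = FALSE], aln, outgroups,
                    rgc_cfg$nested_gap_tol))
    bm <- buildBinaryMatrix(chars)

    stage <- "strip"
    stripped <- stripGapColumns(aln, strip_mode)

    stage <- "markers"
    markers <- NULL
    if (!is.null(tree)) {
      tr <- if (inherits(tree, "phylo")) tree else readNewick(tree)
      markers <- markerReport(tr, bm, outgroup = outgroups)
    }

    stage <- "write"
    p_events <- file.path(out_dir, "events.tsv")
    write.table(.eventsFlat(events), p_events, sep = "\t",
                quote = FALSE, row.names = FALSE)
    written <- c(written, p_events)
    p_nex <- file.path(out_dir, "rgc_matrix.nex")
    writeRestrictionNexus(bm, p_nex)
    written <- c(written, p_nex)
    p_strip <- file.path(out_dir, "stripped.fasta")
    writeAlignment(stripped, p_strip)
    written <- c(written, p_strip)
    p_comb <- writeCombined(stripped, bm, file.path(out_dir, "combined"))
    written <- c(written, p_comb)
    if (!is.null(markers)) {
      p_mark <- file.path(out_dir, "markers.tsv")
      write.table(markers$markers, p_mark, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      written <- c(written, p_mark)
    }
    p_manifest <- file.path(out_dir, "manifest.txt")
    writeLines(c(
      sprintf("rgcscan %s", as.character(packageVersion("rgcscan"))),
      "stages: read_alignment, excise_ira, detect, mechanism, polarize, strip, markers, write",
      sprintf("taxa: %d", length(taxa(aln))),
      sprintf("columns_unstripped: %d", alnWidth(aln)),
      sprintf("columns_stripped: %d", alnWidth(stripped)),
      sprintf("events_total: %d", nrow(events)),
      sprintf("events_non_ambiguous: %d",
              sum(events$status == "non_ambiguous")),
      sprintf("rgc: %d", nrow(flt$rgc)),
      sprintf("microstructural: %d", nrow(flt$microstructural)),
      sprintf("binary_characters: %d", ncol(binaryStates(bm))),
      sprintf("min_rgc_len: %d", rgc_cfg$min_rgc_len),
      sprintf("min_repeat_len: %d", mech_cfg$min_repeat_len),
      sprintf("outgroups: %s", paste(outgroups, collapse = ","))),
      p_manifest)
    written <- c(written, p_manifest)

    list(events = events, rgc = flt$rgc,
         microstructural = flt$microstructural, matrix = bm,
         markers = markers, stripped = stripped,
         paths = written)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
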