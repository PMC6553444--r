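test_that("gap runs are maximal, complete and flagged at edges", {
  aln <- RgcAlignment(c(A = "AC--T-", B = "ACGGTC", C = "--GGTC"))
  runs <- extractGapRuns(aln)
  a <- runs[runs$taxon == "A", ]
  expect_identical(a$start, c(3L, 6L))
  expect_identical(a$length, c(2L, 1L))
  expect_identical(a$terminal, c(FALSE, TRUE))
  expect_true(runs[runs$taxon == "C", "terminal"])

  expect_identical(nrow(extractGapRuns(RgcAlignment(c(A = "ACGT",
                                                      B = "ACGT")))), 0L)

  # every gap character belongs to exactly one run
  set.seed(13)
  for (rep in 1:5) {
    rows <- rand_gapped_rows(8L, 120L)
    runs <- extractGapRuns(RgcAlignment(rows))
    n_gaps <- sum(vapply(strsplit(rows, ""), function(x) sum(x == "-"),
                         integer(1L)))
    expect_identical(sum(runs$length), n_gaps)
  }
})

test_that("documented runs appear in the worked-example windows", {
  r4 <- extractGapRuns(psbE_petL_aln())
  pf <- r4[r4$taxon == "Polypogon_fugax", ]
  expect_identical(pf[which.max(pf$length), "length"], 63L)
  expect_identical(pf[which.max(pf$length), "start"], 4L)
  expect_identical(pf[which.max(pf$length), "end"], 66L)

  r5 <- extractGapRuns(psaJ_rpl33_aln())
  fo <- r5[r5$taxon == "Festuca_ovina_NC_019649", ]
  expect_identical(fo$length, 78L)
  expect_identical(c(fo$start, fo$end), c(4L, 81L))
})

test_that("run clustering merges identical intervals into shared events", {
  ev <- clusterEvents(extractGapRuns(psbE_petL_aln()))
  ag <- ev[vapply(ev$gap_taxa, function(g)
    setequal(g, c("Agrostis_gigantea", "Agrostis_stolonifera")),
    logical(1L)), ]
  expect_identical(nrow(ag), 1L)
  expect_identical(ag$length, 32L)

  # slop 0: off-by-one boundaries stay distinct
  runs <- data.frame(taxon = c("A", "B"), start = c(10L, 10L),
                     end = c(59L, 60L), length = c(50L, 51L),
                     terminal = FALSE, stringsAsFactors = FALSE)
  expect_identical(nrow(clusterEvents(runs, rgcConfig())), 2L)
  expect_identical(nrow(clusterEvents(runs, rgcConfig(boundary_slop = 1L))),
                   1L)

  # partition property: every non-terminal run maps to exactly one event
  set.seed(17)
  for (rep in 1:5) {
    rows <- rand_gapped_rows(6L, 150L)
    runs <- extractGapRuns(RgcAlignment(rows))
    ev <- clusterEvents(runs, rgcConfig())
    nonterm <- runs[!runs$terminal, ]
    expect_identical(sum(ev$n_taxa), nrow(nonterm))
    for (i in seq_len(nrow(nonterm))) {
      hit <- ev$start == nonterm$start[i] & ev$end == nonterm$end[i]
      expect_identical(sum(hit), 1L)
    }
  }
})

test_that("ambiguity culling follows the crossing/density/outgroup rules", {
  a4 <- psbE_petL_aln()
  ev <- flagAmbiguous(clusterEvents(extractGapRuns(a4)), a4,
                      outgroups = "Amelichloa_brachychaeta")
  big <- ev[ev$length == 63L, ]
  expect_identical(big$status, "non_ambiguous")

  # with terminal runs admitted, the window-leading runs cross the long
  # deletion and become ambiguous
  cfg_t <- rgcConfig(include_terminal_runs = TRUE)
  ev_t <- flagAmbiguous(clusterEvents(extractGapRuns(a4), cfg_t), a4,
                        cfg = cfg_t)
  lead <- ev_t[ev_t$start == 1L, ]
  expect_true(all(lead$status == "ambiguous"))
  expect_true(all(lead$ambiguity_reason == "crossing_overlap"))

  # isolated event among gapless neighbours is never ambiguous; taxa
  # sharing one cluster are not mutually ambiguous
  iso <- RgcAlignment(c(O = strrep("A", 30),
                        X = paste0(strrep("A", 10), strrep("-", 10),
                                   strrep("A", 10)),
                        Y = paste0(strrep("A", 10), strrep("-", 10),
                                   strrep("A", 10)),
                        Z = strrep("A", 30)))
  ev_i <- flagAmbiguous(clusterEvents(extractGapRuns(iso)), iso,
                        outgroups = "O")
  expect_identical(nrow(ev_i), 1L)
  expect_identical(ev_i$status, "non_ambiguous")
  expect_true(setequal(ev_i$gap_taxa[[1L]], c("X", "Y")))

  # outgroup with a partial gap over the span makes the event ambiguous
  og_p <- RgcAlignment(c(O = paste0(strrep("A", 12), strrep("-", 6),
                                    strrep("A", 12)),
                         X = paste0(strrep("A", 10), strrep("-", 10),
                                    strrep("A", 10)),
                         Z = strrep("A", 30)))
  ev_o <- flagAmbiguous(clusterEvents(extractGapRuns(og_p)), og_p,
                        outgroups = "O")
  expect_identical(ev_o$status[ev_o$length == 10L], "ambiguous")
  expect_identical(ev_o$ambiguity_reason[ev_o$length == 10L],
                   "outgroup_partial")
})

test_that("the RGC size filter is inclusive at 50 and monotone", {
  mk <- function(lens) {
    n <- length(lens)
    starts <- cumsum(c(1L, head(lens, -1L) + 20L))
    data.frame(id = paste0("e", seq_len(n)), start = starts,
               end = starts + lens - 1L, length = lens, n_taxa = 1L,
               gap_taxa = I(as.list(paste0("t", seq_len(n)))),
               status = "non_ambiguous", ambiguity_reason = "",
               stringsAsFactors = FALSE)
  }
  flt <- filterRgc(mk(c(4L, 49L, 50L, 63L)), rgcConfig())
  expect_identical(flt$rgc$length, c(50L, 63L))
  expect_identical(flt$microstructural$length, c(4L, 49L))

  empty <- clusterEvents(extractGapRuns(RgcAlignment(c(A = "ACGT",
                                                       B = "ACGT"))))
  expect_identical(nrow(filterRgc(empty, rgcConfig())$rgc), 0L)

  # monotonicity: raising the threshold never increases the RGC count
  lens <- sample(1:600, 40L, replace = TRUE)
  ev <- mk(as.integer(lens))
  counts <- vapply(c(1L, 10L, 50L, 100L, 400L), function(th)
    nrow(filterRgc(ev, rgcConfig(min_rgc_len = th))$rgc), integer(1L))
  expect_true(all(diff(counts) <= 0L))
})
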