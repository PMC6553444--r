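mk_event2 <- function(start, end, taxa) {
  data.frame(id = sprintf("rgc_%06d_%06d", start, end), start = start,
             end = end, length = end - start + 1L, n_taxa = length(taxa),
             gap_taxa = I(list(sort(taxa))), status = "non_ambiguous",
             ambiguity_reason = "", stringsAsFactors = FALSE)
}

test_that("polarization takes the outgroup condition as ancestral", {
  a4 <- psbE_petL_aln()
  ev <- mk_event2(4L, 66L, "Polypogon_fugax")
  pol <- polarizeEvent(ev, a4, "Amelichloa_brachychaeta")
  expect_identical(pol$ancestral_condition, "span_present")
  expect_identical(pol$polarity, "deletion")
  expect_identical(unname(pol$states[["Polypogon_fugax"]]), "1")
  expect_identical(unname(pol$states[["Amelichloa_brachychaeta"]]), "0")
  expect_identical(unname(pol$states[["Triplachne_nitens"]]), "0")
  # taxa gapped over about half the span are coded as missing
  expect_identical(unname(pol$states[["Agrostis_gigantea"]]), "?")

  expect_error(polarizeEvent(ev, a4, "Not_a_taxon"), "missing from")
})

test_that("a gapped outgroup polarizes residue carriers as insertions", {
  aln <- RgcAlignment(c(
    OG = paste0(strrep("A", 10L), strrep("-", 12L), strrep("A", 10L)),
    IN = strrep("C", 32L),
    T2 = paste0(strrep("G", 10L), strrep("-", 12L), strrep("G", 10L)),
    T3 = paste0(strrep("T", 10L), "T-----------", strrep("T", 10L))))
  ev <- mk_event2(11L, 22L, c("OG", "T2"))
  pol <- polarizeEvent(ev, aln, "OG")
  expect_identical(pol$ancestral_condition, "span_absent")
  expect_identical(pol$polarity, "insertion")
  expect_identical(unname(pol$states[["IN"]]), "1")
  expect_identical(unname(pol$states[["T2"]]), "0")
  expect_identical(unname(pol$states[["T3"]]), "?")  # partial span
})

test_that("conflicting outgroups drop the character", {
  aln <- RgcAlignment(c(
    O1 = strrep("A", 30L),
    O2 = paste0(strrep("A", 10L), strrep("-", 10L), strrep("A", 10L)),
    X = paste0(strrep("C", 10L), strrep("-", 10L), strrep("C", 10L))))
  ev <- mk_event2(11L, 20L, c("O2", "X"))
  expect_warning(pol <- polarizeEvent(ev, aln, c("O1", "O2")),
                 "outgroup conflict")
  expect_null(pol)
})

test_that("matrix assembly drops invariant characters and keys all taxa", {
  a4 <- psbE_petL_aln()
  og <- "Amelichloa_brachychaeta"
  pol <- polarizeEvent(mk_event2(4L, 66L, "Polypogon_fugax"), a4, og)
  # an all-ancestral character: nothing shows the derived state
  inv <- pol
  inv$event_id <- "inv_char"
  inv$states[] <- "0"
  expect_message(bm <- buildBinaryMatrix(list(pol, inv, NULL)),
                 "invariant")
  expect_identical(ncol(binaryStates(bm)), 1L)
  expect_identical(rownames(binaryStates(bm)), taxa(a4))
  expect_identical(characterInfo(bm)$polarity, "deletion")

  empty <- buildBinaryMatrix(list())
  expect_identical(ncol(binaryStates(empty)), 0L)

  # outgroup taxa never carry the derived state, by construction
  set.seed(23)
  for (rep in 1:5) {
    rows <- rand_gapped_rows(6L, 80L, gap_p = 0.08)
    aln <- RgcAlignment(rows)
    ev <- flagAmbiguous(clusterEvents(extractGapRuns(aln)), aln, "t1")
    ev <- ev[ev$status == "non_ambiguous", , drop = FALSE]
    chars <- lapply(seq_len(nrow(ev)), function(i)
      suppressWarnings(polarizeEvent(ev[i, , drop = FALSE], aln, "t1")))
    bm <- suppressMessages(buildBinaryMatrix(chars))
    if (ncol(binaryStates(bm)))
      expect_true(all(binaryStates(bm)["t1", ] != "1"))
  }
})

test_that("restriction NEXUS round-trips states, ids and awkward labels", {
  st <- matrix(c("0", "1", "?", "1",
                 "1", "0", "0", "?"), nrow = 4L,
               dimnames = list(c("plain", "with space", "it's",
                                 "semi;colon"),
                               c("ev_a", "ev_b")))
  m <- new("RgcBinaryMatrix", states = st,
           info = data.frame(event_id = c("ev_a", "ev_b"),
                             ancestral_condition = "span_present",
                             polarity = "deletion",
                             stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".nex")
  writeRestrictionNexus(m, f)
  txt <- readLines(f)
  expect_true(any(grepl("DATATYPE=RESTRICTION", txt)))
  expect_true(any(grepl("MISSING=\\?", txt)))
  expect_true(any(grepl("SYMBOLS=\"01\"", txt)))
  expect_true(any(grepl("'with space'", txt)))
  back <- readRestrictionNexus(f)
  expect_identical(binaryStates(back), binaryStates(m))

  # 2x2 and empty matrices round-trip too
  m2 <- new("RgcBinaryMatrix",
            states = matrix(c("0", "1", "1", "0"), 2L,
                            dimnames = list(c("A", "B"), c("x", "y"))),
            info = data.frame(event_id = c("x", "y"),
                              ancestral_condition = "span_present",
                              polarity = "deletion",
                              stringsAsFactors = FALSE))
  writeRestrictionNexus(m2, f)
  expect_identical(binaryStates(readRestrictionNexus(f)),
                   binaryStates(m2))
})

test_that("combined PHYLIP export has additive widths and a partition file", {
  aln <- RgcAlignment(setNames(replicate(4L, rand_dna(100L)),
                               c("A", "B", "C", "D")))
  st <- matrix(sample(c("0", "1"), 24L, replace = TRUE), nrow = 4L,
               dimnames = list(c("A", "B", "C", "D"), paste0("e", 1:6)))
  st[1L, ] <- "0"; st[2L, 1L] <- "1"
  m <- new("RgcBinaryMatrix", states = st,
           info = data.frame(event_id = paste0("e", 1:6),
                             ancestral_condition = "span_present",
                             polarity = "deletion",
                             stringsAsFactors = FALSE))
  pref <- tempfile()
  paths <- writeCombined(aln, m, pref)
  phy <- readLines(paths[1L])
  expect_identical(phy[1L], "4 106")
  body <- strsplit(trimws(phy[-1L]), "\\s+")
  expect_true(all(vapply(body, function(x) nchar(x[2L]), integer(1L)) ==
                  106L))
  expect_identical(readLines(paths[2L]),
                   c("DNA, seq = 1-100", "BIN, rgc = 101-106"))

  # empty binary matrix: plain DNA matrix, one partition entry
  paths2 <- writeCombined(aln, buildBinaryMatrix(list()), tempfile())
  expect_identical(readLines(paths2[2L]), "DNA, seq = 1-100")

  # taxa mismatch is a hard error naming the difference
  st2 <- st; rownames(st2) <- c("A", "B", "C", "E")
  m2 <- new("RgcBinaryMatrix", states = st2, info = characterInfo(m))
  expect_error(writeCombined(aln, m2, tempfile()), "only in matrix: E")
})
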