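# one-row event data.frame for a given interval and member set
mk_event <- function(start, end, taxa) {
  data.frame(id = sprintf("rgc_%06d_%06d", start, end), start = start,
             end = end, length = end - start + 1L, n_taxa = length(taxa),
             gap_taxa = I(list(sort(taxa))), status = "non_ambiguous",
             ambiguity_reason = "", stringsAsFactors = FALSE)
}

pfugax_event <- function() mk_event(4L, 66L, "Polypogon_fugax")
fovina_event <- function() mk_event(4L, 81L, "Festuca_ovina_NC_019649")

test_that("the psbE-petL deletion shows its flanking dispersed repeat", {
  a4 <- psbE_petL_aln()
  hit <- findFlankingDirectRepeat(a4, pfugax_event())
  expect_identical(hit$sequence, "TCCAAAATTC")
  expect_identical(hit$length, 10L)
  expect_identical(hit$reference_taxon, "Calamagrostis_breviligulata")
  # 5' copy sits at the deleted span's edge; 3' copy in retained sequence
  expect_lte(abs(hit$copy1_cols[1L] - 4L), 5L)
  expect_gte(hit$copy2_cols[1L], 66L)
  # the repeat is recovered from several independent reference rows
  expect_true(all(c("Calamagrostis_breviligulata", "Triplachne_nitens",
                    "Gastridium_ventricosum") %in%
                  hit$per_reference$reference_taxon))
})

test_that("the psaJ-rpl33 deletion's repeat appears in every reference", {
  a5 <- psaJ_rpl33_aln()
  hit <- findFlankingDirectRepeat(a5, fovina_event())
  expect_true(startsWith(hit$sequence, "AAAAAGAAA"))
  expect_gte(hit$length, 9L)
  refs <- c("Festuca_ovina", "Festuca_altissima", "Festuca_arundinacea",
            "Festuca_pratensis")
  expect_setequal(hit$per_reference$reference_taxon, refs)
  expect_true(all(startsWith(hit$per_reference$repeat_seq, "AAAAAGAAA")))
})

test_that("featureless flanks yield no repeat and classify as recombination", {
  set.seed(101)
  # constructed 60 bp deletion with random flanks; junction scrubbed of
  # chance repeats via the simulator's rejection step
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  sim <- simulatePlastomeEvolution(
    tr, root_len = 2000L, rate = 0,
    events = list(simEvent("A", "recombination_del", 60L)), seed = 3L)
  ev <- clusterEvents(extractGapRuns(sim$alignment))
  expect_null(findFlankingDirectRepeat(sim$alignment, ev[1L, ]))
  expect_identical(classifyMechanism(sim$alignment, ev[1L, ])$mechanism,
                   "recombination_presumed")
})

test_that("windowed repeat search agrees with the brute-force oracle", {
  set.seed(55)
  cfg <- mechanismConfig()
  for (rep in 1:25) {
    # build a reference haplotype, sometimes with a planted flanking repeat
    span <- sample(50:80, 1L)
    rep_len <- sample(8:14, 1L)
    left <- rand_dna(60L); right <- rand_dna(60L)
    mid <- rand_dna(span)
    if (rep %% 2L == 0L) {   # plant: copy at span start and at 3' boundary
      R <- rand_dna(rep_len)
      substr(mid, 1L, rep_len) <- R
      substr(right, 1L, rep_len) <- R
    }
    ref <- paste0(left, mid, right)
    del <- paste0(left, strrep("-", span), right)
    aln <- RgcAlignment(c(refA = ref, delB = del))
    ev <- mk_event(61L, 60L + span, "delB")
    got <- findFlankingDirectRepeat(aln, ev, cfg)
    exp <- oracle_flank(ref, 61L, 61L + span, min_len = 8L, off = 5L)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      expect_identical(got$length, exp$length)
      expect_identical(got$sequence, exp$sequence)
    }
  }
})

test_that("reference ties break alphabetically and absent references error", {
  ref <- paste0(strrep("C", 20L), "TTAGGCATCA", rand_dna(40L),
                "TTAGGCATCA", strrep("G", 20L))
  del <- paste0(strrep("C", 20L), strrep("-", 50L), "TTAGGCATCA",
                strrep("G", 20L))
  aln <- RgcAlignment(c(zeb = ref, abe = ref, mid = del))
  ev <- mk_event(21L, 70L, "mid")
  hit <- findFlankingDirectRepeat(aln, ev)
  expect_identical(hit$reference_taxon, "abe")

  all_gone <- RgcAlignment(c(A = paste0("AC", strrep("-", 50L), "GT"),
                             B = paste0("AC", strrep("-", 50L), "GT")))
  expect_error(
    findFlankingDirectRepeat(all_gone, mk_event(3L, 52L, c("A", "B"))),
    "no reference row")
})

test_that("tandem junctions are detected with the smallest qualifying unit", {
  # canonical slippage: deleted CAGCAG adjacent to a retained CAG
  ref <- paste0(rand_dna(20L), "CAGCAGCAG", rand_dna(20L))
  del <- paste0(substr(ref, 1L, 20L), "------", substr(ref, 27L, 49L))
  aln <- RgcAlignment(c(R = ref, D = del))
  ev <- mk_event(21L, 26L, "D")
  td <- detectTandemJunction(aln, ev, mechanismConfig(min_tandem_unit = 2L))
  expect_identical(td$unit, "CAG")
  expect_identical(td$unit_len, 3L)
  expect_identical(td$copies_removed, 2L)

  # homopolymer contraction: unit length 1 rejected at min_tandem_unit = 2
  refh <- paste0(rand_dna(20L), "AAAAAA", rand_dna(20L))
  delh <- paste0(substr(refh, 1L, 20L), "--", substr(refh, 23L, 46L))
  alnh <- RgcAlignment(c(R = refh, D = delh))
  expect_null(detectTandemJunction(alnh, mk_event(21L, 22L, "D"),
                                   mechanismConfig(min_tandem_unit = 2L)))
})

test_that("mechanism precedence is ISD, then SSM, then recombination", {
  a4 <- psbE_petL_aln()
  expect_identical(classifyMechanism(a4, pfugax_event())$mechanism, "ISD")
  a5 <- psaJ_rpl33_aln()
  expect_identical(classifyMechanism(a5, fovina_event())$mechanism, "ISD")

  # a pure tandem contraction must NOT be called ISD even though its
  # junction trivially carries direct repeats (they are tandem, not
  # dispersed)
  set.seed(77)
  unit <- "TCGAG"
  ref <- paste0(rand_dna(30L), strrep(unit, 11L), rand_dna(30L))
  del <- paste0(substr(ref, 1L, 30L), strrep("-", 50L),
                substr(ref, 81L, nchar(ref)))
  aln <- RgcAlignment(c(R = ref, D = del))
  cl <- classifyMechanism(aln, mk_event(31L, 80L, "D"))
  expect_identical(cl$mechanism, "SSM")
  expect_identical(cl$evidence$unit, unit)
})

test_that("mechanism table fills evidence only for classified events", {
  a4 <- psbE_petL_aln()
  ev <- flagAmbiguous(clusterEvents(extractGapRuns(a4)), a4,
                      "Amelichloa_brachychaeta")
  out <- classifyMechanisms(a4, ev)
  expect_identical(out$mechanism[out$status == "ambiguous"][1L],
                   "undetermined")
  isd <- out[out$length == 63L, ]
  expect_identical(isd$mechanism, "ISD")
  expect_identical(isd$repeat_seq, "TCCAAAATTC")
})
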