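# rgcscan

Detection, mechanistic classification and phylogenetic mapping of **rare
genomic changes (RGC)** — large (≥ 50 bp), infrequent indels — in multiple
sequence alignments of plastid genomes.

Plastome intergenic spacers accumulate two classes of structural mutation.
Small (< 50 bp) microstructural changes arise constantly by slipped-strand
mispairing and saturate across divergent taxa. Large indels are rare,
mostly recombination- or intrastrand-deletion-derived, and therefore make
excellent low-homoplasy phylogenetic characters: a shared 100 bp deletion
with identical boundaries is strong evidence of common ancestry. `rgcscan`
turns an aligned set of plastomes plus an outgroup designation into such
characters and maps them onto a tree as clade-defining taxonomic markers.

The pipeline, for an alignment `A` with outgroup set `O`:

1. **Gap runs** — every maximal run of `-` per taxon; terminal runs are
   missing data, not events.
2. **Events** — runs with identical column boundaries cluster into one
   candidate event; events are culled as *ambiguous* when another event
   crosses their boundaries, when the non-member gap density inside the
   interval exceeds 50 %, or when an outgroup is only partially gapped
   there.
3. **Size filter** — non-ambiguous events ≥ 50 bp are RGC; shorter ones
   are reported as microstructural changes.
4. **Mechanism** — ISD if a reference row (a taxon carrying the span)
   shows an exact direct *dispersed* repeat ≥ 8 bp with one copy at each
   boundary of the deleted span (one copy survives the deletion); else SSM
   if the span is an integer number of tandem units adjacent to a retained
   copy; else presumed recombination.
5. **Polarization** — the outgroup condition over the span is the
   ancestral state 0; the full opposite condition is the derived state 1;
   partial spans are `?`. Characters export as restriction-datatype NEXUS
   (`DATATYPE=RESTRICTION MISSING=? SYMBOLS="01"`) and as a combined
   relaxed-PHYLIP + RAxML partition file for external tree software.
6. **Markers** — each binary character is mapped by small parsimony
   (exact unit-cost DP, `?` = {0,1}) and classified: one change on an
   internal edge = **synapomorphy** (clade marker), one terminal change =
   **autapomorphy**, ≥ 2 changes = **homoplasy**.

A plastome-evolution simulator (`simulatePlastomeEvolution()`) plants ISD
/ SSM / recombination events of known location and mechanism along a tree
under JC69 substitutions and emits the *true* alignment plus a truth
table, so the whole pipeline is verifiable against ground truth. Plastome
descriptor utilities (`summarizePlastome()`: length, inverted-repeat
detection by seed-and-extend, LSC/SSC partition, %AT) round out the
toolkit.

## Worked example

Two small alignment windows ship with the package. The first covers the
psbE–petL intergenic spacer across 17 Poeae grasses and contains a 63 bp
deletion unique to *Polypogon fugax*:

```r
library(rgcscan)

aln <- readAlignment(rgcExample("psbE_petL"))
ev  <- flagAmbiguous(clusterEvents(extractGapRuns(aln)), aln,
                     outgroups = "Amelichloa_brachychaeta")
rgc <- filterRgc(ev)$rgc
rgc[, c("id", "start", "end", "length", "status")]
#>                  id start end length        status
#> 1 rgc_000004_000066     4  66     63 non_ambiguous

cl <- classifyMechanism(aln, rgc[1, ])
cl$mechanism
#> [1] "ISD"
cl$evidence$sequence
#> [1] "TCCAAAATTC"
cl$evidence$reference_taxon
#> [1] "Calamagrostis_breviligulata"
```

Of the 13 candidate events in the window, exactly one survives ambiguity
culling at RGC size: a 63-column deletion spanning columns 4–66, carried
only by *P. fugax*. Its mechanism is intrastrand deletion: reference rows
show the 10 bp direct repeat `TCCAAAATTC` once at the 5′ edge of the
deleted span and once in retained sequence just past the 3′ boundary —
the deleted lineage keeps a single copy. Polarized against the outgroup
and mapped on a tree, the character is an autapomorphy:

```r
pol <- polarizeEvent(rgc[1, ], aln, "Amelichloa_brachychaeta")
bm  <- buildBinaryMatrix(list(pol))
tr  <- ape::read.tree(text = paste0("(", paste(taxa(aln), collapse = ","), ");"))
markerReport(tr, bm, outgroup = "Amelichloa_brachychaeta")$markers
#>            event_id marker_class min_changes code           clade
#> 1 rgc_000004_000066 autapomorphy           1 <NA> Polypogon_fugax
```

The second window (`rgcExample("psaJ_rpl33")`, five *Festuca* plastomes)
contains the corresponding 78 bp ISD in the previously published
*F. ovina* accession NC_019649, with flanking repeat `AAAAAGAAA` visible
in all four reference rows.

A command-line front-end wrapping the same functions is installed at
`system.file("scripts", "rgcscan", package = "rgcscan")`, with
subcommands `scan`, `detect`, `mechanism`, `matrix`, `map`,
`plastome-stats` and `simulate`.

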