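---
title: "Detecting and mapping rare genomic changes in plastome alignments"
author: "rgcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and mapping rare genomic changes in plastome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcscan)
```

## The problem

Plastid genomes (plastomes) are conserved enough that their intergenic
spacers accumulate two distinguishable classes of structural mutation.
Small indels (< 50 bp), mostly from slipped-strand mispairing (SSM) in
tandem repeats, occur frequently, saturate quickly, and are hard to score
as homologous characters across divergent taxa. Large indels (>= 50 bp) —
*rare genomic changes* (RGC) — arise rarely, typically through
nonreciprocal recombination or intrastrand deletion, and because of their
size and rarity they make attractive low-homoplasy phylogenetic
characters: a shared large deletion is far more likely to reflect common
ancestry than parallel mutation.

`rgcscan` mechanizes the workflow that turns a plastome multiple sequence
alignment into such characters:

1. extract per-taxon gap runs from the alignment;
2. cluster identical runs into candidate indel events and cull events
   whose homology or polarity cannot be read from the alignment;
3. apply the >= 50 bp size filter separating RGC from microstructural
   changes;
4. classify each RGC's mutational mechanism — intrastrand deletion (ISD),
   SSM, or presumed recombination;
5. polarize each event against outgroup taxa into a binary 0/1/?
   character and export restriction-datatype NEXUS and combined
   PHYLIP+partition matrices for external tree software;
6. map characters onto a phylogeny by small parsimony and classify each
   as a clade-defining synapomorphy, an autapomorphy, or homoplasy.

A sequence-evolution simulator with *planted* events of known mechanism
provides ground truth, so every stage is testable at desk scale.

## Conventions

All intervals are 1-based and closed, in alignment-column coordinates (or
ungapped-sequence coordinates where stated) — the convention of the R
ecosystem this package lives in (Biostrings, IRanges, ape). The only gap
character is `-`; `.` and `?` in input are normalized to `-` and `N` with
a warning. Rows are uppercased on read.

## Event detection and the ambiguity rules

A *gap run* is a maximal run of `-` in one row. Runs touching the first
or last column are flagged *terminal* and excluded by default
(`rgcConfig(include_terminal_runs = )`): a terminal run is
indistinguishable from missing data, and in windowed alignments it would
create artifactual edge events. Runs with *identical* column boundaries
are clustered into one event whose member set is the union of their taxa
— the strictest defensible mechanization of "the same event in several
taxa" (`boundary_slop` relaxes it).

An event is culled as *ambiguous* when the alignment does not support a
clean ancestral/derived reading:

* **Crossing overlap.** Another event's interval overlaps it partially,
  with neither interval nested in the other. Crossing boundaries mean the
  aligner placed conflicting homology assignments in the same region.
  Nested events are *not* ambiguous: a small indel inside the span of a
  larger deletion in other taxa is ordinary and is scored as its own
  character, as in standard simple indel coding.
* **Gap-dense region.** The density of gap characters among non-member
  cells inside the interval exceeds `ambiguous_gap_density` (default
  0.5). A region riddled with overlapping independent indels supports no
  mechanism or homology inference. Density, not a per-taxon "any gap"
  test, is the right formalization: essentially every taxon carries some
  1–5 bp microindel inside any 60+ bp window of a spacer alignment, and
  a per-taxon test would cull every large event including the textbook
  ones.
* **Unreadable outgroup.** A designated outgroup shows a *partial* gap
  over the interval, so the ancestral condition cannot be read.

### Span states and the nested-gap tolerance

Several stages need "does taxon X carry this span?". The answer is
three-valued: **absent** when the row is gap across the entire interval,
**present** when at most `nested_gap_tol` (default 0.25) of the interval
is gapped, **partial** otherwise. The tolerance matters: in real spacer
alignments the taxa that *carry* a span still harbour small nested
microindels within it (in the bundled psbE–petL window the outgroup has
7 gap columns inside the 63-column deletion), and without the tolerance
no taxon would ever count as a clean reference or a clean ancestral
state. 0.25 is low enough that a half-deleted span still reads as
partial, which becomes `?` (missing), never `0`.

## Mechanism classification

The three mechanism calls follow fixed precedence ISD > SSM > presumed
recombination; evidence for the first two is sought in *reference* rows
(taxa whose span state is present), in their **ungapped** coordinates —
repeats are properties of the sequence, not of the aligner's gap
placement.

**ISD.** An intrastrand deletion leaves a signature in relatives lacking
the deletion: a direct dispersed repeat with one copy at the 5' edge of
the deleted span and one just downstream of the 3' boundary (or the
mirror arrangement), of which a single copy survives in the deleted
lineage. `findFlankingDirectRepeat()` maps the event boundaries into each
reference's ungapped coordinates and takes the longest exact repeat with
copy starts (or ends) within `max_boundary_offset` (default 5 bp, which
absorbs aligner wobble such as a junction copy split by a small alignment
gap) of the two boundaries. Defaults: `min_repeat_len = 8` — the
documented ISD evidence repeats in grasses are 9–10 bp, and a chance
8-mer at a fixed junction offset has probability about 6e-5 per
comparison; matches are exact (`max_mismatches = 0`). The longest hit
across references wins; ties break alphabetically so results are
deterministic. One exclusion is essential: the two copies must not be
part of a single periodic run. A tandem-array contraction trivially
offers "repeats flanking the deletion" at a one-unit offset, but those
copies are tandem, not dispersed, and they diagnose slippage; without the
exclusion every SSM event would be mislabelled ISD.

**SSM.** `detectTandemJunction()` fires when the deleted span equals an
integer number of copies of a unit (>= `min_tandem_unit`, default 2)
tandemly adjacent to the span in a reference. The smallest qualifying
unit is reported, and the unit must be primitive — a 2-base deletion in a
homopolymer is unit "A", which the minimum is meant to exclude, not unit
"AA".

**Presumed recombination.** Everything else. Large indels that leave no
junction sequence evidence are attributed to nonreciprocal recombination;
this is a default of ignorance, reflected in the name.

## Polarization and export

The ancestral condition of a character is the outgroup condition over the
event span: all outgroups absent → ancestral absence (the event is an
insertion); all present → ancestral presence (a deletion). Conflicting
or partial outgroups drop the character with a warning — guessing a
polarity would manufacture signal. Taxa matching the ancestral condition
score 0, the full opposite condition 1, partial spans `?`; uncertain
homology is treated as missing data, not as ancestral. Characters with no
taxon in state 1 are dropped from exports (logged): they are detectable
events whose derived state is absent from the sample. By construction an
outgroup can never score 1.

Exports: a NEXUS DATA block with `DATATYPE=RESTRICTION MISSING=?
SYMBOLS="01"` (the binary partition format Bayesian samplers expect), a
`CHARLABELS` line carrying event ids so matrices round-trip, and a
combined relaxed-PHYLIP matrix (nucleotide columns, then binary columns)
with a RAxML-style partition file. Tree inference itself is out of scope:
the package emits the matrices those programs consume.

## Parsimony mapping

`fitchCount()` computes the minimum number of 0/1 changes by unit-cost
dynamic programming over the (rooted) tree — on binary trees this equals
the classical two-pass Fitch count, and on polytomies the DP still
returns the exact minimum, where the naive set-intersection
generalization can undercount. `?` is the full state set. The count is
root-independent; classification roots on the outgroup so the ancestral
state sits at the root. A character is a *synapomorphy* when one change
suffices and it sits on an internal edge (the derived state defines that
clade), an *autapomorphy* when the single change is terminal, *homoplasy*
when two or more changes are forced. Supporting edges come from one
minimal reconstruction whose ties resolve toward the parental state:
under the accelerated (ACCTRAN) alternative, missing-data leaves adjacent
to a derived tip are swept into the derived clade, turning clean
autapomorphies into spurious two-taxon synapomorphies. Tie policy affects
edge placement only, never the change count. `markerReport()` groups
synapomorphies by clade and assigns letter–number codes (letter = clade
series in order of appearance, number = index within the clade).

## The simulator

`simulatePlastomeEvolution()` evolves a root sequence (random, AT-biased
to a target — 62 %AT by default, the plastome norm) down a tree under
JC69 with the full transition probability (multiple hits included), and
plants events on chosen branches:

* **ISD**: a repeat of `repeat_len` is written at both ends of the chosen
  span *in the parent node* (so all of the parent's descendants are
  potential references), then the child lineage deletes from the first
  copy's start through the second copy's start, leaving one copy — the
  textbook ISD footprint.
* **SSM**: a tandem array of `copy_delta + 1` primitive units is seeded
  in the parent; the child removes `copy_delta` units, leaving one
  adjacent copy.
* **recombination_del / recombination_ins / micro_indel**: plain span
  edits. Deletion junctions are re-randomized until no chance >= 8 bp
  flanking repeat exists, so a planted recombination can never masquerade
  as ISD.

Because the simulator tracks column identities through every edit, it
emits the *true* alignment — detection is tested independently of any
aligner — plus the unaligned leaf FASTA and a truth table (branch, kind,
true columns, planted repeat). Events are placed in disjoint seeded
windows with 50 bp margins, keeping the truth unambiguous; overlapping
requests fail loudly. Fixed seeds give byte-identical output.

What the simulator does *not* emulate: alignment error (the true
alignment is exact), rate heterogeneity and base-composition drift (JC69
only — richer models matter for tree inference, which is out of scope,
not for indel coding), stochastic indel processes (events are planted,
not drawn), inversions, and IR boundary shifts. Passing the planted-truth
suites therefore demonstrates correctness of the machinery on clean
homology, not robustness to aligner artefacts; on real alignments the
ambiguity culling is the guard, and its thresholds are configurable.

## Plastome summaries

`summarizePlastome()` reports the descriptors customary in plastome
papers: total length, inverted-repeat length, LSC/SSC lengths, %AT.
The IR pair is found by 21-mer seeding of the forward strand against the
sequence's reverse complement with exact bidirectional extension —
plastid IRs are near-identical, so exact matching is both adequate and
verifiable against an exhaustive quadratic oracle. The two inter-IR
segments on the circle become LSC (longer) and SSC (shorter); a tie
takes the segment containing coordinate 1, with a warning. Junction
conventions differ between annotation pipelines by a few bp, so
published IR/LSC/SSC lengths should be compared with that tolerance in
mind; total length and %AT are convention-free. %AT excludes Ns and
ambiguity codes from numerator and denominator and rounds half-up to one
decimal, matching the printed precision of published tables.

## Worked example

```{r example}
aln <- readAlignment(rgcExample("psbE_petL"))
ev  <- flagAmbiguous(clusterEvents(extractGapRuns(aln)), aln,
                     outgroups = "Amelichloa_brachychaeta")
rgc <- filterRgc(ev)$rgc
rgc[, c("id", "start", "end", "length", "status")]
classifyMechanism(aln, rgc[1, ])$evidence$sequence
```

The bundled 17-taxon psbE–petL window yields a single 63 bp
non-ambiguous RGC, unique to *Polypogon fugax*, classified ISD with
flanking repeat `TCCAAAATTC`; polarized against the outgroup it maps as
an autapomorphy on any tree containing *P. fugax*. The 5-taxon
psaJ–rpl33 window gives the corresponding 78 bp ISD in the NC_019649
accession of *Festuca ovina* with repeat `AAAAAGAAA` visible in all four
reference rows.

## Problem sizes and numerical choices

The test and acceptance suites run the full pipeline on 20 simulated
replicates of 30 kb, 6 taxa, 5 planted events each; parsimony is checked
against exhaustive enumeration on trees up to 12 leaves; the repeat
finders against quadratic brute force on windows up to ~180 bp and
sequences up to ~800 bp; IR detection additionally on multi-kb planted
quadripartite genomes. These sizes exercise every code path at full
fidelity while keeping a complete run in tens of seconds; nothing in the
implementation is size-limited below real plastome scale (the scan of a
140 kb alignment is dominated by the one-off gap-run extraction, which
is linear).

Known limitations: homology is boundary-exact by default, so aligner
wobble across *datasets* (as opposed to within a window) fragments
shared events unless `boundary_slop` is raised; mechanism classification
is evidence-based and one-sided (absence of a repeat cannot prove
recombination, hence "presumed"); insertions lacking any reference
context get no mechanism call; and ancient ISD events whose repeats have
since decayed are indistinguishable from recombination, which is why the
observed ISD rate in deep-time comparisons should be read as a floor.
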