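Package: rgcscan
Title: Rare Genomic Changes in Plastome Alignments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection, mechanistic classification and phylogenetic mapping
    of rare genomic changes (RGC) -- large, infrequent indels -- in multiple
    sequence alignments of plastid genomes. Gap runs are extracted per taxon,
    clustered into candidate indel events, culled for ambiguity and filtered
    by a size threshold; surviving events are classified as intrastrand
    deletions (direct dispersed repeats exactly flanking the deleted span),
    slipped-strand mispairing (tandem-repeat contraction/expansion at the
    junction) or presumed recombination; events are polarized against
    outgroup taxa into a binary 0/1/? character matrix exportable as
    restriction-datatype NEXUS or combined PHYLIP+partition matrices, and
    mapped onto a phylogeny by small parsimony to classify each character as
    a clade-defining synapomorphy, an autapomorphy or homoplasy. Also
    included: quadripartite plastome summaries (inverted-repeat detection,
    LSC/SSC partition, AT content) and a plastome-evolution simulator that
    plants indel events of known mechanism along a tree and emits the true
    alignment plus a truth table, so the whole pipeline is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Alignment, Phylogenetics, Genetics, SequenceMatching
RoxygenNote: 7.3.3
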