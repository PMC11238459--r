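Package: spliceforest
Title: Simulation of Alternative Splicing and Transcript Phylogenies Along Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of a eukaryotic gene's exon-intron
    structure, its nucleotide sequences, and its set of alternative
    transcripts along the branches of a guide gene tree. Exon-intron
    structures evolve by exon loss, gain and duplication under Dollo
    parsimony; exon sequences evolve at the codon level and intron
    sequences at the nucleotide level; transcript sets evolve through
    budgeted alternative-splicing events (alternative 5'/3' splice sites,
    exon skipping, mutually exclusive exons, intron retention) plus
    transcript gain and loss. The simulator emits the transcript
    phylogenies as a forest, true multiple sequence alignments, ortholog
    groups, exon coordinates and a complete event log, providing ground
    truth for benchmarking spliced alignment, conserved-transcript
    identification and transcript phylogeny reconstruction methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    Biostrings,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
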