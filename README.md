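# spliceforest

Splicing-aware simulation of gene-family evolution and transcript
phylogenies, for benchmarking spliced RNA sequence analysis.

## The problem

Methods for spliced alignment, conserved-transcript identification and
transcript-phylogeny reconstruction need gold-standard data, and real
annotation cannot supply the true evolutionary history of isoforms.
`spliceforest` simulates that history. Given a rooted **guide gene tree**
with branch lengths, it evolves, from the root to the leaves:

* the gene's **exon–intron structure** (exon loss, gain, duplication,
  under Dollo parsimony — a lost exon is never regained);
* the **nucleotide sequences** (codon-level substitutions/indels for
  exons, nucleotide-level for introns, all replayable from logs);
* the gene's **set of alternative transcripts**, through the five
  alternative-splicing event types — alternative 5'/3' splice-site choice
  (a5/a3), exon skipping (es), mutually exclusive exons (me), intron
  retention (ir) — plus transcript gain (rs) and loss (tl).

Because every transcript at a node either descends from a parent-node
transcript or is a recorded gain, the simulation yields a **transcript
forest**: a directed forest over all transcripts whose edges are labeled
`conserved` or by the AS event that produced the child. The forest, the
true multiple sequence alignment, splicing-ortholog groups, exon
coordinates and the full event log are all emitted as ground truth.

## The model in brief

The number of transcripts undergoing an event of type *x* at one
evolutionary stage on a branch of length *c_s_r* with *n* source
transcripts is the **event budget**

    B_x = ceil( k_tc * c_s_r * n * tc_x )

where `k_tc` is a user constant and `tc_x` the event type's relative
proportion. At the root, where evolution starts and no losses occur, the
proportions apply directly: `ceil(n * tc_x)`. The root's initial
transcript count is drawn from Normal(1.45, 1.08) — the observed mean and
sd of transcripts per gene in eukaryotes — and isoforms are drawn
uniformly from the `2^m − 1` exon subsets of an `m`-exon gene. One stage
is run per AS type (order es, me, a5, a3, ir), each budget recomputed from
the current source-set size, so transcripts can accumulate several events.
On a branch, transcripts containing an exon lost on that branch are lost
structurally, `tl` removes conserved survivors, `rs` gains fresh isoforms
(new forest roots), and the AS stages follow.

Two transcripts are **splicing orthologs** when they belong to distinct
extant genes and the forest path connecting them contains only conserved
edges; ortholog groups are maximal sets of pairwise orthologs. The
**conservation ratio** (clusters / transcripts; 1 = no conservation)
summarizes how much transcript conservation a dataset carries.

See `vignettes/transcript-evolution-model.Rmd` for the full model,
parameter table and design rationale.

## Worked example

```r
library(spliceforest)
cfg <- spliceSimConfig(seed = 1001)   # k_tc = 5, tc_rs = 1, tc_es = 0.25, ...
res <- simulateSpliceEvolution("((A:0.3,B:0.4):0.2,C:0.5);", cfg)
res
#> SpliceSimResult
#>   guide tree: 3 leaves; 5 gene nodes simulated
#>   transcripts: 526 across all nodes; forest: 442 edges, 15 losses
#>   events logged: 541

stageTable(res)[1:6, ]
#>   node branch stage type n_source budget n_applied
#> 1   n1   <NA>     0   rs       NA      1         1
#> 2   n1   <NA>     1   es        1      1         1
#> 3   n1   <NA>     2   me        2      1         1
#> 4   n1   <NA>     3   a5        3      1         1
#> 5   n1   <NA>     4   a3        4      1         1
#> 6   n1   <NA>     5   ir        5      1         1
```

The root (`n1`) selected one transcript, then each AS stage applied its
budget `ceil(n * tc_x)` to the growing source set (1 → 2 → 3 → 4 → 5 → 6
transcripts). Downstream:

```r
orthologGroups(transcriptForest(res), leafLabels(res@guideTree))[1:2]
#> [[1]]
#> [1] "A#140" "B#223"
#> [[2]]
#> [1] "A#141" "B#224"

cl <- clusterByPhylogeny(transcriptForest(res), leafLabels(res@guideTree))
length(cl) / length(unlist(cl))
#> [1] 0.959596
```

16 ortholog groups link transcripts of the extant genes (A and B are the
closest pair), and the phylogeny-based conservation ratio of the 495 leaf
transcripts is 0.96. `writeSimulationOutputs(res, "out")` writes the
FASTA sequences, true alignments, forest (Newick/NHX), coordinate tables,
event log and ortholog groups; file contents are documented in
`?writeSimulationOutputs`.

## Command line

```sh
Rscript exec/spliceforest --tree guide.nwk --out sim_out --seed 7 \
    --k-tc 5 --tc-es 0.25
Rscript exec/spliceforest --tree-string '((A:0.2,B:0.3):0.2,C:0.4);' \
    --mode conservation-experiment --iterations 10 --k-tc-values 5,10 \
    --out exp_out
```

Flags override a `--config` YAML file (keys are the `spliceSimConfig()`
argument names; nested constants as `structure.exonCountMean: 7`).

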