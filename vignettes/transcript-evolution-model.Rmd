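---
title: "Simulating alternative splicing and transcript phylogenies along a gene tree"
author: "spliceforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating alternative splicing and transcript phylogenies along a gene tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceforest)
```

## The problem

Benchmarking methods that work on spliced RNA sequences — spliced aligners,
conserved-transcript callers, transcript-phylogeny reconstruction — needs
ground truth that real annotation cannot provide. `spliceforest` produces
that ground truth: given a rooted guide gene tree with branch lengths, it
simulates a gene family's exon–intron structures, nucleotide sequences and,
crucially, the evolution of each gene's *set of alternative transcripts*,
emitting the transcript phylogenies (a forest), the true multiple sequence
alignments, splicing-ortholog groups and a complete event log.

The distinguishing feature is that transcript sets at different tree nodes
are evolutionarily connected: each transcript at a node either descends
from a parent-node transcript (conserved, or modified by a recorded
alternative-splicing event) or is a fresh gain. Without that connection a
simulator cannot be used to evaluate transcript-phylogeny inference at all.

## The model

### Event budgets

All evolutionary change is driven by *budgets*. For a transcript-set event
of type $x$ with relative proportion $tc_x$, acting on $n$ source
transcripts on a branch of length $c_{s,r}$ (expected substitutions per
site), the number of events is

$$ B_x \;=\; \left\lceil\, k_{tc} \cdot c_{s,r} \cdot n \cdot tc_x \,\right\rceil $$

with a user constant $k_{tc}$. At the root the proportions apply directly,
$B_x = \lceil n \cdot tc_x \rceil$, because the root is the starting point
of the homologous family and has no branch above it. The ceiling means any
positive expectation produces at least one event; a numerical guard
(`ceiling(x - 1e-9)`) prevents mathematically integral products from
rounding up one unit too many. Exon-intron structure events (loss, gain,
duplication) use the same form with their own constant `kSt` and
proportions, with $n$ replaced by the exon count $m$.

### Transcript-set evolution

Seven event types act on a gene's transcript set: the five alternative
splicing (AS) types — alternative 5' and 3' splice-site choice (`a5`,
`a3`), exon skipping (`es`), mutually exclusive exons (`me`), intron
retention (`ir`) — plus transcript gain by random selection from the
isoform pool (`rs`) and transcript loss (`tl`). The isoform pool of an
$m$-exon structure is the $2^m - 1$ non-empty exon subsets.

**Root.** If $tc_{rs} = 0$, a single transcript containing every exon is
selected. Otherwise the number of initial transcripts is drawn from
$\mathcal{N}(1.45,\,1.08)$ — the mean and standard deviation of
transcripts per gene across eukaryotes in Ensembl Compara — rounded to the
nearest integer and clamped to a minimum of 1 (the distribution is about
*counts*; a draw of zero or less would leave nothing to evolve). Isoforms
are drawn uniformly without replacement; a draw exceeding the pool is
clamped to it.

**Evolutionary stages.** The remaining transcripts arise by applying AS
events in *stages*: a stage converts a source set into a sink set, each
sink linked to at most one source. The stopping rule for stages is a
genuinely open design point: budgets use ceilings, so any rule of the form
"iterate until budgets are exhausted" never terminates and any fixed large
stage count grows the set geometrically. We therefore run **one stage per
AS type in the fixed order es, me, a5, a3, ir**, recomputing each stage's
budget from the *current* source-set size. This choice uniquely reproduces
the worked example counts of the model: starting from $n = 2$ root
transcripts with $(tc_{es}, tc_{me}, tc_{a5}, tc_{a3}, tc_{ir}) = (0.2,
0.1, 0.1, 0.1, 0.1)$ the stages add $1+1+1+1+1$ transcripts through source
sets of sizes $2,3,4,5,6$, ending with exactly 7; and on a branch with one
conserved transcript and two gains the ir stage sees exactly $n = 7$
sources. Because sinks of one stage are sources of later stages, a
transcript can accumulate several AS events (an es-derived transcript can
subsequently undergo a3, and so on).

**Branches.** On a branch, in order: (1) *structural losses* — every
parent transcript containing an exon lost on the branch is lost;
(2) *regulated losses* — $B_{tl}$ of the conserved survivors, chosen
uniformly; (3) *gains* — $B_{rs}$ isoforms drawn from the child pool,
excluding isoform signatures already present (a gain that exactly
reproduces an existing transcript would be indistinguishable from
conservation), added as new forest roots; (4) the five AS stages as at the
root but with branch budgets. Conserved transcripts keep their parent
identity while the branch evolves (they can serve as AS sources) and are
finally copied into child-node transcripts via `conserved` edges. No
losses occur at the root.

When a drawn (transcript, type) pair is inapplicable — es on a single-exon
transcript, me when no structure exon is absent, ir with no unretained
junction between consecutive exons — the transcript is redrawn up to $n$
times, after which the remaining budget is skipped and recorded as a
shortfall rather than silently faked.

### AS event semantics

The model names the five AS types without fixing their mechanics; the
package's choices are:

* **es** removes one uniformly chosen exon; the result must stay
  non-empty.
* **me** swaps one present exon for one absent structure exon, inserted in
  structure order. This is the minimal reading of "mutually exclusive":
  the sink contains an exon the source lacks and vice versa.
* **a5 / a3** shift one exon's 5'/3' boundary by a signed nonzero offset
  $3k$ with $k$ truncated-geometric and the sign uniform. Negative offsets
  trim the exon (clamped so the core keeps at least one codon); positive
  offsets extend into the flanking intron, capped at
  $\lfloor (L_i - 6)/2 \rfloor$ rounded down to a multiple of 3, so the
  two sides of one intron can never claim overlapping nucleotides. The
  multiple-of-3 constraint keeps every transcript in frame.
* **ir** retains one intron lying between two structure-consecutive exons
  of the transcript; at assembly time the retained intron is trimmed at
  its 3' end to a multiple of 3, and extensions into a retained intron are
  suppressed (retention supersedes them).

Offsets are inherited verbatim along conserved edges while the underlying
sequences keep evolving; the CDS assembler therefore re-clamps effective
offsets against the *current* exon and intron lengths. Transcripts are not
required to begin with ATG or end with a stop codon — a simulated CDS may
lack either — but frame-0 internal stop codons are excluded from exon
sequences as a modeling choice (substitutions that would create one are
resampled), keeping every simulated CDS interpretable as coding sequence.

### Structure and sequence evolution

The ancestral structure draws its exon count from
$\mathcal{N}(\texttt{exonCountMean}, \texttt{exonCountSd})$ (clamped to
$\ge 1$), exon lengths in codons and intron lengths in nucleotides from
normals with documented defaults (6 exons; 57 codons $\approx$ 171 nt
exons; 150 nt introns — typical orders of magnitude for compact eukaryotic
genes). Exon and intron sequences come from order-2 Markov chains; the
bundled defaults are a mildly GC-shifted chain for exons and an AT-rich
chain for introns, and users can supply their own estimated parameters as
a TSV (`readMarkovParams()`). Introns carry canonical `GT`...`AG` ends.

Structures evolve by exon loss (flanking introns merge; a loss that would
empty the gene is skipped and logged), exon gain (a freshly generated exon
and intron inserted at a uniform slot, including the gene's extremities)
and exon duplication (a verbatim copy beside its template that diverges
afterwards). Lost exon identifiers are never reused, so Dollo parsimony —
an exon, once lost on a lineage, is never regained — holds by
construction.

Sequences evolve with substitution counts that are Poisson in sequence
length times branch length, an HKY-style replacement kernel
(transition/transversion weight `kappa`, default 2, equal base
frequencies — composition is the Markov chains' job), and
truncated-geometric indels: whole codons for exons (frame preserved),
arbitrary lengths for intron interiors. These mechanics fill a gap the
model leaves open ("indel-Seq-Gen-like"); they are documented package
defaults, not claims of equivalence to any other implementation. Every
mutation is logged, and replaying a log on the ancestral sequence
reproduces the descendant exactly — this replay property is what makes the
true alignment possible.

### True alignment

Every nucleotide position that ever exists acquires a global column;
insertions allocate fresh columns spliced into the column order, deletions
merely remove positions from a lineage's map, duplicated exons get fresh
columns (two copies in one gene cannot share columns), and merged introns
concatenate their parents' maps. A row — a gene's genomic sequence or a
transcript's CDS — places its characters in its columns and gaps the rest,
so homologous exon positions are aligned across all rows by construction
and ungapping any row returns its sequence exactly. Column provenance
(root, insertion, gain, duplication) is reported alongside.

### Orthology and the conservation ratio

Two transcripts are splicing orthologs when they belong to distinct
*extant* genes and the forest path between them contains only conserved
edges. The restriction to extant genes follows from the model's worked
example, in which an ancestral transcript conserved into two leaf
transcripts yields exactly one ortholog group — the two leaf transcripts,
not the triple including their ancestor. Groups are the leaf-gene
transcripts of each conserved-edge component (pairwise orthology is then
automatic because each transcript has at most one conserved descendant per
branch, so a component holds at most one transcript per gene).

The conservation ratio is the number of transcript clusters divided by the
number of transcripts: 1 means no conservation. `conservationExperiment()`
contrasts history-aware clustering (conserved components of the forest)
with composition-based clustering of *history-free* sets (each leaf's
transcripts re-generated independently from its own structure by the root
procedure, then clustered by identical homologous-exon composition —
including offsets and retained introns, the strictest reading of "same
composition"). History-aware simulation conserves more: its mean ratio is
lower.

## Parameters that matter

| parameter | meaning | default |
|---|---|---|
| `kTc` | constant scaling transcript-event budgets on branches | 5 |
| `tcRs, tcEs, tcMe, tcA5, tcA3, tcIr, tcTl` | relative event proportions | 1, 0.25, 0.15, 0.15, 0.15, 0.15, 0.05 |
| `structure$kSt, loss, gain, dup` | structure-event constant and proportions | 1, 0.1, 0.1, 0.05 |
| `structure$exonCountMean/Sd` | root exon count (normal, clamped $\ge 1$) | 6, 2 |
| `structure$exonLenMeanCodons/SdCodons` | root exon length in codons ($\ge 3$) | 57, 15 |
| `structure$intronLenMean/Sd` | root intron length in nt ($\ge 12$) | 150, 50 |
| `sequence$exSubRate, exIndelRate` | exon substitution / indel Poisson rates per nt per unit branch | 1, 0.02 |
| `sequence$inSubRate, inIndelRate` | intron counterparts | 1, 0.05 |
| `sequence$kappa` | transition/transversion weight | 2 |
| `seed` | RNG seed; per-node streams derive from (seed, node label) | 1 |

The transcript-event defaults are the tool's standard settings; the
structure and sequence defaults are package choices stated once here and
used consistently.

## A small run

```{r example, eval = FALSE}
cfg <- spliceSimConfig(seed = 42)
res <- simulateSpliceEvolution("((A:0.3,B:0.4):0.2,C:0.5);", cfg)
res
stageTable(res)[1:6, ]            # per-stage sources, budgets, applied events
orthologGroups(transcriptForest(res), leafLabels(res@guideTree))
writeSimulationOutputs(res, "sim_out")
```

## Numerical and degenerate-input choices

* Budgets use `ceiling(x - 1e-9)`; all budget arguments must be
  non-negative and violations are domain errors, not silent clamps.
* Exon generation redraws stop codons (up to 50 times, then forces the
  third base to the best non-stop alternative) — relevant only for
  near-degenerate user-supplied chains.
* A gene keeps at least one exon; a transcript keeps at least one exon and
  at least one codon per exon core.
* Empty transcript sets can arise on long branches (everything lost, gain
  budget zero because $n = 0$); downstream budgets are then zero and the
  lineage stays empty. The experiment report records such runs with
  `ratio = NA` rather than dropping them.
* Deterministic replay: the same seed gives byte-identical outputs; child
  nodes draw from RNG streams derived from (seed, node label), so a
  node's result does not depend on sibling traversal order.

## What the simulator does and does not emulate

Generated data reproduce the *structural* statistics the model defines —
event counts tied to branch lengths, Dollo-consistent structures, in-frame
transcripts, evolutionarily linked transcript sets. They do not carry
functional signal: codons are generated independently (no selection, no
amino-acid model), splice-site strength does not modulate a5/a3 choice,
and introns undergo no gain, loss or sliding. Start/stop codons appear
only by chance. Passing tests therefore certify the bookkeeping and the
stated distributions, not biological realism of any particular sequence.

Test and vignette examples run at reduced gene sizes (about 4 exons of 8
codons with 30 nt introns), moderate event budgets (`kTc` of 1–2) and
trees of 3–8 leaves with branch lengths up to 0.3; these are the package's
chosen property-testing conditions — transcript counts grow roughly
geometrically in `kTc` times branch length per branch, and the invariants
checked are size-independent. The conservation-ratio comparison keeps the
full default settings (`kTc = 5`).

## Known limitations

* The stage-order rule (es, me, a5, a3, ir) is one consistent reading of
  the model's stage arithmetic; other orders would reproduce the same
  totals only partially.
* `me` does not constrain the swapped-in exon to be adjacent to the
  removed one, which real mutually-exclusive splicing usually is.
* Orthology under guide trees containing gene duplications is resolved by
  splitting components into same-gene-free subsets; with duplication-free
  trees (the usual benchmark case) this code path is inert.
* The conservation experiment's "history-free" arm emulates
  composition-based clustering on independently generated sets; it is a
  baseline, not a reimplementation of any other tool.
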