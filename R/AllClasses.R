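#' @import methods
NULL

#' Guide gene tree
#'
#' A rooted gene tree with branch lengths that scales all mutation-event
#' budgets. Wraps an [ape::phylo] object after validation; every node
#' (including internal nodes) carries a unique label so that every simulated
#' gene is addressable.
#'
#' @slot tree a rooted `phylo` object with `edge.length` on every edge.
#' @slot nhx character vector of NHX comment strings found in the input
#'   (retained verbatim, unused by the simulation).
#' @exportClass GuideTree
setClass("GuideTree", representation(tree = "ANY", nhx = "character"))

setValidity("GuideTree", function(object) {
  tr <- object@tree
  if (!inherits(tr, "phylo")) return("slot 'tree' must be a 'phylo' object")
  if (!ape::is.rooted(tr)) return("guide tree must be rooted")
  if (is.null(tr$edge.length)) return("guide tree must carry branch lengths")
  if (length(tr$edge.length) != nrow(tr$edge))
    return("every non-root edge must carry a branch length")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    return("branch lengths must be finite and >= 0")
  labs <- c(tr$tip.label, tr$node.label)
  if (any(is.na(labs)) || any(labs == "")) return("node labels must be non-empty")
  if (anyDuplicated(tr$tip.label)) return("leaf labels must be unique")
  if (anyDuplicated(labs)) return("node labels must be unique")
  TRUE
})

#' Simulation configuration
#'
#' Holds every tunable constant of the simulator: the transcript-event
#' constant factor `kTc` and the seven relative proportions governing the
#' transcript-set events (a5, a3, es, me, ir, tl, rs), the exon-intron
#' structure evolution constants, and the sequence generation/evolution
#' constants. Construct with [spliceSimConfig()].
#'
#' @slot kTc constant factor scaling transcript-event budgets on branches.
#' @slot tc named numeric of the seven transcript-event proportions
#'   (`a5`, `a3`, `es`, `me`, `ir`, `tl`, `rs`), each >= 0.
#' @slot structure named list of structure-evolution constants.
#' @slot sequence named list of sequence generation/evolution constants.
#' @slot seed integer RNG seed fixed before any stochastic call.
#' @exportClass SpliceSimConfig
setClass("SpliceSimConfig",
  representation(kTc = "numeric", tc = "numeric", structure = "list",
                 sequence = "list", seed = "integer"))

setValidity("SpliceSimConfig", function(object) {
  need <- c("a5", "a3", "es", "me", "ir", "tl", "rs")
  if (!identical(names(object@tc), need))
    return(sprintf("tc must be named %s", paste(need, collapse = ", ")))
  if (any(!is.finite(object@tc)) || any(object@tc < 0))
    return("all tc proportions must be finite and >= 0")
  if (!is.finite(object@kTc) || object@kTc < 0) return("kTc must be >= 0")
  stc <- object@structure
  for (k in c("kSt", "loss", "gain", "dup")) {
    v <- stc[[k]]
    if (is.null(v) || !is.finite(v) || v < 0)
      return(sprintf("structure constant '%s' must be >= 0", k))
  }
  TRUE
})

#' Exon-intron structure of a gene at one tree node
#'
#' An ordered alternation of exons and introns: `m` exons and `m - 1`
#' introns. Exon and intron identifiers are globally unique and stable
#' across the tree, so homology is carried by identity.
#'
#' @slot nodeId label of the guide-tree node this structure belongs to.
#' @slot exonIds,exonSeqs parallel character vectors; every exon sequence
#'   has length divisible by 3.
#' @slot intronIds,intronSeqs parallel character vectors; intron `k` lies
#'   between exons `k` and `k + 1` and starts `GT` / ends `AG`.
#' @exportClass GeneStructure
setClass("GeneStructure",
  representation(nodeId = "character", exonIds = "character",
                 exonSeqs = "character", intronIds = "character",
                 intronSeqs = "character"))

setValidity("GeneStructure", function(object) {
  m <- length(object@exonIds)
  if (m < 1) return("a gene must keep at least one exon")
  if (length(object@exonSeqs) != m) return("exonSeqs must parallel exonIds")
  if (length(object@intronIds) != m - 1 ||
      length(object@intronSeqs) != m - 1)
    return("a gene with m exons must have exactly m - 1 introns")
  if (any(nchar(object@exonSeqs) %% 3L != 0L) ||
      any(nchar(object@exonSeqs) == 0L))
    return("exon sequence lengths must be positive multiples of 3")
  if (m > 1) {
    if (any(substr(object@intronSeqs, 1, 2) != "GT") ||
        any(substring(object@intronSeqs,
                      nchar(object@intronSeqs) - 1) != "AG"))
      return("introns must begin GT and end AG")
  }
  if (anyDuplicated(c(object@exonIds, object@intronIds)))
    return("exon/intron ids must be unique")
  TRUE
})

#' Directed forest of transcript evolutionary histories
#'
#' Nodes are all transcripts simulated at all guide-tree nodes; edges are
#' labeled `conserved` or by the AS event type that produced the child.
#' Roots are transcript gains. Losses are markers on (transcript, branch)
#' pairs, not forest nodes.
#'
#' @slot nodes data.frame with columns `id`, `gene` (guide-tree node label).
#' @slot edges data.frame with columns `parent`, `child`, `label`
#'   (one of conserved, a5, a3, es, me, ir).
#' @slot losses data.frame with columns `id` (lost transcript), `branch`
#'   (child node label of the branch on which it was lost), `type`
#'   (structural_loss or tl).
#' @exportClass TranscriptForest
setClass("TranscriptForest",
  representation(nodes = "data.frame", edges = "data.frame",
                 losses = "data.frame"))

setValidity("TranscriptForest", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "gene") %in% names(nd))) return("nodes need id, gene")
  if (!all(c("parent", "child", "label") %in% names(ed)))
    return("edges need parent, child, label")
  if (anyDuplicated(nd$id)) return("transcript ids must be unique")
  if (nrow(ed)) {
    if (!all(ed$parent %in% nd$id) || !all(ed$child %in% nd$id))
      return("edge endpoints must be forest nodes")
    if (anyDuplicated(ed$child)) return("sink in-degree must be <= 1")
    ok <- ed$label %in% c("conserved", "a5", "a3", "es", "me", "ir")
    if (!all(ok)) return("unknown edge label")
  }
  TRUE
})

#' Complete result of one simulation
#'
#' Returned by [simulateSpliceEvolution()]. Accessors: [geneStructures()],
#' [transcriptSets()], [transcriptForest()], [eventLog()], [stageTable()].
#'
#' @slot guideTree the validated [GuideTree-class].
#' @slot config the [SpliceSimConfig-class] used.
#' @slot structures named list of [GeneStructure-class], one per node.
#' @slot transcripts named list (per node) of transcript records.
#' @slot forest the [TranscriptForest-class].
#' @slot events data.frame event log (node, branch, stage, event_type,
#'   source_id, sink_id, payload).
#' @slot stages data.frame stage summaries (node, branch, stage, type,
#'   n_source, budget, n_applied).
#' @slot structureEvents named list (per non-root node) of structure event
#'   records for the branch leading to that node.
#' @slot seqLogs named list (per non-root node) of per-unit sequence event
#'   logs for the branch leading to that node.
#' @slot maps alignment bookkeeping: per-node unit -> global column maps,
#'   master unit order, per-unit column order and column origins.
#' @exportClass SpliceSimResult
setClass("SpliceSimResult",
  representation(guideTree = "GuideTree", config = "SpliceSimConfig",
                 structures = "list", transcripts = "list",
                 forest = "TranscriptForest", events = "data.frame",
                 stages = "data.frame", structureEvents = "list",
                 seqLogs = "list", maps = "list"))

#' True multiple sequence alignment
#'
#' Rows are gene and/or transcript sequences threaded through the global
#' column system built from the event logs; ungapping any row reproduces
#' that row's sequence exactly.
#'
#' @slot rows named character vector of aligned rows over `A,C,G,T,-`.
#' @slot columns data.frame of per-column provenance: `column` (global
#'   column id), `unit` (exon/intron lineage id), `origin` (root, gain,
#'   dup or insertion event that created the column).
#' @exportClass TrueAlignment
setClass("TrueAlignment",
  representation(rows = "character", columns = "data.frame"))

setValidity("TrueAlignment", function(object) {
  if (length(object@rows) && length(unique(nchar(object@rows))) != 1L)
    return("all alignment rows must have equal length")
  TRUE
})
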