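# Splicing orthology and the conservation-ratio statistic. Two transcripts
# are splicing orthologs when they belong to distinct extant genes and the
# unique forest path connecting them contains only conserved edges; the
# conserved-edge components of the forest therefore carry both the
# ortholog groups and the phylogeny-based transcript clusters.

# connected components of the conserved-edge subgraph; returns a named
# character vector id -> component label
conservedComponents <- function(forest) {
  ids <- forest@nodes$id
  ed <- forest@edges[forest@edges$label == "conserved", c("parent", "child"),
                     drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership
  stats::setNames(paste0("c", memb[ids]), ids)
}

leafTranscriptIds <- function(forest, leafGenes) {
  forest@nodes$id[forest@nodes$gene %in% leafGenes]
}

#' Test splicing orthology of two transcripts
#'
#' Two transcripts are splicing orthologs when they belong to distinct
#' extant genes (leaves of the guide tree), lie in the same transcript
#' tree, and every edge on the forest path connecting them is labeled
#' `conserved` (no AS event separates them). Transcripts of ancestral
#' genes are not considered orthologous to anything: orthology is a
#' statement about extant sequences.
#'
#' @param t1,t2 transcript ids.
#' @param forest a [TranscriptForest-class].
#' @param leafGenes character vector of extant gene labels (defaults to
#'   every gene in the forest that looks extant is unknown here, so pass
#'   the guide tree's leaf labels; [orthologGroups()] does this for you).
#' @return `TRUE` or `FALSE`.
#' @export
areOrthologs <- function(t1, t2, forest, leafGenes = unique(forest@nodes$gene)) {
  nd <- forest@nodes
  if (!(t1 %in% nd$id) || !(t2 %in% nd$id))
    stop("unknown transcript id: ", paste(setdiff(c(t1, t2), nd$id),
                                          collapse = ", "))
  g1 <- nd$gene[nd$id == t1]; g2 <- nd$gene[nd$id == t2]
  if (g1 == g2) return(FALSE)
  if (!(g1 %in% leafGenes) || !(g2 %in% leafGenes)) return(FALSE)
  comp <- conservedComponents(forest)
  unname(comp[t1] == comp[t2])
}

#' Groups of orthologous transcripts
#'
#' Maximal sets of pairwise splicing orthologs: the extant (leaf-gene)
#' transcripts of each conserved-edge connected component of the forest,
#' reported when the set covers at least two distinct genes. Should a
#' component ever contain two extant transcripts of the same gene, the
#' component is split into maximal same-gene-free subsets; for
#' duplication-free histories (one conserved descendant per transcript per
#' branch) components never contain same-gene pairs and no splitting
#' occurs.
#'
#' @param forest a [TranscriptForest-class].
#' @param leafGenes labels of the extant genes (guide-tree leaves).
#' @return list of character vectors of transcript ids.
#' @export
orthologGroups <- function(forest, leafGenes = unique(forest@nodes$gene)) {
  comp <- conservedComponents(forest)
  leaves <- leafTranscriptIds(forest, leafGenes)
  if (!length(leaves)) return(list())
  split_ids <- split(leaves, comp[leaves])
  out <- list()
  for (grp in split_ids) {
    if (length(grp) < 2L) next
    genes <- forest@nodes$gene[match(grp, forest@nodes$id)]
    if (anyDuplicated(genes)) {
      # split per the pairwise definition: one transcript per gene
      for (pick in seq_len(max(table(genes)))) {
        sel <- unlist(lapply(split(grp, genes), function(g)
          if (length(g) >= pick) g[pick] else NULL))
        if (length(sel) >= 2L) out[[length(out) + 1L]] <- unname(sort(sel))
      }
    } else if (length(unique(genes)) >= 2L) {
      out[[length(out) + 1L]] <- sort(grp)
    }
  }
  out
}

#' Transcript clusters
#'
#' Two ways of partitioning the extant (leaf-gene) transcripts into
#' clusters of conserved transcripts. `clusterByPhylogeny()` uses the
#' simulated history: clusters are the conserved-edge connected components
#' of the forest restricted to leaf transcripts. `clusterByExonComposition()`
#' ignores the history and groups transcripts whose homologous-exon
#' composition (exon ids plus boundary offsets plus retained introns) is
#' identical.
#'
#' @param forest a [TranscriptForest-class].
#' @param leafGenes labels of the extant genes.
#' @return named list: cluster label -> character vector of transcript ids;
#'   the clusters partition the leaf transcripts.
#' @export
clusterByPhylogeny <- function(forest, leafGenes = unique(forest@nodes$gene)) {
  comp <- conservedComponents(forest)
  leaves <- leafTranscriptIds(forest, leafGenes)
  split(leaves, comp[leaves])
}

#' @rdname clusterByPhylogeny
#' @param result a [SpliceSimResult-class] (composition clustering needs
#'   the transcript records, not just the forest).
#' @export
clusterByExonComposition <- function(result,
                                     leafGenes = leafLabels(result@guideTree)) {
  txs <- list()
  for (nd in leafGenes) txs <- c(txs, result@transcripts[[nd]])
  if (!length(txs)) return(list())
  sigs <- vapply(txs, txSignature, "")
  ids <- vapply(txs, `[[`, "", "id")
  split(ids, sigs)
}

#' Conservation ratio
#'
#' The number of conserved transcript clusters divided by the number of
#' transcripts clustered. A ratio of 1 indicates no conservation (every
#' transcript alone in its cluster); a ratio tending to 0 indicates all
#' transcripts grouped together.
#'
#' @param clusters list of clusters (as from [clusterByPhylogeny()]).
#' @param transcripts character vector of the transcript ids partitioned
#'   by `clusters` (defaults to their union).
#' @return a number in (0, 1].
#' @export
conservationRatio <- function(clusters, transcripts = unlist(clusters)) {
  n <- length(unique(transcripts))
  if (n == 0L) stop("domain error: conservation ratio needs >= 1 transcript")
  covered <- sort(unique(unlist(clusters)))
  if (!identical(covered, sort(unique(transcripts))))
    stop("clusters must partition the transcripts")
  length(clusters) / n
}

#' Conservation-ratio comparison experiment
#'
#' For each seed and each `kTc` value, runs (a) a full simulation and
#' computes the phylogeny-based conservation ratio of its leaf
#' transcripts, and (b) an independent history-free simulation in which
#' the transcript set of every leaf gene is re-generated from its own
#' structure by the root procedure (no inheritance along branches), scored
#' by exon-composition clustering. History-aware clustering is expected to
#' yield lower ratios (more conservation) than composition clustering of
#' history-free sets.
#'
#' @param tree a [GuideTree-class] or Newick string.
#' @param config base [SpliceSimConfig-class]; its `kTc` and seed are
#'   overridden per run.
#' @param kTcValues numeric vector of `kTc` values to test.
#' @param iterations number of seeds per `kTc` value.
#' @param seedBase seeds used are `seedBase + 1:iterations`.
#' @return data.frame with columns seed, k_tc, mode (`phylogeny` or
#'   `composition`), n_transcripts, n_clusters, ratio (`NA` when a run
#'   leaves no transcripts at the leaves).
#' @export
conservationExperiment <- function(tree, config = spliceSimConfig(),
                                   kTcValues = config@kTc, iterations = 10L,
                                   seedBase = 0L) {
  if (is.character(tree)) tree <- parseGuideTree(tree)
  out <- NULL
  for (k in kTcValues) {
    for (it in seq_len(iterations)) {
      cfg <- config
      cfg@kTc <- k
      cfg@seed <- as.integer(seedBase + it)
      res <- simulateSpliceEvolution(tree, cfg)
      lg <- leafLabels(tree)
      cl <- clusterByPhylogeny(res@forest, lg)
      nTx <- length(unlist(cl))
      out <- rbind(out, data.frame(seed = cfg@seed, k_tc = k,
                                   mode = "phylogeny", n_transcripts = nTx,
                                   n_clusters = length(cl),
                                   ratio = if (nTx > 0) length(cl) / nTx
                                           else NA_real_,
                                   stringsAsFactors = FALSE))
      free <- historyFreeLeafSets(res, cfg)
      ncl <- length(unique(free$sigs))
      out <- rbind(out, data.frame(seed = cfg@seed, k_tc = k,
                                   mode = "composition",
                                   n_transcripts = length(free$ids),
                                   n_clusters = ncl,
                                   ratio = if (length(free$ids) > 0)
                                     ncl / length(free$ids) else NA_real_,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# history-free leaf transcript sets: re-run the root procedure on every
# leaf structure independently (no evolutionary connection between nodes)
historyFreeLeafSets <- function(result, config) {
  ids <- character(0); sigs <- character(0)
  for (nd in leafLabels(result@guideTree)) {
    st <- result@structures[[nd]]
    txs <- withNodeSeed(config@seed + 1000003L, nd,
                        simulateRootTranscripts(st, config)$transcripts)
    ids <- c(ids, vapply(txs, `[[`, "", "id"))
    sigs <- c(sigs, vapply(txs, txSignature, ""))
  }
  list(ids = ids, sigs = sigs)
}
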