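# Shared fixtures: a fast small-gene configuration, random guide trees,
# and the worked three-gene scenario (ancestral gene with exons e1..e4,
# transcripts 1#1..1#7, exon e4 lost on the branch to the first child).

smallConfig <- function(seed = 1L, structure = list(), kTc = 2, ...) {
  stDef <- list(exonCountMean = 4, exonCountSd = 1,
                exonLenMeanCodons = 8, exonLenSdCodons = 2,
                intronLenMean = 30, intronLenSd = 6)
  stDef[names(structure)] <- structure
  spliceSimConfig(kTc = kTc, structure = stDef, seed = seed, ...)
}

randomTreeText <- function(nLeaves, maxLen = 0.3) {
  tr <- ape::rtree(nLeaves, br = function(n) stats::runif(n, 0.05, maxLen))
  ape::write.tree(tr)
}

# deterministic exon/intron sequences for hand-built structures
fixedExon <- function(len = 6L) paste(rep("GCA", len %/% 3L), collapse = "")
fixedIntron <- function(len = 30L) {
  paste0("GT", paste(rep("C", len - 4L), collapse = ""), "AG")
}

fig1Structure <- function() {
  new("GeneStructure", nodeId = "Gene1",
      exonIds = paste0("e", 1:4),
      exonSeqs = rep(fixedExon(9L), 4),
      intronIds = paste0("i", 1:3),
      intronSeqs = rep(fixedIntron(30L), 3))
}

fig1ChildStructure <- function(nodeId = "Gene2") {
  new("GeneStructure", nodeId = nodeId,
      exonIds = paste0("e", 1:3),
      exonSeqs = rep(fixedExon(9L), 3),
      intronIds = paste0("i", 1:2),
      intronSeqs = rep(fixedIntron(30L), 2))
}

fig1LossEvents <- function() {
  list(list(kind = "exon_loss", exonId = "e4", index = 4L))
}

# 1#1 and 1#7 avoid e4; 1#2..1#6 all contain e4 (the basis of the five
# structural losses); concrete compositions are otherwise free.
fig1Transcripts <- function() {
  mk <- function(k, exons) makeTranscript(paste0("Gene1#", k), "Gene1", exons)
  list(mk(1, c("e1", "e2", "e3")),
       mk(2, c("e1", "e2", "e3", "e4")),
       mk(3, c("e1", "e2", "e4")),
       mk(4, c("e1", "e3", "e4")),
       mk(5, c("e2", "e3", "e4")),
       mk(6, c("e1", "e4")),
       mk(7, c("e2", "e3")))
}

# hand-built forest of the same scenario: 1#1 conserved into both child
# genes (2#1, 3#1); everything else separated by AS events or gains
fig1Forest <- function() {
  nodes <- data.frame(
    id = c(paste0("Gene1#", 1:7), "Gene2#0", "Gene2#1", "Gene3#1", "Gene3#2"),
    gene = c(rep("Gene1", 7), "Gene2", "Gene2", "Gene3", "Gene3"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    parent = c("Gene1#2", "Gene1#3", "Gene1#1", "Gene1#1", "Gene1#1",
               "Gene1#1", "Gene1#1", "Gene3#1"),
    child  = c("Gene1#3", "Gene1#6", "Gene1#4", "Gene1#5", "Gene1#7",
               "Gene2#1", "Gene3#1", "Gene3#2"),
    label  = c("es", "a3", "a5", "me", "ir", "conserved", "conserved", "es"),
    stringsAsFactors = FALSE)
  losses <- data.frame(id = character(0), branch = character(0),
                       type = character(0), stringsAsFactors = FALSE)
  new("TranscriptForest", nodes = nodes, edges = edges, losses = losses)
}

# replay the stored structural + sequence logs of the branch leading to
# `child`; must reproduce the child structure exactly
replayBranch <- function(res, child) {
  parent <- spliceforest:::parentOf(res@guideTree, child)
  st0 <- replayStructureEvents(geneStructures(res)[[parent]],
                               res@structureEvents[[child]], child)
  logs <- res@seqLogs[[child]]
  eseqs <- vapply(seq_along(st0@exonIds), function(k)
    replaySequenceLog(st0@exonSeqs[k], logs[[st0@exonIds[k]]]), "")
  iseqs <- vapply(seq_along(st0@intronIds), function(k)
    replaySequenceLog(st0@intronSeqs[k], logs[[st0@intronIds[k]]]), "")
  if (!length(st0@intronIds)) iseqs <- character(0)
  new("GeneStructure", nodeId = child, exonIds = st0@exonIds,
      exonSeqs = eseqs, intronIds = st0@intronIds, intronSeqs = iseqs)
}

# full invariant battery over one simulation result; expectations are
# aggregated (one expect per property) so the battery stays fast across
# hundreds of seeds
checkSimulationInvariants <- function(res, checkAlignment = TRUE) {
  gt <- res@guideTree
  cfg <- res@config
  root <- spliceforest:::rootLabel(gt)
  sts <- stageTable(res)

  # forest sanity: in-degree <= 1, rs transcripts are roots
  expect_equal(anyDuplicated(res@forest@edges$child), 0L)
  rsIds <- unlist(lapply(transcriptSets(res), function(s)
    vapply(Filter(function(tx) tx$origin == "rs", s), `[[`, "", "id")))
  expect_false(any(rsIds %in% res@forest@edges$child))

  # no transcript losses at the root
  expect_false(root %in% res@forest@losses$branch)
  expect_false(any(res@events$event_type %in% c("tl", "structural_loss") &
                     !is.na(res@events$node) & res@events$node == root))

  # per-stage event counts match the budget formula recomputed from logs
  tr <- gt@tree
  labs <- c(tr$tip.label, tr$node.label)
  brLen <- function(child)
    tr$edge.length[tr$edge[, 2] == match(child, labs)]
  as <- sts[sts$type %in% c("es", "me", "a5", "a3", "ir"), ]
  expected <- vapply(seq_len(nrow(as)), function(r) {
    row <- as[r, ]
    if (!is.na(row$node) && row$node == root)
      rootEventBudget(row$n_source, cfg@tc[[row$type]])
    else eventBudget(row$n_source, cfg@tc[[row$type]], cfg@kTc,
                     brLen(row$branch))
  }, 0L)
  expect_equal(as$budget, expected)
  expect_true(all(as$n_applied <= as$budget))

  # structure invariants, Dollo, transcript consistency, mod-3
  dolloOK <- TRUE
  lostBelow <- function(label, lost) {
    st <- geneStructures(res)[[label]]
    if (any(lost %in% st@exonIds)) dolloOK <<- FALSE
    for (k in spliceforest:::childrenOf(gt, label)$child) {
      ev <- res@structureEvents[[k]]
      lostHere <- vapply(Filter(function(e) e$kind == "exon_loss", ev),
                         `[[`, "", "exonId")
      lostBelow(k, c(lost, lostHere))
    }
  }
  lostBelow(root, character(0))
  expect_true(dolloOK)

  structOK <- TRUE; txOK <- TRUE; frameOK <- TRUE
  for (nd in names(geneStructures(res))) {
    st <- geneStructures(res)[[nd]]
    if (length(st@intronIds) != length(st@exonIds) - 1L ||
        any(nchar(st@exonSeqs) %% 3L != 0L)) structOK <- FALSE
    for (tx in transcriptSets(res)[[nd]]) {
      idx <- match(tx$exons, st@exonIds)
      if (any(is.na(idx)) || is.unsorted(idx, strictly = TRUE)) txOK <- FALSE
      if (any(c(tx$off5, tx$off3) %% 3 != 0) ||
          nchar(transcriptCDS(st, tx)) %% 3L != 0L) frameOK <- FALSE
    }
  }
  expect_true(structOK)
  expect_true(txOK)
  expect_true(frameOK)

  # branch replay oracle (structure + sequence logs)
  replayOK <- TRUE
  for (nd in setdiff(names(geneStructures(res)), root)) {
    rep <- replayBranch(res, nd)
    st <- geneStructures(res)[[nd]]
    if (!identical(rep@exonIds, st@exonIds) ||
        !identical(rep@exonSeqs, st@exonSeqs) ||
        !identical(rep@intronSeqs, st@intronSeqs)) replayOK <- FALSE
  }
  expect_true(replayOK)

  if (checkAlignment) {
    aln <- buildTrueAlignment(res, "all")
    expect_equal(length(unique(nchar(aln@rows))), 1L)
    ungapOK <- TRUE
    for (nd in names(geneStructures(res))) {
      st <- geneStructures(res)[[nd]]
      if (!identical(ungap(aln@rows[[nd]]), geneSequence(st)))
        ungapOK <- FALSE
      for (tx in transcriptSets(res)[[nd]])
        if (!identical(ungap(aln@rows[[tx$id]]), transcriptCDS(st, tx)))
          ungapOK <- FALSE
    }
    expect_true(ungapOK)
    # forest Newick round trip
    fl <- writeTranscriptForest(res@forest)
    f2 <- readTranscriptForest(lines = fl)
    expect_setequal(f2@nodes$id, res@forest@nodes$id)
    expect_setequal(paste(f2@edges$parent, f2@edges$child, f2@edges$label),
                    paste(res@forest@edges$parent, res@forest@edges$child,
                          res@forest@edges$label))
  }
  invisible(TRUE)
}
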