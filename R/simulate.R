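# Top-level simulation: preorder traversal of the guide tree, evolving the
# structure, the unit sequences and the transcript set on every branch,
# while threading every indel and structural event through a global column
# system from which the true alignments are later assembled.

newMaster <- function() {
  m <- new.env(parent = emptyenv())
  m$units <- character(0)       # ordered master unit ids
  m$cols <- list()              # unit id -> ordered global column ids
  m$colUnit <- character(0)     # column id -> owning unit
  m$colOrigin <- character(0)   # column id -> provenance label
  m$nextCol <- 0L
  m
}

newCols <- function(master, n, unit, origin) {
  if (n == 0L) return(integer(0))
  ids <- master$nextCol + seq_len(n)
  master$nextCol <- master$nextCol + n
  master$colUnit[ids] <- unit
  master$colOrigin[ids] <- origin
  ids
}

# insert `unitIds` (in order) into the master unit order after `anchorUnit`
# (NULL = at the front); anchors that are not master units (merged introns)
# resolve through the owner of their last column.
addUnitsAfter <- function(master, unitIds, anchorUnit, map = NULL) {
  if (is.null(anchorUnit)) {
    master$units <- c(unitIds, master$units)
    return(invisible(NULL))
  }
  if (!(anchorUnit %in% master$units)) {
    v <- map[[anchorUnit]]
    anchorUnit <- master$colUnit[v[length(v)]]
  }
  at <- match(anchorUnit, master$units)
  master$units <- append(master$units, unitIds, after = at)
  invisible(NULL)
}

# splice freshly allocated columns into the per-unit master column order,
# after global column `afterCol` (NA = before `beforeCol`).
spliceCols <- function(master, ids, afterCol = NA, beforeCol = NA) {
  if (!is.na(afterCol)) {
    u <- master$colUnit[afterCol]
    at <- match(afterCol, master$cols[[u]])
    master$cols[[u]] <- append(master$cols[[u]], ids, after = at)
  } else {
    u <- master$colUnit[beforeCol]
    at <- match(beforeCol, master$cols[[u]]) - 1L
    master$cols[[u]] <- append(master$cols[[u]], ids, after = at)
  }
  invisible(NULL)
}

registerRootStructure <- function(master, structure) {
  map <- list()
  m <- length(structure@exonIds)
  order <- character(0)
  for (k in seq_len(m)) {
    eid <- structure@exonIds[k]
    ids <- newCols(master, nchar(structure@exonSeqs[k]), eid, "root")
    master$cols[[eid]] <- ids
    map[[eid]] <- ids
    order <- c(order, eid)
    if (k < m) {
      iid <- structure@intronIds[k]
      ids <- newCols(master, nchar(structure@intronSeqs[k]), iid, "root")
      master$cols[[iid]] <- ids
      map[[iid]] <- ids
      order <- c(order, iid)
    }
  }
  master$units <- order
  map
}

# replay structural events on the parent's column map
mapAfterStructureEvents <- function(master, parentMap, parentStruct, events,
                                    nodeLabel) {
  map <- parentMap
  exons <- parentStruct@exonIds
  intr <- parentStruct@intronIds
  for (ev in events) {
    if (ev$kind == "exon_loss_skipped") next
    if (ev$kind == "exon_loss") {
      i <- match(ev$exonId, exons)
      mCur <- length(exons)
      if (i == 1L) {
        map[[intr[1L]]] <- NULL
        intr <- intr[-1L]
      } else if (i == mCur) {
        map[[intr[mCur - 1L]]] <- NULL
        intr <- intr[-(mCur - 1L)]
      } else {
        map[[ev$merged$newId]] <- c(map[[ev$merged$leftId]],
                                    map[[ev$merged$rightId]])
        map[[ev$merged$leftId]] <- NULL
        map[[ev$merged$rightId]] <- NULL
        intr[i - 1L] <- ev$merged$newId
        intr <- intr[-i]
      }
      map[[ev$exonId]] <- NULL
      exons <- exons[-i]
    } else if (ev$kind == "exon_gain") {
      j <- ev$index; mCur <- length(exons)
      eCols <- newCols(master, nchar(ev$exonSeq), ev$exonId,
                       paste0("gain:", nodeLabel))
      iCols <- newCols(master, nchar(ev$intronSeq), ev$intronId,
                       paste0("gain:", nodeLabel))
      master$cols[[ev$exonId]] <- eCols
      master$cols[[ev$intronId]] <- iCols
      if (j == 0L) {
        addUnitsAfter(master, c(ev$exonId, ev$intronId), NULL)
      } else if (j < mCur) {
        addUnitsAfter(master, c(ev$exonId, ev$intronId), intr[j], map)
      } else {
        addUnitsAfter(master, c(ev$intronId, ev$exonId), exons[mCur], map)
      }
      map[[ev$exonId]] <- eCols
      map[[ev$intronId]] <- iCols
      exons <- append(exons, ev$exonId, after = j)
      intr <- append(intr, ev$intronId, after = min(j + 1L, mCur) - 1L)
    } else if (ev$kind == "exon_duplication") {
      t <- match(ev$templateId, exons)
      eCols <- newCols(master, nchar(ev$exonSeq), ev$exonId,
                       paste0("dup:", ev$templateId))
      iCols <- newCols(master, nchar(ev$intronSeq), ev$intronId,
                       paste0("dup:", ev$templateId))
      master$cols[[ev$exonId]] <- eCols
      master$cols[[ev$intronId]] <- iCols
      addUnitsAfter(master, c(ev$intronId, ev$exonId), ev$templateId, map)
      map[[ev$exonId]] <- eCols
      map[[ev$intronId]] <- iCols
      exons <- append(exons, ev$exonId, after = t)
      intr <- append(intr, ev$intronId, after = t - 1L)
    }
  }
  map
}

applySeqLogToMap <- function(master, map, unit, log, branchLabel) {
  v <- map[[unit]]
  for (ev in log) {
    if (ev$kind == "substitution") next
    if (ev$kind == "insertion") {
      anchor <- if (ev$pos == 0L) v[1L] else v[ev$pos]
      ids <- newCols(master, nchar(ev$seq), master$colUnit[anchor],
                     paste0("ins:", branchLabel))
      if (ev$pos == 0L) spliceCols(master, ids, beforeCol = anchor)
      else spliceCols(master, ids, afterCol = anchor)
      v <- append(v, ids, after = ev$pos)
    } else if (ev$kind == "deletion") {
      v <- v[-(ev$pos:(ev$pos + ev$len - 1L))]
    }
  }
  map[[unit]] <- v
  map
}

#' Simulate splicing-aware gene and transcript evolution
#'
#' Runs the complete simulation over a guide gene tree: the ancestral
#' exon-intron structure and transcript set are simulated at the root,
#' then every branch (preorder) evolves the structure (exon loss, gain,
#' duplication), the exon/intron sequences (codon- and nucleotide-level
#' substitutions and indels) and the transcript set (structural and
#' regulated losses, gains, and one evolutionary stage per AS type).
#' Every stochastic draw flows from `config@seed`; per-node RNG streams
#' are derived from `(seed, node label)`, so results are reproducible.
#'
#' @param tree a [GuideTree-class], or a Newick/NHX string or file path.
#' @param config a [SpliceSimConfig-class] from [spliceSimConfig()].
#' @return a [SpliceSimResult-class].
#' @examples
#' res <- simulateSpliceEvolution("((A:0.3,B:0.4):0.2,C:0.5);",
#'                                spliceSimConfig(seed = 42))
#' res
#' @export
simulateSpliceEvolution <- function(tree, config = spliceSimConfig()) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) parseGuideTree(file = tree)
            else parseGuideTree(tree)
  }
  validObject(tree)
  validObject(config)
  seed <- config@seed
  idGen <- makeIdGen()
  master <- newMaster()
  root <- rootLabel(tree)

  structures <- list(); transcripts <- list(); maps <- list()
  structureEvents <- list(); seqLogs <- list()
  allEvents <- emptyEvents(); allStages <- NULL
  edges <- data.frame(parent = character(0), child = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  losses <- data.frame(id = character(0), branch = character(0),
                       type = character(0), stringsAsFactors = FALSE)

  rootOut <- withNodeSeed(seed, root, {
    st <- simulateRootStructure(config, root, idGen)
    list(struct = st, txs = simulateRootTranscripts(st, config))
  })
  structures[[root]] <- rootOut$struct
  transcripts[[root]] <- rootOut$txs$transcripts
  maps[[root]] <- registerRootStructure(master, rootOut$struct)
  allEvents <- rbind(allEvents, rootOut$txs$events)
  allStages <- rbind(allStages, rootOut$txs$stages)
  edges <- rbind(edges, rootOut$txs$edges)

  recurse <- function(label) {
    kids <- childrenOf(tree, label)
    for (r in seq_len(nrow(kids))) {
      child <- kids$child[r]
      len <- kids$length[r]
      parentStruct <- structures[[label]]
      out <- withNodeSeed(seed, child, {
        evo <- evolveStructure(parentStruct, len, config, child, idGen)
        preSeq <- evo$structure
        logs <- list()
        eseqs <- preSeq@exonSeqs
        for (k in seq_along(eseqs)) {
          r2 <- evolveExonSequence(eseqs[k], len, config)
          eseqs[k] <- r2$seq
          logs[[preSeq@exonIds[k]]] <- r2$log
        }
        iseqs <- preSeq@intronSeqs
        for (k in seq_along(iseqs)) {
          r2 <- evolveIntronSequence(iseqs[k], len, config)
          iseqs[k] <- r2$seq
          logs[[preSeq@intronIds[k]]] <- r2$log
        }
        childStruct <- new("GeneStructure", nodeId = child,
                           exonIds = preSeq@exonIds, exonSeqs = eseqs,
                           intronIds = preSeq@intronIds, intronSeqs = iseqs)
        prop <- propagateTranscripts(transcripts[[label]], parentStruct,
                                     childStruct, evo$events, len, config,
                                     child)
        list(evo = evo, childStruct = childStruct, logs = logs, prop = prop)
      })
      structures[[child]] <<- out$childStruct
      transcripts[[child]] <<- out$prop$transcripts
      structureEvents[[child]] <<- out$evo$events
      seqLogs[[child]] <<- out$logs
      map <- mapAfterStructureEvents(master, maps[[label]], parentStruct,
                                     out$evo$events, child)
      for (unit in names(out$logs))
        map <- applySeqLogToMap(master, map, unit, out$logs[[unit]], child)
      maps[[child]] <<- map
      allEvents <<- rbind(allEvents, out$prop$events)
      allStages <<- rbind(allStages, out$prop$stages)
      edges <<- rbind(edges, out$prop$edges)
      losses <<- rbind(losses, out$prop$losses)
      recurse(child)
    }
  }
  recurse(root)

  allTx <- do.call(rbind, lapply(names(transcripts), function(nd) {
    ids <- vapply(transcripts[[nd]], `[[`, "", "id")
    if (!length(ids)) return(NULL)
    data.frame(id = ids, gene = nd, stringsAsFactors = FALSE)
  }))
  if (is.null(allTx))
    allTx <- data.frame(id = character(0), gene = character(0),
                        stringsAsFactors = FALSE)
  forest <- new("TranscriptForest", nodes = allTx, edges = edges,
                losses = losses)
  validObject(forest)

  new("SpliceSimResult", guideTree = tree, config = config,
      structures = structures, transcripts = transcripts, forest = forest,
      events = allEvents, stages = allStages,
      structureEvents = structureEvents, seqLogs = seqLogs,
      maps = list(nodeMaps = maps, units = master$units,
                  cols = master$cols, colUnit = master$colUnit,
                  colOrigin = master$colOrigin))
}

#' @describeIn simulateSpliceEvolution gene structures per node.
#' @param result a [SpliceSimResult-class].
#' @export
geneStructures <- function(result) result@structures

#' @describeIn simulateSpliceEvolution transcript records per node.
#' @export
transcriptSets <- function(result) result@transcripts

#' @describeIn simulateSpliceEvolution the transcript forest.
#' @export
transcriptForest <- function(result) result@forest

#' @describeIn simulateSpliceEvolution the full event log.
#' @export
eventLog <- function(result) result@events

#' @describeIn simulateSpliceEvolution per-stage summaries (source count,
#'   budget, applied events).
#' @export
stageTable <- function(result) result@stages

setMethod("show", "SpliceSimResult", function(object) {
  nTx <- sum(vapply(object@transcripts, length, 0L))
  cat("SpliceSimResult\n")
  cat(sprintf("  guide tree: %d leaves; %d gene nodes simulated\n",
              length(leafLabels(object@guideTree)),
              length(object@structures)))
  cat(sprintf("  transcripts: %d across all nodes; forest: %d edges, %d losses\n",
              nTx, nrow(object@forest@edges), nrow(object@forest@losses)))
  cat(sprintf("  events logged: %d\n", nrow(object@events)))
  invisible(NULL)
})

setMethod("show", "TranscriptForest", function(object) {
  roots <- setdiff(object@nodes$id, object@edges$child)
  cat(sprintf("TranscriptForest: %d transcripts, %d edges, %d trees, %d loss markers\n",
              nrow(object@nodes), nrow(object@edges), length(roots),
              nrow(object@losses)))
  invisible(NULL)
})
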