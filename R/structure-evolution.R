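# Exon-intron structure evolution: exon loss (with flanking-intron merge),
# exon gain (freshly generated exon) and exon duplication (verbatim copy
# that diverges afterwards through sequence evolution). Lost exon ids are
# never reused, so Dollo parsimony holds by construction.

# shared generator of globally unique exon/intron ids
makeIdGen <- function(start = 0L) {
  env <- new.env(parent = emptyenv())
  env$counter <- as.integer(start)
  env$nextId <- function(prefix) {
    env$counter <- env$counter + 1L
    paste0(prefix, env$counter)
  }
  env
}

# a fresh generator whose ids cannot collide with those already in `ids`
idGenAfter <- function(ids) {
  suff <- suppressWarnings(as.integer(sub("^[a-z]+", "", ids)))
  makeIdGen(max(0L, suff[is.finite(suff)]))
}

drawExonLength <- function(config) {
  st <- config@structure
  3L * max(3L, round(stats::rnorm(1, st$exonLenMeanCodons, st$exonLenSdCodons)))
}

drawIntronLength <- function(config) {
  st <- config@structure
  max(12L, round(stats::rnorm(1, st$intronLenMean, st$intronLenSd)))
}

#' Simulate the ancestral gene structure at the root
#'
#' Draws the exon count from a normal distribution (mean
#' `structure$exonCountMean`, sd `structure$exonCountSd`, clamped to >= 1),
#' generates each exon from the exon Markov chain (lengths normal in
#' codons, clamped to >= 3 codons) and each of the `m - 1` introns from the
#' intron chain (lengths normal, clamped to >= 12 nt).
#'
#' @param config a [SpliceSimConfig-class].
#' @param nodeId label for the root node.
#' @param idGen internal id generator; supply one shared generator when
#'   composing structures manually.
#' @return a [GeneStructure-class].
#' @export
simulateRootStructure <- function(config, nodeId = "root",
                                  idGen = makeIdGen()) {
  st <- config@structure
  m <- max(1L, round(stats::rnorm(1, st$exonCountMean, st$exonCountSd)))
  exonIds <- vapply(seq_len(m), function(i) idGen$nextId("e"), "")
  exonSeqs <- vapply(seq_len(m), function(i)
    generateExonSequence(drawExonLength(config), config@sequence$exonChain), "")
  intronIds <- intronSeqs <- character(0)
  if (m > 1) {
    intronIds <- vapply(seq_len(m - 1L), function(i) idGen$nextId("i"), "")
    intronSeqs <- vapply(seq_len(m - 1L), function(i)
      generateIntronSequence(drawIntronLength(config),
                             config@sequence$intronChain), "")
  }
  new("GeneStructure", nodeId = nodeId, exonIds = exonIds,
      exonSeqs = exonSeqs, intronIds = intronIds, intronSeqs = intronSeqs)
}

#' Evolve an exon-intron structure along a branch
#'
#' Event counts per kind are `ceiling(kSt * branchLength * m * proportion)`
#' with `m` the parent's exon count (the structure analogue of the
#' transcript budget). Losses remove a uniformly chosen exon and merge its
#' flanking introns (at a gene end the single flanking intron is removed
#' with it); a loss that would leave the gene exonless is skipped and
#' logged. Gains insert a freshly generated exon (new id) at a uniform
#' slot among the `m + 1` possibilities, with a freshly generated intron
#' separating it from its neighbour. Duplications copy a uniformly chosen
#' template verbatim (new id, parent-linked) immediately after it.
#'
#' @param parent a [GeneStructure-class].
#' @param branchLength the branch length `c_s_r`.
#' @param config a [SpliceSimConfig-class].
#' @param childNodeId label for the child node.
#' @param idGen id generator; defaults to one that avoids the parent's ids.
#' @return `list(structure = <child GeneStructure>, events = <list>)`;
#'   [replayStructureEvents()] on the parent reproduces the child.
#' @export
evolveStructure <- function(parent, branchLength, config,
                            childNodeId = parent@nodeId,
                            idGen = idGenAfter(c(parent@exonIds,
                                                 parent@intronIds))) {
  st <- config@structure
  m <- length(parent@exonIds)
  counts <- vapply(c(loss = st$loss, gain = st$gain, dup = st$dup),
                   function(p) eventBudget(m, p, st$kSt, branchLength), 0L)
  exons <- parent@exonIds; eseqs <- parent@exonSeqs
  intr <- parent@intronIds; iseqs <- parent@intronSeqs
  events <- list()
  rec <- function(ev) events[[length(events) + 1L]] <<- ev

  for (k in seq_len(counts["loss"])) {
    if (length(exons) <= 1L) {
      rec(list(kind = "exon_loss_skipped",
               reason = "gene must keep at least one exon"))
      next
    }
    i <- sample.int(length(exons), 1L)
    mCur <- length(exons)
    ev <- list(kind = "exon_loss", exonId = exons[i], index = i)
    if (i == 1L) {
      ev$removedIntronId <- intr[1L]
      intr <- intr[-1L]; iseqs <- iseqs[-1L]
    } else if (i == mCur) {
      ev$removedIntronId <- intr[mCur - 1L]
      intr <- intr[-(mCur - 1L)]; iseqs <- iseqs[-(mCur - 1L)]
    } else {
      newId <- idGen$nextId("i")
      ev$merged <- list(newId = newId, leftId = intr[i - 1L],
                        rightId = intr[i])
      iseqs[i - 1L] <- paste0(iseqs[i - 1L], iseqs[i])
      intr[i - 1L] <- newId
      intr <- intr[-i]; iseqs <- iseqs[-i]
    }
    exons <- exons[-i]; eseqs <- eseqs[-i]
    rec(ev)
  }

  for (k in seq_len(counts["gain"])) {
    mCur <- length(exons)
    j <- sample.int(mCur + 1L, 1L) - 1L          # slot 0..m
    exId <- idGen$nextId("e")
    exSeq <- generateExonSequence(drawExonLength(config),
                                  config@sequence$exonChain)
    inId <- idGen$nextId("i")
    inSeq <- generateIntronSequence(drawIntronLength(config),
                                    config@sequence$intronChain)
    exons <- append(exons, exId, after = j); eseqs <- append(eseqs, exSeq, after = j)
    iAt <- min(j + 1L, mCur)
    intr <- append(intr, inId, after = iAt - 1L)
    iseqs <- append(iseqs, inSeq, after = iAt - 1L)
    rec(list(kind = "exon_gain", exonId = exId, index = j, exonSeq = exSeq,
             intronId = inId, intronSeq = inSeq))
  }

  for (k in seq_len(counts["dup"])) {
    mCur <- length(exons)
    t <- sample.int(mCur, 1L)
    exId <- idGen$nextId("e")
    inId <- idGen$nextId("i")
    inSeq <- generateIntronSequence(drawIntronLength(config),
                                    config@sequence$intronChain)
    rec(list(kind = "exon_duplication", exonId = exId,
             templateId = exons[t], index = t, exonSeq = eseqs[t],
             intronId = inId, intronSeq = inSeq))
    exons <- append(exons, exId, after = t); eseqs <- append(eseqs, eseqs[t], after = t)
    intr <- append(intr, inId, after = t - 1L)
    iseqs <- append(iseqs, inSeq, after = t - 1L)
  }

  child <- new("GeneStructure", nodeId = childNodeId, exonIds = exons,
               exonSeqs = eseqs, intronIds = intr, intronSeqs = iseqs)
  list(structure = child, events = events)
}

#' Replay structure events on a parent structure
#'
#' Deterministically re-applies a list of structure event records (as
#' produced by [evolveStructure()]) to the parent structure; the result
#' equals the child structure before sequence evolution.
#'
#' @param parent a [GeneStructure-class].
#' @param events list of structure event records.
#' @param childNodeId label for the resulting structure.
#' @return a [GeneStructure-class].
#' @export
replayStructureEvents <- function(parent, events,
                                  childNodeId = parent@nodeId) {
  exons <- parent@exonIds; eseqs <- parent@exonSeqs
  intr <- parent@intronIds; iseqs <- parent@intronSeqs
  for (ev in events) {
    if (ev$kind == "exon_loss_skipped") next
    if (ev$kind == "exon_loss") {
      i <- match(ev$exonId, exons)
      if (is.na(i)) stop("replay mismatch: exon ", ev$exonId, " absent")
      mCur <- length(exons)
      if (i == 1L) {
        intr <- intr[-1L]; iseqs <- iseqs[-1L]
      } else if (i == mCur) {
        intr <- intr[-(mCur - 1L)]; iseqs <- iseqs[-(mCur - 1L)]
      } else {
        iseqs[i - 1L] <- paste0(iseqs[i - 1L], iseqs[i])
        intr[i - 1L] <- ev$merged$newId
        intr <- intr[-i]; iseqs <- iseqs[-i]
      }
      exons <- exons[-i]; eseqs <- eseqs[-i]
    } else if (ev$kind == "exon_gain") {
      j <- ev$index; mCur <- length(exons)
      exons <- append(exons, ev$exonId, after = j)
      eseqs <- append(eseqs, ev$exonSeq, after = j)
      iAt <- min(j + 1L, mCur)
      intr <- append(intr, ev$intronId, after = iAt - 1L)
      iseqs <- append(iseqs, ev$intronSeq, after = iAt - 1L)
    } else if (ev$kind == "exon_duplication") {
      t <- match(ev$templateId, exons)
      if (is.na(t)) stop("replay mismatch: template ", ev$templateId, " absent")
      exons <- append(exons, ev$exonId, after = t)
      eseqs <- append(eseqs, ev$exonSeq, after = t)
      intr <- append(intr, ev$intronId, after = t - 1L)
      iseqs <- append(iseqs, ev$intronSeq, after = t - 1L)
    } else stop("unknown structure event kind: ", ev$kind)
  }
  new("GeneStructure", nodeId = childNodeId, exonIds = exons,
      exonSeqs = eseqs, intronIds = intr, intronSeqs = iseqs)
}

setMethod("show", "GeneStructure", function(object) {
  m <- length(object@exonIds)
  cat(sprintf("GeneStructure at node '%s': %d exon(s), %d intron(s)\n",
              object@nodeId, m, m - 1L))
  cat(sprintf("  exon lengths (nt): %s\n",
              paste(nchar(object@exonSeqs), collapse = ", ")))
  invisible(NULL)
})

#' @describeIn simulateRootStructure full genomic sequence of a structure
#'   (exons and introns concatenated in order).
#' @param structure a [GeneStructure-class].
#' @export
geneSequence <- function(structure) {
  m <- length(structure@exonIds)
  parts <- character(2L * m - 1L)
  parts[seq(1L, 2L * m - 1L, by = 2L)] <- structure@exonSeqs
  if (m > 1) parts[seq(2L, 2L * m - 2L, by = 2L)] <- structure@intronSeqs
  paste(parts, collapse = "")
}
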