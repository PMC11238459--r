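# Assembly of a transcript's CDS from its node's structure: exon cores
# adjusted by effective 5'/3' offsets, plus retained introns trimmed at
# their 3' end to a multiple of 3. Offsets are re-clamped here because
# sequence evolution changes exon/intron lengths on later branches while
# offsets are inherited verbatim on conserved edges.

#' Segment decomposition of a transcript
#'
#' Returns the ordered genomic segments (unit id, 1-based start/end in the
#' unit's current sequence) whose concatenation is the transcript's CDS.
#' Positive boundary offsets extend into the flanking intron (suppressed
#' when that intron is retained, since retention already includes it);
#' negative offsets trim the exon core, clamped so it keeps >= 3 nt; all
#' effective lengths are multiples of 3.
#'
#' @param structure the [GeneStructure-class] of the transcript's node.
#' @param tx a transcript record.
#' @return data.frame with columns `unit`, `start`, `end`, `role`
#'   (`exon`, `ext5`, `ext3`, `retained`).
#' @export
transcriptSegments <- function(structure, tx) {
  exIds <- structure@exonIds
  sIdx <- match(tx$exons, exIds)
  if (any(is.na(sIdx)))
    stop("transcript references exons absent from its node's structure")
  m <- length(exIds)
  segs <- NULL
  addSeg <- function(unit, start, end, role)
    segs <<- rbind(segs, data.frame(unit = unit, start = start, end = end,
                                    role = role, stringsAsFactors = FALSE))
  for (j in seq_along(tx$exons)) {
    ex <- tx$exons[j]
    k <- sIdx[j]
    exonLen <- nchar(structure@exonSeqs[k])
    upI <- if (k > 1L) k - 1L else NA_integer_
    dnI <- if (k < m) k else NA_integer_
    off5 <- if (ex %in% names(tx$off5)) tx$off5[[ex]] else 0
    off3 <- if (ex %in% names(tx$off3)) tx$off3[[ex]] else 0
    upRetained <- !is.na(upI) && structure@intronIds[upI] %in% tx$retained &&
      j > 1L && sIdx[j - 1L] == k - 1L
    dnRetained <- !is.na(dnI) && structure@intronIds[dnI] %in% tx$retained &&
      j < length(sIdx) && sIdx[j + 1L] == k + 1L
    # effective extensions: clamp to the per-side cap of the current intron
    ext5 <- if (off5 > 0 && !is.na(upI) && !upRetained)
      min(off5, perSideExtensionCap(nchar(structure@intronSeqs[upI]))) else 0
    ext3 <- if (off3 > 0 && !is.na(dnI) && !dnRetained)
      min(off3, perSideExtensionCap(nchar(structure@intronSeqs[dnI]))) else 0
    # effective trims: keep >= 3 nt of exon core
    trim5 <- if (off5 < 0) min(-off5, exonLen - 3L) else 0
    trim3 <- if (off3 < 0) min(-off3, exonLen - 3L - trim5) else 0
    if (ext5 > 0) {
      iLen <- nchar(structure@intronSeqs[upI])
      addSeg(structure@intronIds[upI], iLen - ext5 + 1L, iLen, "ext5")
    }
    addSeg(ex, 1L + trim5, exonLen - trim3, "exon")
    if (ext3 > 0) addSeg(structure@intronIds[dnI], 1L, ext3, "ext3")
    if (dnRetained) {
      iLen <- nchar(structure@intronSeqs[dnI])
      keep <- (iLen %/% 3L) * 3L
      if (keep > 0) addSeg(structure@intronIds[dnI], 1L, keep, "retained")
    }
  }
  segs
}

#' Spliced CDS of a transcript
#'
#' @inheritParams transcriptSegments
#' @return the transcript's coding sequence (length a multiple of 3).
#' @export
transcriptCDS <- function(structure, tx) {
  segs <- transcriptSegments(structure, tx)
  unitSeq <- c(stats::setNames(structure@exonSeqs, structure@exonIds),
               stats::setNames(structure@intronSeqs, structure@intronIds))
  paste(vapply(seq_len(nrow(segs)), function(r)
    substr(unitSeq[[segs$unit[r]]], segs$start[r], segs$end[r]), ""),
    collapse = "")
}

#' Exon coordinate tables
#'
#' Coordinates of every exon on its gene sequence (introns included) and
#' of every transcript segment on its spliced CDS. All coordinates are
#' 0-based half-open.
#'
#' @param result a [SpliceSimResult-class].
#' @return `list(gene = data.frame(node, exon_id, start, end),
#'   transcript = data.frame(transcript_id, node, unit, role, start, end))`.
#' @export
exonCoordinates <- function(result) {
  gene <- NULL
  for (nd in names(result@structures)) {
    st <- result@structures[[nd]]
    m <- length(st@exonIds)
    lens <- integer(2L * m - 1L)
    lens[seq(1L, 2L * m - 1L, 2L)] <- nchar(st@exonSeqs)
    if (m > 1L) lens[seq(2L, 2L * m - 2L, 2L)] <- nchar(st@intronSeqs)
    starts <- cumsum(c(0L, lens))[seq(1L, 2L * m - 1L, 2L)]
    gene <- rbind(gene, data.frame(node = nd, exon_id = st@exonIds,
                                   start = starts,
                                   end = starts + nchar(st@exonSeqs),
                                   stringsAsFactors = FALSE))
  }
  txt <- NULL
  for (nd in names(result@transcripts)) {
    st <- result@structures[[nd]]
    for (tx in result@transcripts[[nd]]) {
      segs <- transcriptSegments(st, tx)
      lens <- segs$end - segs$start + 1L
      starts <- cumsum(c(0L, lens))[seq_len(nrow(segs))]
      txt <- rbind(txt, data.frame(transcript_id = tx$id, node = nd,
                                   unit = segs$unit, role = segs$role,
                                   start = starts, end = starts + lens,
                                   stringsAsFactors = FALSE))
    }
  }
  list(gene = gene, transcript = txt)
}
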