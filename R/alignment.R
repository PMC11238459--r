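# True multiple sequence alignment: every nucleotide position that ever
# existed during the simulation owns a global column; rows (gene or
# transcript sequences) place their characters in their columns and gap
# everything else, so homologous exon positions share columns across the
# whole tree and ungapping a row reproduces its sequence exactly.

globalColumnOrder <- function(maps) {
  unlist(maps$cols[maps$units], use.names = FALSE)
}

#' Build the true multiple sequence alignment
#'
#' Assembles the alignment implied by the simulation's event logs: each
#' row is a gene sequence (exons and introns of one node) or a transcript
#' CDS, threaded through the global column system in which every
#' substitution, indel, structural and AS event was recorded. Removing the
#' gaps of any row reproduces that row's sequence exactly, and homologous
#' exon positions are aligned across all rows.
#'
#' @param result a [SpliceSimResult-class].
#' @param what which rows to include: `"all"`, `"genes"`, `"transcripts"`.
#' @param nodes guide-tree node labels to include (default all nodes).
#' @param dropEmptyColumns drop columns that are gaps in every included
#'   row (useful for transcript-only alignments).
#' @return a [TrueAlignment-class]; row names are node labels (genes) and
#'   transcript ids.
#' @export
buildTrueAlignment <- function(result, what = c("all", "genes", "transcripts"),
                               nodes = names(result@structures),
                               dropEmptyColumns = FALSE) {
  what <- match.arg(what)
  maps <- result@maps
  ord <- globalColumnOrder(maps)
  ncol <- length(ord)
  colPos <- integer(max(ord))
  colPos[ord] <- seq_len(ncol)
  rows <- character(0)
  columns <- data.frame(column = ord,
                        unit = maps$colUnit[ord],
                        origin = maps$colOrigin[ord],
                        stringsAsFactors = FALSE)

  placeRow <- function(chars, cols, label) {
    if (length(chars) != length(cols))
      stop("integrity error: sequence/column map length mismatch for ", label)
    row <- rep("-", ncol)
    row[colPos[cols]] <- chars
    rows[[label]] <<- paste(row, collapse = "")
  }

  for (nd in nodes) {
    st <- result@structures[[nd]]
    map <- maps$nodeMaps[[nd]]
    if (what %in% c("all", "genes")) {
      m <- length(st@exonIds)
      units <- character(2L * m - 1L)
      units[seq(1L, 2L * m - 1L, 2L)] <- st@exonIds
      if (m > 1L) units[seq(2L, 2L * m - 2L, 2L)] <- st@intronIds
      chars <- unlist(strsplit(c(rbind(st@exonSeqs,
                                       c(st@intronSeqs, "")))[seq_len(2L * m - 1L)],
                               ""))
      cols <- unlist(map[units], use.names = FALSE)
      placeRow(chars, cols, nd)
    }
    if (what %in% c("all", "transcripts")) {
      for (tx in result@transcripts[[nd]]) {
        segs <- transcriptSegments(st, tx)
        unitSeq <- c(stats::setNames(st@exonSeqs, st@exonIds),
                     stats::setNames(st@intronSeqs, st@intronIds))
        chars <- unlist(lapply(seq_len(nrow(segs)), function(r)
          strsplit(substr(unitSeq[[segs$unit[r]]], segs$start[r],
                          segs$end[r]), "")[[1]]))
        cols <- unlist(lapply(seq_len(nrow(segs)), function(r)
          map[[segs$unit[r]]][segs$start[r]:segs$end[r]]))
        placeRow(chars, cols, tx$id)
      }
    }
  }

  if (dropEmptyColumns && length(rows)) {
    mat <- do.call(rbind, strsplit(unlist(rows), ""))
    keep <- colSums(mat != "-") > 0L
    rows <- stats::setNames(apply(mat[, keep, drop = FALSE], 1, paste,
                                  collapse = ""), names(rows))
    columns <- columns[keep, , drop = FALSE]
  }
  new("TrueAlignment", rows = unlist(rows), columns = columns)
}

#' Remove gaps from an alignment row
#'
#' @param row an aligned string over `A,C,G,T,-`.
#' @return the ungapped sequence.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)
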