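# Serialization of every simulation artifact: FASTA sequences and
# alignments (Biostrings), the transcript forest as multi-tree Newick with
# NHX edge tags, and TSV event/coordinate/group tables.

#' Write the transcript forest as Newick/NHX
#'
#' One tree per line; roots are transcript gains. Edge labels (`conserved`
#' or the AS event type) are encoded as NHX tags on the child node
#' (`[&&NHX:event=es]`), since plain Newick has no edge-label slot.
#'
#' @param forest a [TranscriptForest-class].
#' @param path output file (omit to return the lines).
#' @return invisibly, the Newick lines.
#' @export
writeTranscriptForest <- function(forest, path = NULL) {
  ed <- forest@edges
  kidsOf <- split(seq_len(nrow(ed)), ed$parent)
  sub <- function(id) {
    rows <- kidsOf[[id]]
    if (is.null(rows)) return(id)
    parts <- vapply(rows[order(ed$child[rows])], function(r)
      paste0(sub(ed$child[r]), "[&&NHX:event=", ed$label[r], "]"), "")
    paste0("(", paste(parts, collapse = ","), ")", id)
  }
  roots <- sort(setdiff(forest@nodes$id, ed$child))
  lines <- vapply(roots, function(r) paste0(sub(r), ";"), "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a transcript forest from Newick/NHX
#'
#' Re-parses the format written by [writeTranscriptForest()]. Gene labels
#' are recovered from the `gene#k` id convention.
#'
#' @param path file path, or `lines` a character vector of Newick strings.
#' @param lines alternative to `path`.
#' @return a [TranscriptForest-class] (loss markers are not part of the
#'   Newick serialization and come back empty).
#' @export
readTranscriptForest <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nodes <- character(0)
  edges <- data.frame(parent = character(0), child = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  for (ln in lines) {
    s <- strsplit(trimws(ln), "")[[1]]
    env <- new.env(parent = emptyenv()); env$i <- 1L
    peek <- function() if (env$i <= length(s)) s[env$i] else ""
    advance <- function() env$i <- env$i + 1L
    readName <- function() {
      out <- character(0)
      while (!(peek() %in% c("(", ")", ",", "[", ";", ""))) {
        out <- c(out, peek()); advance()
      }
      paste(out, collapse = "")
    }
    readTag <- function() {
      if (peek() != "[") return(NA_character_)
      tag <- character(0)
      while (peek() != "]") {
        if (peek() == "") stop("malformed NHX tag: unterminated '['")
        tag <- c(tag, peek()); advance()
      }
      advance()
      tag <- paste(tag, collapse = "")
      sub(":.*$", "", sub("^.*event=", "", tag))
    }
    parseNode <- function() {
      children <- list()
      if (peek() == "(") {
        advance()
        repeat {
          children[[length(children) + 1L]] <- parseNode()
          if (peek() == ",") { advance(); next }
          if (peek() == ")") { advance(); break }
          stop("malformed Newick forest line at position ", env$i)
        }
      }
      name <- readName()
      tag <- readTag()
      nodes <<- c(nodes, name)
      for (ch in children)
        edges <<- rbind(edges, data.frame(parent = name, child = ch$name,
                                          label = ch$tag,
                                          stringsAsFactors = FALSE))
      list(name = name, tag = tag)
    }
    parseNode()
    if (peek() != ";") stop("malformed Newick forest line: missing ';'")
  }
  genes <- sub("#.*$", "", nodes)
  new("TranscriptForest",
      nodes = data.frame(id = nodes, gene = genes, stringsAsFactors = FALSE),
      edges = edges,
      losses = data.frame(id = character(0), branch = character(0),
                          type = character(0), stringsAsFactors = FALSE))
}

writeTsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write all simulation outputs
#'
#' Emits, under `outdir`:
#' \describe{
#'   \item{genes_leaves.fasta}{genomic sequences (exons + introns) of the
#'     leaf genes}
#'   \item{transcripts.fasta}{CDS of every transcript at every node}
#'   \item{exon_coords_genes.tsv / exon_coords_transcripts.tsv}{0-based
#'     half-open exon (and transcript-segment) coordinates}
#'   \item{transcript_forest.nwk}{the transcript forest, one Newick/NHX
#'     tree per line}
#'   \item{alignment_all.fasta}{true alignment of all gene and transcript
#'     sequences}
#'   \item{alignment_transcripts.fasta}{true alignment of leaf transcripts
#'     only, all-gap columns removed}
#'   \item{events.tsv}{the complete event log}
#'   \item{ortholog_groups.tsv}{one group of orthologous transcripts per
#'     line, tab-separated}
#' }
#'
#' @param result a [SpliceSimResult-class].
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
writeSimulationOutputs <- function(result, outdir) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop("I/O error: cannot create output directory ", outdir)
  leaves <- leafLabels(result@guideTree)
  files <- character(0)
  emit <- function(name) { p <- file.path(outdir, name); files <<- c(files, p); p }

  gseqs <- vapply(leaves, function(nd) geneSequence(result@structures[[nd]]), "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gseqs),
                              emit("genes_leaves.fasta"))

  txSeqs <- character(0)
  for (nd in names(result@transcripts)) {
    st <- result@structures[[nd]]
    for (tx in result@transcripts[[nd]])
      txSeqs[tx$id] <- transcriptCDS(st, tx)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(txSeqs),
                              emit("transcripts.fasta"))

  co <- exonCoordinates(result)
  writeTsv(co$gene, emit("exon_coords_genes.tsv"),
           "exon coordinates on the gene sequence; 0-based, half-open")
  writeTsv(co$transcript, emit("exon_coords_transcripts.tsv"),
           "segment coordinates on the transcript CDS; 0-based, half-open")

  writeTranscriptForest(result@forest, emit("transcript_forest.nwk"))

  aln <- buildTrueAlignment(result, "all")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln@rows),
                              emit("alignment_all.fasta"))
  alnTx <- buildTrueAlignment(result, "transcripts", nodes = leaves,
                              dropEmptyColumns = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(alnTx@rows),
                              emit("alignment_transcripts.fasta"))

  ev <- result@events
  writeTsv(ev, emit("events.tsv"),
           "record of all simulated evolutionary events")

  groups <- orthologGroups(result@forest, leaves)
  con <- file(emit("ortholog_groups.tsv"), "w")
  writeLines(vapply(groups, paste, "", collapse = "\t"), con)
  close(con)

  invisible(files)
}
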