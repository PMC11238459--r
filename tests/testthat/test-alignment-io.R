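test_that("an exon-skipping transcript shows an all-gap block at that exon", {
  st <- fig1Structure()
  cfg <- smallConfig(tcRs = 0, tcEs = 0, tcMe = 0, tcA5 = 0, tcA3 = 0,
                     tcIr = 0, tcTl = 0,
                     structure = list(loss = 0, gain = 0, dup = 0))
  res <- simulateSpliceEvolution("(A:0.0);", cfg)
  root <- spliceforest:::rootLabel(res@guideTree)
  full <- transcriptSets(res)[[root]][[1]]
  stRoot <- geneStructures(res)[[root]]
  skipped <- applyASEvent(full, "es", stRoot, "manual#1")
  res@transcripts[[root]] <- c(res@transcripts[[root]], list(skipped))
  aln <- buildTrueAlignment(res, "transcripts", nodes = root)
  rowFull <- aln@rows[[full$id]]
  rowSkip <- aln@rows[["manual#1"]]
  gone <- setdiff(full$exons, skipped$exons)
  cols <- which(aln@columns$unit == gone)
  expect_true(all(substring(rowSkip, cols, cols) == "-"))
  expect_true(all(substring(rowFull, cols, cols) != "-"))
  expect_identical(ungap(rowSkip), transcriptCDS(stRoot, skipped))
})

test_that("all output files are written, consistent and re-readable", {
  cfg <- smallConfig(seed = 8)
  res <- simulateSpliceEvolution("((A:0.3,B:0.4):0.2,C:0.5);", cfg)
  outdir <- tempfile("simout")
  files <- writeSimulationOutputs(res, outdir)
  expect_true(all(file.exists(files)))

  # transcript FASTA: ids consistent, lengths multiples of 3
  txFa <- Biostrings::readDNAStringSet(file.path(outdir, "transcripts.fasta"))
  allIds <- unlist(lapply(transcriptSets(res), function(s)
    vapply(s, `[[`, "", "id")))
  expect_setequal(names(txFa), allIds)
  expect_true(all(Biostrings::width(txFa) %% 3 == 0))

  # alignment FASTA: equal widths, ungapping leaf genes gives the genome
  aln <- Biostrings::readDNAStringSet(file.path(outdir, "alignment_all.fasta"))
  expect_equal(length(unique(Biostrings::width(aln))), 1L)
  for (leaf in leafLabels(res@guideTree)) {
    expect_identical(gsub("-", "", as.character(aln[[leaf]])),
                     geneSequence(geneStructures(res)[[leaf]]))
  }

  # exon coordinates slice out of the gene FASTA
  genes <- Biostrings::readDNAStringSet(file.path(outdir, "genes_leaves.fasta"))
  co <- read.delim(file.path(outdir, "exon_coords_genes.tsv"), comment.char = "#")
  for (leaf in leafLabels(res@guideTree)) {
    st <- geneStructures(res)[[leaf]]
    rows <- co[co$node == leaf, ]
    expect_identical(rows$exon_id, st@exonIds)
    got <- substring(as.character(genes[[leaf]]), rows$start + 1, rows$end)
    expect_identical(got, unname(st@exonSeqs))
  }

  # transcript segment coordinates re-concatenate to the CDS
  # skip = 1: the header comment line (transcript ids themselves contain '#')
  cot <- read.delim(file.path(outdir, "exon_coords_transcripts.tsv"),
                    skip = 1)
  for (leaf in leafLabels(res@guideTree)) {
    st <- geneStructures(res)[[leaf]]
    for (tx in transcriptSets(res)[[leaf]]) {
      rows <- cot[cot$transcript_id == tx$id, ]
      cds <- as.character(txFa[[tx$id]])
      expect_equal(max(rows$end), nchar(cds))
      segs <- transcriptSegments(st, tx)
      unitSeq <- c(setNames(st@exonSeqs, st@exonIds),
                   setNames(st@intronSeqs, st@intronIds))
      rebuilt <- paste(vapply(seq_len(nrow(segs)), function(r)
        substr(unitSeq[[segs$unit[r]]], segs$start[r], segs$end[r]), ""),
        collapse = "")
      expect_identical(rebuilt, cds)
    }
  }

  # forest round trip from disk
  f2 <- readTranscriptForest(file.path(outdir, "transcript_forest.nwk"))
  expect_setequal(f2@nodes$id, res@forest@nodes$id)
  unlink(outdir, recursive = TRUE)
})

test_that("alignment integrity errors surface on inconsistent input", {
  cfg <- smallConfig(seed = 9)
  res <- simulateSpliceEvolution("(A:0.2);", cfg)
  root <- spliceforest:::rootLabel(res@guideTree)
  # corrupt one exon sequence: its column map no longer fits
  st <- res@structures[[root]]
  st@exonSeqs[1] <- paste0(st@exonSeqs[1], "AAA")
  res@structures[[root]] <- st
  expect_error(buildTrueAlignment(res, "genes"), "integrity")
})
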