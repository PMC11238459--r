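test_that("root structure respects the configured exon count", {
  for (m in c(1L, 4L)) {
    cfg <- smallConfig(structure = list(exonCountMean = m, exonCountSd = 0,
                                        exonLenMeanCodons = 8,
                                        exonLenSdCodons = 2,
                                        intronLenMean = 30, intronLenSd = 6))
    set.seed(10 + m)
    st <- simulateRootStructure(cfg)
    expect_equal(length(st@exonIds), m)
    expect_equal(length(st@intronIds), m - 1L)
    expect_true(all(nchar(st@exonSeqs) %% 3L == 0L))
  }
  cfg <- smallConfig()
  set.seed(77); a <- simulateRootStructure(cfg)
  set.seed(77); b <- simulateRootStructure(cfg)
  expect_identical(a@exonSeqs, b@exonSeqs)
  expect_identical(a@intronSeqs, b@intronSeqs)
})

test_that("a forced exon loss removes the exon and its flanking intron", {
  parent <- fig1Structure()
  child <- replayStructureEvents(parent, fig1LossEvents(), "Gene2")
  expect_identical(child@exonIds, c("e1", "e2", "e3"))
  expect_equal(length(child@intronIds), 2L)
  # interior loss merges the two flanking introns into one new unit
  child2 <- replayStructureEvents(
    parent, list(list(kind = "exon_loss", exonId = "e2", index = 2L,
                      merged = list(newId = "i99", leftId = "i1",
                                    rightId = "i2"))), "GeneX")
  expect_identical(child2@exonIds, c("e1", "e3", "e4"))
  expect_identical(child2@intronIds, c("i99", "i3"))
  expect_equal(nchar(child2@intronSeqs[1]), 60)
  expect_equal(substr(child2@intronSeqs[1], 1, 2), "GT")
  expect_equal(substring(child2@intronSeqs[1], 59), "AG")
})

test_that("zero-length branches leave the structure unchanged", {
  cfg <- smallConfig()
  set.seed(4)
  parent <- simulateRootStructure(cfg)
  out <- evolveStructure(parent, 0, cfg)
  expect_identical(out$structure@exonIds, parent@exonIds)
  expect_identical(out$structure@exonSeqs, parent@exonSeqs)
  expect_length(out$events, 0)
})

test_that("structure events replay to the evolved child over many seeds", {
  cfg <- smallConfig()
  for (seed in 1:100) {
    set.seed(seed)
    parent <- simulateRootStructure(cfg)
    out <- evolveStructure(parent, runif(1, 0.1, 1), cfg, "child")
    rep <- replayStructureEvents(parent, out$events, "child")
    expect_identical(rep@exonIds, out$structure@exonIds)
    expect_identical(rep@exonSeqs, out$structure@exonSeqs)
    expect_identical(rep@intronIds, out$structure@intronIds)
    expect_identical(rep@intronSeqs, out$structure@intronSeqs)
    expect_equal(length(out$structure@intronIds),
                 length(out$structure@exonIds) - 1L)
    # fresh ids only: no reuse of parent's ids for gained/duplicated exons
    gained <- vapply(Filter(function(e)
      e$kind %in% c("exon_gain", "exon_duplication"), out$events),
      `[[`, "", "exonId")
    expect_false(any(gained %in% parent@exonIds))
  }
})

test_that("the last exon can never be lost", {
  cfg <- smallConfig(structure = list(exonCountMean = 1, exonCountSd = 0,
                                      loss = 5, gain = 0, dup = 0, kSt = 1,
                                      exonLenMeanCodons = 8,
                                      exonLenSdCodons = 2,
                                      intronLenMean = 30, intronLenSd = 6))
  set.seed(21)
  parent <- simulateRootStructure(cfg)
  out <- evolveStructure(parent, 1, cfg)
  expect_equal(length(out$structure@exonIds), 1L)
  kinds <- vapply(out$events, `[[`, "", "kind")
  expect_true(all(kinds == "exon_loss_skipped"))
})

test_that("duplicated exons copy the template sequence and sit beside it", {
  cfg <- smallConfig(structure = list(loss = 0, gain = 0, dup = 0.3, kSt = 1,
                                      exonCountMean = 3, exonCountSd = 0,
                                      exonLenMeanCodons = 8,
                                      exonLenSdCodons = 2,
                                      intronLenMean = 30, intronLenSd = 6))
  set.seed(31)
  parent <- simulateRootStructure(cfg)
  out <- evolveStructure(parent, 1, cfg)
  dups <- Filter(function(e) e$kind == "exon_duplication", out$events)
  expect_gte(length(dups), 1L)
  ev <- dups[[1]]
  st <- out$structure
  tIdx <- match(ev$templateId, st@exonIds)
  cIdx <- match(ev$exonId, st@exonIds)
  expect_equal(cIdx, tIdx + 1L)
  expect_identical(ev$exonSeq,
                   parent@exonSeqs[match(ev$templateId, parent@exonIds)])
})
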