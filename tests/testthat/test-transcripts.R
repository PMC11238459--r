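test_that("isoform pool size is 2^m - 1", {
  expect_equal(isoformPoolSize(1), 1)
  # brute-force enumeration oracle
  for (m in c(3, 10)) {
    ids <- paste0("e", seq_len(m))
    count <- sum(vapply(seq_len(2^m - 1), function(b)
      any(bitwAnd(b, 2^(seq_len(m) - 1)) > 0), TRUE))
    expect_equal(isoformPoolSize(m), count)
  }
  expect_error(isoformPoolSize(0), "domain")
})

test_that("root transcript count draws have the documented mean and sd", {
  set.seed(42)
  raw <- sampleRootTranscriptCount(20000, raw = TRUE)
  expect_lt(abs(mean(raw) - 1.45), 0.03)
  expect_lt(abs(sd(raw) - 1.08), 0.03)
  set.seed(42)
  n <- sampleRootTranscriptCount(20000)
  expect_true(all(n >= 1L))
  expect_true(is.integer(n))
})

test_that("the isoform sampler is uniform over the pool (chi-square oracle)", {
  st <- fig1ChildStructure()  # m = 3, pool of 7
  set.seed(9)
  draws <- replicate(7000, {
    ex <- spliceforest:::sampleIsoforms(st, 1)[[1]]
    paste(ex, collapse = "+")
  })
  tab <- table(draws)
  expect_equal(length(tab), 7L)
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
})

test_that("a null tc_rs selects the single all-exon transcript at the root", {
  st <- fig1Structure()
  cfg <- smallConfig(tcRs = 0, tcEs = 0, tcMe = 0, tcA5 = 0, tcA3 = 0,
                     tcIr = 0)
  set.seed(1)
  out <- simulateRootTranscripts(st, cfg)
  expect_length(out$transcripts, 1L)
  expect_identical(out$transcripts[[1]]$exons, st@exonIds)
  expect_equal(nrow(out$edges), 0L)
})

test_that("one root es stage on 2 sources yields 3 source transcripts", {
  st <- fig1Structure()
  sources <- fig1Transcripts()[1:2]
  budget <- rootEventBudget(length(sources), 0.3)
  expect_identical(budget, 1L)
  set.seed(3)
  stage <- runEvolutionaryStage(sources, "es", budget, st, "Gene1")
  expect_length(stage$sources, 3L)
  expect_equal(stage$nApplied, 1L)
  expect_equal(nrow(stage$records), 1L)
  # sink linked to exactly one source
  expect_true(stage$records$source_id %in% c("Gene1#1", "Gene1#2"))
})

test_that("es removes one exon and is inapplicable on single-exon input", {
  st <- fig1Structure()
  tx <- makeTranscript("Gene1#2", "Gene1", paste0("e", 1:4))
  set.seed(5)
  out <- applyASEvent(tx, "es", st, "Gene1#3")
  expect_length(out$exons, 3L)
  expect_true(all(out$exons %in% tx$exons))
  expect_identical(out$source, "Gene1#2")
  single <- makeTranscript("t", "Gene1", "e1")
  expect_error(applyASEvent(single, "es", st),
               class = "spliceforestInapplicable")
})

test_that("me swaps a present exon for an absent one in structure order", {
  st <- fig1Structure()
  tx <- makeTranscript("t", "Gene1", c("e1", "e2", "e3"))
  set.seed(6)
  out <- applyASEvent(tx, "me", st, "t2")
  expect_length(out$exons, 3L)
  expect_true("e4" %in% out$exons)
  idx <- match(out$exons, st@exonIds)
  expect_true(all(diff(idx) > 0))
  full <- makeTranscript("t", "Gene1", paste0("e", 1:4))
  expect_error(applyASEvent(full, "me", st),
               class = "spliceforestInapplicable")
})

test_that("a5/a3 offsets are nonzero multiples of 3 within clamp bounds", {
  st <- fig1Structure()
  tx <- makeTranscript("t", "Gene1", c("e1", "e2", "e3"))
  for (seed in 1:30) {
    set.seed(seed)
    kind <- sample(c("a5", "a3"), 1)
    out <- applyASEvent(tx, kind, st, "t2")
    off <- c(out$off5, out$off3)
    off <- off[off != 0]
    expect_length(off, 1L)
    expect_equal(off[[1]] %% 3, 0)
    expect_identical(out$exons, tx$exons)
    # assembled CDS stays in frame and differs from the source
    expect_equal(nchar(transcriptCDS(st, out)) %% 3L, 0L)
    expect_false(identical(transcriptCDS(st, out), transcriptCDS(st, tx)))
  }
})

test_that("ir retains an intron between consecutive exons, in frame", {
  st <- fig1Structure()
  tx <- makeTranscript("t", "Gene1", c("e1", "e2", "e4"))
  set.seed(8)
  out <- applyASEvent(tx, "ir", st, "t2")
  expect_length(out$retained, 1L)
  # only the e1-e2 junction is structure-consecutive
  expect_identical(out$retained, "i1")
  cds <- transcriptCDS(st, out)
  expect_equal(nchar(cds) %% 3L, 0L)
  expect_gt(nchar(cds), nchar(transcriptCDS(st, tx)))
  # all junctions retained -> inapplicable
  expect_error(applyASEvent(out, "ir", st),
               class = "spliceforestInapplicable")
})

test_that("chains of AS events replay as exactly those modifications", {
  st <- fig1Structure()
  base <- makeTranscript("t0", "Gene1", paste0("e", 1:4))
  totalHops <- 0L
  for (seed in 1:8) {
    set.seed(seed)
    cur <- base
    for (k in 1:4) {
      kind <- sample(c("es", "me", "a5", "a3", "ir"), 1)
      nxt <- tryCatch(applyASEvent(cur, kind, st, paste0("s", seed, "t", k)),
                      spliceforestInapplicable = function(e) NULL)
      if (is.null(nxt)) next
      expect_identical(nxt$source, cur$id)
      expect_false(identical(spliceforest:::txSignature(nxt),
                             spliceforest:::txSignature(cur)))
      totalHops <- totalHops + 1L
      cur <- nxt
    }
  }
  expect_gte(totalHops, 8L)
})
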