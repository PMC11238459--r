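test_that("losing exon4 loses exactly the five transcripts that carry it", {
  cfg <- smallConfig(tcTl = 0, tcRs = 0, tcEs = 0, tcMe = 0, tcA5 = 0,
                     tcA3 = 0, tcIr = 0)
  set.seed(1)
  out <- propagateTranscripts(fig1Transcripts(), fig1Structure(),
                              fig1ChildStructure("Gene2"), fig1LossEvents(),
                              1, cfg, "Gene2")
  structural <- out$losses[out$losses$type == "structural_loss", ]
  expect_equal(nrow(structural), 5L)
  expect_setequal(structural$id, paste0("Gene1#", 2:6))
  conservedEdges <- out$edges[out$edges$label == "conserved", ]
  expect_equal(nrow(conservedEdges), 2L)
  expect_setequal(conservedEdges$parent, c("Gene1#1", "Gene1#7"))
  expect_length(out$transcripts, 2L)
  # conserved children keep exon composition
  comps <- lapply(out$transcripts, `[[`, "exons")
  expect_setequal(vapply(comps, paste, "", collapse = "+"),
                  c("e1+e2+e3", "e2+e3"))
})

test_that("regulated loss removes a conserved transcript with a tl record", {
  cfg <- smallConfig(tcTl = 0.3, tcRs = 0, tcEs = 0, tcMe = 0, tcA5 = 0,
                     tcA3 = 0, tcIr = 0, kTc = 1)
  set.seed(2)
  out <- propagateTranscripts(fig1Transcripts(), fig1Structure(),
                              fig1ChildStructure("Gene2"), fig1LossEvents(),
                              1, cfg, "Gene2")
  tl <- out$losses[out$losses$type == "tl", ]
  # budget = ceil(1 * 1 * 2 * 0.3) = 1 of the two conserved transcripts
  expect_equal(nrow(tl), 1L)
  expect_true(tl$id %in% c("Gene1#1", "Gene1#7"))
  expect_length(out$transcripts, 1L)
})

test_that("gains are drawn from the child pool and become forest roots", {
  cfg <- smallConfig(tcTl = 0, tcRs = 1, tcEs = 0, tcMe = 0, tcA5 = 0,
                     tcA3 = 0, tcIr = 0, kTc = 1)
  set.seed(3)
  out <- propagateTranscripts(fig1Transcripts()[1], fig1Structure(),
                              fig1ChildStructure("Gene2"), fig1LossEvents(),
                              1, cfg, "Gene2")
  # budget = ceil(1 * 1 * 1 * 1) = 1 gain
  gained <- Filter(function(tx) tx$origin == "rs", out$transcripts)
  expect_length(gained, 1L)
  expect_false(gained[[1]]$id %in% out$edges$child)
  expect_true(all(gained[[1]]$exons %in% fig1ChildStructure()@exonIds))
  # gains never duplicate an isoform already present
  expect_false(spliceforest:::txSignature(gained[[1]]) %in%
                 vapply(fig1Transcripts()[1], spliceforest:::txSignature, ""))
})

test_that("branch es example: 3 sources at tc_es = 0.2 give one es event", {
  cfg <- smallConfig(tcTl = 0, tcRs = 0.5, tcEs = 0.2, tcMe = 0, tcA5 = 0,
                     tcA3 = 0, tcIr = 0, kTc = 1)
  set.seed(2)
  out <- propagateTranscripts(fig1Transcripts()[c(1, 7)], fig1Structure(),
                              fig1ChildStructure("Gene2"), fig1LossEvents(),
                              1, cfg, "Gene2")
  st <- out$stages
  # after 2 conserved + ceil(2*0.5)=1 gain, the es stage sees n = 3 and a
  # budget of ceil(1 * 1 * 3 * 0.2) = 1
  esRow <- st[st$type == "es", ]
  expect_equal(esRow$n_source, 3L)
  expect_equal(esRow$budget, 1L)
  expect_equal(esRow$n_applied, 1L)
})

test_that("sink in-degree stays <= 1 through stages and finalization", {
  cfg <- smallConfig(seed = 1)
  set.seed(13)
  parent <- simulateRootStructure(cfg, "P")
  rootTx <- simulateRootTranscripts(parent, cfg)$transcripts
  evo <- evolveStructure(parent, 0.5, cfg, "C")
  out <- propagateTranscripts(rootTx, parent, evo$structure, evo$events,
                              0.5, cfg, "C")
  expect_equal(anyDuplicated(out$edges$child), 0L)
  # every non-gain child transcript traces to exactly one parent edge
  for (tx in out$transcripts) {
    incoming <- sum(out$edges$child == tx$id)
    expect_equal(incoming, if (tx$origin == "rs") 0L else 1L)
  }
})
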