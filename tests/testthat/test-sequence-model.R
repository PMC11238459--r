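test_that("exon generation honours length, frame and the no-stop rule", {
  set.seed(1)
  for (len in c(6L, 30L, 300L)) {
    s <- generateExonSequence(len)
    expect_equal(nchar(s), len)
    expect_true(all(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T")))
    codons <- substring(s, seq(1, len, 3), seq(3, len, 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(generateExonSequence(10), "multiple of 3")
})

test_that("a degenerate chain is generated deterministically", {
  probs <- matrix(0, 16, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[, "A"] <- 1
  rownames(probs) <- sort(apply(expand.grid(c("A","C","G","T"),
                                            c("A","C","G","T"))[, 2:1], 1,
                                paste, collapse = ""))
  chain <- markovChainParams(probs, 2L)
  set.seed(5)
  expect_identical(generateExonSequence(3, chain), "AAA")
})

test_that("generated dinucleotide frequencies match the stationary law", {
  # eigen-analysis oracle: stationary distribution of the order-2 chain,
  # compared with empirical overlapping-dinucleotide frequencies
  chain <- defaultMarkovParams("intron")
  pi0 <- stationaryDistribution(chain)
  expect_equal(sum(pi0), 1, tolerance = 1e-9)
  set.seed(7)
  s <- generateIntronSequence(3004)
  body <- substr(s, 3, 3002)  # interior, free of the GT/AG constraint
  din <- substring(body, 1:(nchar(body) - 1), 2:nchar(body))
  N <- length(din)
  for (ctx in names(pi0)) {
    p <- pi0[[ctx]]
    sigma <- sqrt(p * (1 - p) / N)
    expect_lt(abs(mean(din == ctx) - p), 3 * sigma + 0.01)
  }
})

test_that("intron generation keeps canonical GT...AG ends", {
  expect_identical(generateIntronSequence(4), "GTAG")
  set.seed(2)
  s <- generateIntronSequence(10)
  expect_equal(nchar(s), 10)
  expect_equal(substr(s, 1, 2), "GT")
  expect_equal(substring(s, 9), "AG")
  set.seed(11); a <- generateIntronSequence(100)
  set.seed(11); b <- generateIntronSequence(100)
  expect_identical(a, b)
  expect_error(generateIntronSequence(3), "domain")
})

test_that("Markov parameter files round-trip", {
  chain <- defaultMarkovParams("exon")
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writeMarkovParams(chain, path)
  back <- readMarkovParams(path)
  expect_equal(back$probs, chain$probs, tolerance = 1e-12)
  expect_equal(back$order, 2L)
})

test_that("zero-length branch leaves sequences untouched with empty logs", {
  cfg <- smallConfig()
  set.seed(3)
  ex <- generateExonSequence(60)
  intr <- generateIntronSequence(50)
  re <- evolveExonSequence(ex, 0, cfg)
  ri <- evolveIntronSequence(intr, 0, cfg)
  expect_identical(re$seq, ex)
  expect_identical(ri$seq, intr)
  expect_length(re$log, 0)
  expect_length(ri$log, 0)
  # no mutable interior: GTAG can only map to itself
  rg <- evolveIntronSequence("GTAG", 2.0, cfg)
  expect_identical(rg$seq, "GTAG")
})

test_that("sequence logs replay exactly and preserve the invariants", {
  cfg <- smallConfig()
  for (seed in 1:40) {
    set.seed(seed)
    ex <- generateExonSequence(3L * sample(5:40, 1))
    re <- evolveExonSequence(ex, runif(1, 0.1, 1.5), cfg)
    expect_identical(replaySequenceLog(ex, re$log), re$seq)
    expect_equal(nchar(re$seq) %% 3L, 0L)
    codons <- substring(re$seq, seq(1, nchar(re$seq), 3),
                        seq(3, nchar(re$seq), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
    for (ev in re$log)
      if (ev$kind != "substitution") expect_equal(nchar(ev$seq) %% 3L, 0L)

    intr <- generateIntronSequence(sample(10:120, 1))
    ri <- evolveIntronSequence(intr, runif(1, 0.1, 1.5), cfg)
    expect_identical(replaySequenceLog(intr, ri$log), ri$seq)
    expect_equal(substr(ri$seq, 1, 2), "GT")
    expect_equal(substring(ri$seq, nchar(ri$seq) - 1), "AG")
  }
})

test_that("exon substitution counts follow the Poisson expectation", {
  cfg <- smallConfig()
  set.seed(123)
  ex <- generateExonSequence(999)
  lambda <- cfg@sequence$exSubRate * 0.5 * 999
  nSeeds <- 300
  counts <- vapply(seq_len(nSeeds), function(s) {
    set.seed(s)
    sum(vapply(evolveExonSequence(ex, 0.5, cfg)$log,
               function(e) e$kind == "substitution", TRUE))
  }, 0)
  sigma <- sqrt(lambda / nSeeds)
  expect_lt(abs(mean(counts) - lambda), 3 * sigma)
})
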