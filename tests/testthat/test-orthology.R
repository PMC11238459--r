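leafG <- c("Gene2", "Gene3")

test_that("the worked scenario yields the single ortholog group {2#1, 3#1}", {
  fo <- fig1Forest()
  groups <- orthologGroups(fo, leafG)
  expect_length(groups, 1L)
  expect_setequal(groups[[1]], c("Gene2#1", "Gene3#1"))
})

test_that("orthology is symmetric, cross-gene and conserved-path-only", {
  fo <- fig1Forest()
  expect_true(areOrthologs("Gene2#1", "Gene3#1", fo, leafG))
  expect_true(areOrthologs("Gene3#1", "Gene2#1", fo, leafG))
  # same gene: never orthologs
  expect_false(areOrthologs("Gene1#4", "Gene1#5", fo, leafG))
  # an AS edge on the path breaks orthology
  expect_false(areOrthologs("Gene2#1", "Gene3#2", fo, leafG))
  # different forest trees: no connecting path
  expect_false(areOrthologs("Gene2#0", "Gene3#1", fo, leafG))
  # ancestral transcripts are not part of extant orthology
  expect_false(areOrthologs("Gene1#1", "Gene2#1", fo, leafG))
  expect_error(areOrthologs("nope#1", "Gene2#1", fo, leafG), "unknown")
})

test_that("a forest whose edges all carry AS labels has no groups", {
  fo <- fig1Forest()
  fo@edges$label[fo@edges$label == "conserved"] <- "es"
  expect_length(orthologGroups(fo, leafG), 0L)
})

test_that("groups match a brute-force pairwise-orthology enumeration", {
  set.seed(20)
  for (rep in 1:5) {
    cfg <- smallConfig(seed = rep)
    res <- simulateSpliceEvolution(parseGuideTree(randomTreeText(3)), cfg)
    fo <- transcriptForest(res)
    lg <- leafLabels(res@guideTree)
    groups <- orthologGroups(fo, lg)
    leaves <- fo@nodes$id[fo@nodes$gene %in% lg]
    # oracle: pairwise orthology from scratch, maximal groups = components
    pairs <- outer(leaves, leaves, Vectorize(function(a, b)
      a != b && areOrthologs(a, b, fo, lg)))
    oracle <- list()
    seen <- character(0)
    for (i in seq_along(leaves)) {
      if (leaves[i] %in% seen) next
      grp <- leaves[c(i, which(pairs[i, ]))]
      grp <- grp[vapply(grp, function(x) all(
        vapply(setdiff(grp, x), function(y)
          pairs[match(x, leaves), match(y, leaves)], TRUE)), TRUE)]
      if (length(grp) >= 2) {
        oracle[[length(oracle) + 1L]] <- sort(grp)
        seen <- c(seen, grp)
      }
    }
    expect_setequal(vapply(groups, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("clusterings partition the leaf transcripts", {
  cfg <- smallConfig(seed = 5)
  res <- simulateSpliceEvolution(parseGuideTree("((A:0.2,B:0.3):0.2,C:0.4);"),
                                 cfg)
  lg <- leafLabels(res@guideTree)
  leafIds <- unlist(lapply(lg, function(nd)
    vapply(transcriptSets(res)[[nd]], `[[`, "", "id")))
  phylo <- clusterByPhylogeny(transcriptForest(res), lg)
  comp <- clusterByExonComposition(res, lg)
  expect_setequal(unlist(phylo), leafIds)
  expect_setequal(unlist(comp), leafIds)
  expect_equal(anyDuplicated(unlist(phylo)), 0L)
  expect_equal(anyDuplicated(unlist(comp)), 0L)
})

test_that("conservation ratio arithmetic and domain errors", {
  cl5 <- split(paste0("t", 1:5), 1:5)
  expect_equal(conservationRatio(cl5), 1.0)
  expect_equal(conservationRatio(list(paste0("t", 1:4))), 0.25)
  expect_error(conservationRatio(list(), character(0)), "domain")
  expect_error(conservationRatio(list(c("a", "b")), c("a", "c")), "partition")
})
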