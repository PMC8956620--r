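test_that("identical configs give byte-identical datasets", {
  s1 <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 12))
  s2 <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 12))
  expect_identical(SummarizedExperiment::assay(s1$sce, "counts"),
                   SummarizedExperiment::assay(s2$sce, "counts"))
  expect_identical(SingleCellExperiment::reducedDim(s1$sce, "EMBED"),
                   SingleCellExperiment::reducedDim(s2$sce, "EMBED"))
  s3 <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 13))
  expect_false(identical(SummarizedExperiment::assay(s1$sce, "counts"),
                         SummarizedExperiment::assay(s3$sce, "counts")))
})

test_that("infeasible planted probabilities fail config validation", {
  groups <- data.frame(group = "A", nNormal = 50, nDisease = 50,
                       cx = 0, cy = 0, ax = 1, ay = 0, spread = 1)
  det <- data.frame(gene = "L1", group = "A", condition = "Normal",
                    prob = 0.21)  # inside the (0.15, 0.25) margin band
  expect_error(simConfig(1, groups, det, pairs = LRPairList("L1", "R1")),
               "margin")
  expect_error(presetConfig("nonsense"), "arg")
})

test_that("zero planted edges with low background give empty networks", {
  groups <- data.frame(group = c("A", "B"), nNormal = 200, nDisease = 200,
                       cx = c(0, 10), cy = 0, ax = 1, ay = 0, spread = 1)
  cfg <- simConfig(5, groups, pairs = LRPairList("BG001", "BG002"),
                   nBackground = 10L, background = 0.01)
  sim <- generateDataset(cfg)
  prof <- expressedFraction(sim$sce)
  calls <- callsByCondition(prof, 0.20)
  for (cond in c("Normal", "Disease"))
    expect_equal(nrow(commEdges(buildNetwork(calls[[cond]], sim$pairs,
                                             cond))), 0L)
})

test_that("planted fibroblast-to-lymphocyte motif is recovered from
           sampled counts", {
  sim <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 8))
  prof <- expressedFraction(sim$sce)
  calls <- callsByCondition(prof, 0.20)
  d <- diffNetworks(buildNetwork(calls$Normal, sim$pairs, "Normal"),
                    buildNetwork(calls$Disease, sim$pairs, "Disease"))
  bp <- as.data.frame(byPairCounts(d))
  row <- bp[bp$broadcaster == "Fibroblast" & bp$receiver == "Lymphocyte", ]
  expect_equal(row$n_normal, 1L)
  expect_equal(row$n_disease, 13L)
  expect_equal(row$n_gained, 12L)
  # ITGB1 arrives with its ten cognate matrix ligands
  g <- as.data.frame(gainedEdges(d))
  expect_equal(sum(g$receptor == "ITGB1"), 10L)
  expect_setequal(g$receptor, c("ITGB1", "CD36"))
})

test_that("ground truth matches the recovered networks edge for edge", {
  sim <- generateDataset(presetConfig("itgb1_gain", seed = 4))
  prof <- expressedFraction(sim$sce)
  calls <- callsByCondition(prof, 0.20)
  for (cond in c("Normal", "Disease")) {
    got <- as.data.frame(commEdges(buildNetwork(calls[[cond]], sim$pairs,
                                                cond)))
    want <- as.data.frame(commEdges(
      if (cond == "Normal") sim$truth$netNormal else sim$truth$netDisease))
    expect_identical(got, want)
  }
})

test_that("spatial labels separate gradient from null genes", {
  sim <- generateDataset(presetConfig("spatial_sarcomere", seed = 2))
  lab <- as.data.frame(sim$truth$spatialLabels)
  expect_setequal(lab$label[lab$gene %in% c("ACTA1", "MYH7")], "gradient")
  expect_true(all(lab$label[grepl("^NULL", lab$gene)] == "null"))
})

test_that("a simulated dataset round-trips through the standard files", {
  sim <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 3,
                                      cellsPerGroup = 40L))
  d <- withr::local_tempdir()
  writeDataset(sim, d)
  sce <- readMatrix10x(file.path(d, "matrix.mtx"),
                       file.path(d, "features.tsv"),
                       file.path(d, "barcodes.tsv"))
  sce <- attachCellMeta(sce, readCellTable(file.path(d, "cells.tsv")))
  expect_identical(
    as.matrix(SummarizedExperiment::assay(sce, "counts")),
    as.matrix(SummarizedExperiment::assay(sim$sce, "counts")))
  lr <- suppressMessages(readLRPairs(file.path(d, "lr_pairs.csv")))
  expect_identical(as.data.frame(lr), as.data.frame(sim$pairs))
})
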