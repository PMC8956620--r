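test_that("single-pair, loop and missing-gene edge semantics", {
  calls <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2,
                  dimnames = list(c("COL1A1", "ITGB1"), c("F", "L")))
  net <- buildNetwork(calls, LRPairList("COL1A1", "ITGB1"), "Normal")
  C <- pairCounts(net)
  expect_equal(unname(C["F", "L"]), 1L)
  expect_equal(sum(C), 1L)

  # receptor in both groups, ligand in F -> F->L and the F->F loop
  calls2 <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2,
                   dimnames = list(c("COL1A1", "ITGB1"), c("F", "L")))
  net2 <- buildNetwork(calls2, LRPairList("COL1A1", "ITGB1"), "Normal")
  C2 <- pairCounts(net2)
  expect_equal(unname(C2["F", "F"]), 1L)
  expect_equal(unname(C2["F", "L"]), 1L)

  # ligand gene absent from the matrix contributes nothing
  expect_message(
    net3 <- buildNetwork(calls2, LRPairList(c("COL1A1", "GHOST"),
                                            c("ITGB1", "ITGB1")),
                         "Normal"),
    "absent")
  expect_equal(nrow(commEdges(net3)), 2L)
  expect_error(buildNetwork(calls2, LRPairList("A", "B"), "N",
                            groups = character()), "nonempty")
})

test_that("build_network matches the exhaustive triple-loop oracle", {
  set.seed(11)
  for (rep in 1:60) {
    inst <- randomNetInstance()
    net <- buildNetwork(inst$calls, LRPairList(inst$lig, inst$rec), "X")
    got <- as.data.frame(commEdges(net))
    want <- bruteNetwork(inst$calls, inst$lig, inst$rec)
    expect_identical(got, want)
    # conservation: sum of C equals edge count
    expect_equal(sum(pairCounts(net)), nrow(got))
  }
})

test_that("relabeling groups permutes the pair-count matrix", {
  set.seed(3)
  inst <- randomNetInstance(maxGroups = 4)
  lr <- LRPairList(inst$lig, inst$rec)
  C1 <- pairCounts(buildNetwork(inst$calls, lr, "X"))
  perm <- sample(ncol(inst$calls))
  calls2 <- inst$calls[, perm, drop = FALSE]
  C2 <- pairCounts(buildNetwork(calls2, lr, "X"))
  expect_identical(C2, C1[colnames(calls2), colnames(calls2)])
})

test_that("pathway enumeration counts ordered pairs with loops", {
  expect_equal(countPathways("A", "A"), 1L)
  expect_equal(countPathways(paste0("T", 1:10), paste0("T", 1:10)), 100L)
  expect_error(countPathways(character(), "A"), "nonempty")
})

test_that("differential report identities and special cases", {
  calls <- matrix(TRUE, 2, 1, dimnames = list(c("L1", "R1"), "A"))
  lr <- LRPairList("L1", "R1")
  net <- buildNetwork(calls, lr, "Normal")
  netSame <- buildNetwork(calls, lr, "Disease")
  d <- diffNetworks(net, netSame)
  expect_equal(nrow(gainedEdges(d)), 0L)
  expect_equal(nrow(lostEdges(d)), 0L)
  expect_equal(unname(commTotals(d)[1]), unname(commTotals(d)[2]))

  # disjoint sets: 3 lost, 4 gained, none persisted
  genes <- c(paste0("L", 1:7), paste0("R", 1:7))
  lr7 <- LRPairList(paste0("L", 1:7), paste0("R", 1:7))
  cN <- matrix(FALSE, 14, 1, dimnames = list(genes, "A"))
  cD <- cN
  cN[c(paste0("L", 1:3), paste0("R", 1:3)), 1] <- TRUE
  cD[c(paste0("L", 4:7), paste0("R", 4:7)), 1] <- TRUE
  d2 <- diffNetworks(buildNetwork(cN, lr7, "Normal"),
                     buildNetwork(cD, lr7, "Disease"))
  bp <- as.data.frame(byPairCounts(d2))
  expect_equal(bp$n_gained, 4L)
  expect_equal(bp$n_lost, 3L)
  expect_equal(bp$n_persisted, 0L)
  expect_true(is.na(bp$fold_change) == FALSE)  # 4/3 both positive
  expect_equal(bp$fold_change, 4 / 3)

  # node-set mismatch errors
  cB <- matrix(TRUE, 2, 1, dimnames = list(c("L1", "R1"), "B"))
  expect_error(diffNetworks(net, buildNetwork(cB, lr, "Disease")),
               "node set")
})

test_that("diff identities hold on random synthetic network pairs", {
  set.seed(21)
  for (rep in 1:40) {
    inst <- randomNetInstance()
    lr <- LRPairList(inst$lig, inst$rec)
    callsD <- inst$calls
    flip <- matrix(stats::runif(length(callsD)) < 0.25, nrow(callsD))
    callsD[flip] <- !callsD[flip]
    d <- diffNetworks(buildNetwork(inst$calls, lr, "Normal"),
                      buildNetwork(callsD, lr, "Disease"))
    bp <- as.data.frame(byPairCounts(d))
    expect_true(all(bp$n_gained + bp$n_persisted == bp$n_disease))
    expect_true(all(bp$n_lost + bp$n_persisted == bp$n_normal))
    expect_equal(sum(bp$n_normal), unname(commTotals(d)[1]))
    expect_equal(sum(bp$n_disease), unname(commTotals(d)[2]))
  }
})

test_that("zeroed ligands are control-expressed ligands lost in disease", {
  genes <- c("L1", "L2", "R1")
  lr <- LRPairList(c("L1", "L2"), c("R1", "R1"))
  cN <- matrix(c(TRUE, TRUE, TRUE), 3, 1, dimnames = list(genes, "A"))
  cD <- matrix(c(FALSE, TRUE, TRUE), 3, 1, dimnames = list(genes, "A"))
  d <- diffNetworks(buildNetwork(cN, lr, "Normal"),
                    buildNetwork(cD, lr, "Disease"))
  zl <- as.data.frame(zeroedLigands(d))
  expect_identical(zl$ligand, "L1")
  expect_identical(zl$group, "A")
})

test_that("threshold monotonicity: higher threshold never adds edges", {
  set.seed(5)
  nExpr <- matrix(sample(0:200, 12 * 4, replace = TRUE), 12, 4,
                  dimnames = list(sprintf("g%02d", 1:12),
                                  paste0(LETTERS[1:4], "|N")))
  prof <- profileFrom(nExpr, rep(200L, 4), LETTERS[1:4], rep("N", 4))
  lr <- LRPairList(sprintf("g%02d", 1:6), sprintf("g%02d", 7:12))
  edKey <- function(t) {
    calls <- expressedCall(prof, t)
    colnames(calls) <- LETTERS[1:4]
    ed <- as.data.frame(commEdges(buildNetwork(calls, lr, "X")))
    paste(ed$broadcaster, ed$receiver, ed$ligand, ed$receptor)
  }
  for (pair in list(c(0.05, 0.2), c(0.2, 0.4), c(0.4, 0.8)))
    expect_true(all(edKey(pair[2]) %in% edKey(pair[1])))
})

test_that("broadcast summary counts distinct and with-multiplicity", {
  calls <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE), 3,
                  dimnames = list(c("COL1A1", "FN1", "ITGB1"),
                                  c("F", "L")))
  lr <- LRPairList(c("COL1A1", "FN1"), c("ITGB1", "ITGB1"))
  s <- ligandBroadcastSummary(buildNetwork(calls, lr, "N"))
  expect_equal(s$ligands_distinct[s$group == "F"], 2L)
  expect_equal(s$receptors_distinct[s$group == "L"], 1L)
  expect_equal(s$receptors_total[s$group == "L"], 2L)

  # same ligand broadcast to 3 receivers: 1 distinct, 3 edge slots
  calls3 <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE), 2,
                   dimnames = list(c("LG", "RC"), c("A", "B", "C")))
  s3 <- ligandBroadcastSummary(buildNetwork(calls3, LRPairList("LG", "RC"),
                                            "N"))
  expect_equal(s3$ligands_distinct[s3$group == "A"], 1L)
  expect_equal(s3$ligands_total[s3$group == "A"], 3L)

  sEmpty <- ligandBroadcastSummary(
    buildNetwork(calls3 & FALSE, LRPairList("LG", "RC"), "N"))
  expect_true(all(sEmpty[, -1] == 0))
})
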