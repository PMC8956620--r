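sceFromCounts <- function(m, group, condition) {
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                       "CsparseMatrix")),
    colData = S4Vectors::DataFrame(group = group, condition = condition,
                                   row.names = colnames(m)))
}

test_that("detection fractions are exact cell-count ratios", {
  # 10 cells, gene nonzero in 2 -> 0.2; 20 cells with 7 nonzero -> 0.35
  m1 <- matrix(0, 2, 10, dimnames = list(c("g1", "g2"), paste0("c", 1:10)))
  m1["g1", 1:2] <- 5
  p1 <- expressedFraction(sceFromCounts(m1, rep("A", 10), rep("N", 10)))
  expect_equal(unname(exprFraction(p1)["g1", 1]), 0.2)
  expect_equal(unname(exprFraction(p1)["g2", 1]), 0)

  x <- c(0, 1, 0, 5, 2, 0, 0, 3, 1, 0, 0, 4, 0, 0, 1, 0, 0, 1, 0, 0)
  m2 <- matrix(x, 1, 20, dimnames = list("g", paste0("c", 1:20)))
  p2 <- expressedFraction(sceFromCounts(m2, rep("A", 20), rep("N", 20)))
  expect_equal(unname(exprFraction(p2)[1, 1]), sum(x > 0) / 20)  # 0.35

  # degenerate single-cell group
  m3 <- matrix(0, 1, 1, dimnames = list("g", "c1"))
  p3 <- expressedFraction(sceFromCounts(m3, "A", "N"))
  expect_equal(unname(exprFraction(p3)[1, 1]), 0)
})

test_that("expressed calls are inclusive at the threshold boundary", {
  nExpr <- matrix(c(2L, 40L, 199999L), 3, 1,
                  dimnames = list(c("at", "at200", "below"), "A|N"))
  prof <- profileFrom(rbind(at = 2L, at200 = 40L, below = 199999L),
                      1000000L, "A", "N")
  # 2/10 at threshold .2 via a 10-cell key
  p10 <- profileFrom(matrix(2L, 1, 1, dimnames = list("g", "A|N")),
                     10L, "A", "N")
  expect_true(expressedCall(p10, 0.20)["g", 1])
  # 0.199999 (199999/1000000) is below 0.20
  pBig <- profileFrom(matrix(199999L, 1, 1, dimnames = list("g", "A|N")),
                      1000000L, "A", "N")
  expect_false(expressedCall(pBig, 0.20)["g", 1])
  # 0.012 passes the 1% rule
  p1pc <- profileFrom(matrix(12L, 1, 1, dimnames = list("g", "A|N")),
                      1000L, "A", "N")
  expect_true(expressedCall(p1pc, 0.01)["g", 1])
  expect_error(expressedCall(p1pc, 0), "threshold")
  expect_error(expressedCall(p1pc, 1.5), "threshold")
})

test_that("raising the threshold never turns a call on (monotonicity)", {
  set.seed(42)
  nExpr <- matrix(sample(0:50, 60, replace = TRUE), 20, 3,
                  dimnames = list(sprintf("g%02d", 1:20),
                                  c("A|N", "B|N", "C|N")))
  prof <- profileFrom(nExpr, c(50L, 50L, 50L), c("A", "B", "C"),
                      rep("N", 3))
  for (pair in list(c(0.1, 0.2), c(0.2, 0.5), c(0.02, 0.04))) {
    lo <- expressedCall(prof, pair[1]); hi <- expressedCall(prof, pair[2])
    expect_true(all(lo[hi]))   # every high-threshold call holds at low
  }
})

test_that("pooled fraction is the cell-weighted mean of subkey fractions", {
  set.seed(7)
  m <- matrix(rbinom(30 * 5, 1, 0.4) * rpois(150, 2), 5, 30,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:30)))
  grp <- rep(c("A1", "A2"), c(12, 18))
  sceSplit <- sceFromCounts(m, grp, rep("N", 30))
  scePooled <- sceFromCounts(m, rep("A", 30), rep("N", 30))
  fs <- exprFraction(expressedFraction(sceSplit))
  fp <- exprFraction(expressedFraction(scePooled))
  expect_equal(unname(fp[, "A|N"]),
               unname((12 * fs[, "A1|N"] + 18 * fs[, "A2|N"]) / 30))
})

test_that("cell-id mismatch between matrix and table errors", {
  m <- matrix(1, 1, 2, dimnames = list("g", c("c1", "c2")))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                       "CsparseMatrix")))
  tab <- data.frame(cell_id = "c1", group = "A", condition = "N",
                    embed_x = 0, embed_y = 0)
  expect_error(attachCellMeta(sce, tab), "absent")
  expect_error(expressedFraction(sce), "missing grouping")
})
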