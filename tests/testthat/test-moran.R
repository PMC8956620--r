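test_that("kNN graph symmetrizes by union with deterministic ties", {
  # 3 collinear equally spaced points, k = 1: both ends pick the middle,
  # the middle picks one end; union gives the middle 2 neighbours
  g <- knnWeights(cbind(c(0, 1, 2), 0), k = 1)
  w <- weightMatrix(g)
  expect_equal(unname(Matrix::rowSums(w)), c(1, 2, 1))
  expect_true(Matrix::isSymmetric(w))
  expect_true(all(Matrix::diag(w) == 0))
  expect_error(knnWeights(cbind(1:3, 0), k = 3), "smaller")
  expect_error(knnWeights(cbind(1, 0), k = 1), "at least 2")
  # duplicate coordinates are allowed
  expect_s4_class(knnWeights(rbind(c(0, 0), c(0, 0), c(1, 1)), k = 1),
                  "WeightGraph")
})

test_that("Moran's I matches the hand case and the brute-force oracle", {
  g2 <- knnWeights(cbind(c(0, 1), 0), k = 1)
  expect_equal(moransI(c(0, 1), g2), -1)

  set.seed(101)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    g <- randomWeightGraph(n)
    x <- rnorm(n)
    expect_equal(moransI(x, g), bruteMoran(x, weightMatrix(g)),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I agrees with an independent library implementation", {
  skip_if_not_installed("ape")
  # ape::Moran.I row-normalizes its weight matrix, so hand it the raw
  # binary weights and evaluate ours on the row-normalized equivalent
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    w <- as.matrix(weightMatrix(randomWeightGraph(n)))
    x <- rnorm(n)
    ref <- ape::Moran.I(x, w, scaled = FALSE)
    expect_equal(moransI(x, w / rowSums(w)), ref$observed,
                 tolerance = 1e-10)
  }
})

test_that("two separated constant blobs give I = +1; constant x errors", {
  coords <- rbind(cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1)),
                  cbind(rnorm(20, 100, 0.1), rnorm(20, 100, 0.1)))
  g <- knnWeights(coords, k = 5)
  x <- rep(c(0, 1), each = 20)
  # no cross-blob edges at this separation, so neighbours always agree
  expect_equal(moransI(x, g), 1, tolerance = 1e-12)
  expect_error(moransI(rep(2, 40), g), "constant")
})

test_that("Moran's I is invariant to affine transforms of expression", {
  set.seed(9)
  g <- randomWeightGraph(30)
  x <- rnorm(30)
  i0 <- moransI(x, g)
  for (rep in 1:10) {
    a <- rnorm(1); b <- rnorm(1)
    if (abs(a) < 1e-3) a <- 1
    expect_equal(moransI(a * x + b, g), i0, tolerance = 1e-9)
  }
})

test_that("permutation test is seeded, reproducible, and correctly
           calibrated in its null mean", {
  set.seed(31)
  n <- 80
  g <- knnWeights(cbind(rnorm(n), rnorm(n)), k = 6)
  x <- rnorm(n)
  r1 <- moransTest(x, g, nPerm = 599, seed = 77)
  r2 <- moransTest(x, g, nPerm = 599, seed = 77)
  expect_identical(r1, r2)
  # permutation-null expectation of I is -1/(n-1)
  se <- r1$sdPermI / sqrt(599)
  expect_lt(abs(r1$meanPermI - (-1 / (n - 1))), 3 * se)
})

test_that("a strong gradient on a line embedding attains the minimum
           achievable p-value", {
  set.seed(13)
  n <- 200
  coords <- cbind(seq_len(n) + rnorm(n, sd = 0.01), 0)
  g <- knnWeights(coords, k = 10)
  x <- seq_len(n) / n + rnorm(n, sd = 0.05)
  r <- moransTest(x, g, nPerm = 199, seed = 4)
  expect_equal(r$p, 1 / 200)
  expect_gt(r$I, 0.5)
})

test_that("analytic normal approximation tracks the permutation test", {
  skip_if_not_installed("ape")
  # on a regular graph ape's row normalization is a scalar rescaling,
  # which Moran's I and its randomization moments are invariant to
  set.seed(17)
  n <- 60
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ring[i, i %% n + 1L] <- 1
    ring[i %% n + 1L, i] <- 1
  }
  g <- new("WeightGraph", w = methods::as(Matrix::Matrix(ring,
                                                         sparse = TRUE),
                                          "CsparseMatrix"))
  x <- rnorm(n)
  rN <- moransTest(x, g, method = "normal")
  ref <- ape::Moran.I(x, ring, scaled = FALSE, alternative = "greater")
  expect_equal(rN$I, ref$observed, tolerance = 1e-10)
  expect_equal(rN$p, ref$p.value, tolerance = 1e-8)
})

test_that("spatial DE table applies the 1% prefilter, BH family and
           stage-1 rule", {
  sim <- generateDataset(presetConfig("spatial_sarcomere", seed = 19,
                                      cellsPerGroup = 150L))
  tab <- spatialDETable(sim$sce, "Cardiomyocyte", "Disease", nPerm = 199,
                        seed = 5)
  expect_true(all(tab$pct_expressed >= 0.01 - 1e-9))
  # BH monotonicity: sorted p_adj non-decreasing in sorted p
  o <- order(tab$p)
  expect_true(all(diff(tab$p_adj[o]) >= -1e-12))
  expect_true(all(tab$p_adj >= tab$p - 1e-12))
  expect_identical(tab$stage1,
                   tab$I > 0 & tab$p_adj <= 0.05 &
                     tab$pct_expressed + 1e-9 >= 0.01)
  expect_error(spatialDETable(sim$sce, "Cardiomyocyte", "Disease",
                              k = 200), "k \\+ 1")
})

test_that("conservative filter applies single-condition and
           both-condition rules strictly", {
  tN <- fakeMoranTable(c("g1", "g2", "g3"), c(0.30, 0.05, 0.2),
                       stage1 = c(TRUE, TRUE, FALSE))
  tD <- fakeMoranTable(c("g1", "g2", "g4", "g5"),
                       c(0.35, 0.30, 0.25, 0.08),
                       stage1 = c(TRUE, TRUE, TRUE, TRUE),
                       condition = "Disease")
  out <- conservativeFilter(tN, tD)
  res <- stats::setNames(out$pass, out$gene)
  expect_false(res[["g1"]])  # both, |0.30-0.35| = 0.05 <= 0.1
  expect_true(res[["g2"]])   # both, |0.05-0.30| = 0.25 > 0.1
  expect_true(res[["g4"]])   # single (disease), I = 0.25 > 0.1
  expect_false(res[["g5"]])  # single, I = 0.08 <= 0.1
  expect_false("g3" %in% out$gene)  # not stage-1 anywhere
  # "tested" presence treats g3 as available in Normal
  out2 <- conservativeFilter(tN, tD, presence = "tested")
  expect_true("g3" %in% out2$gene)
})
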