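# Independent reference implementations and fixture builders used across
# the suite. These stay deliberately naive (double/triple loops) so they
# cannot share a defect with the vectorized package code.

# Moran's I by explicit double loop over all ordered pairs.
bruteMoran <- function(x, w) {
  w <- as.matrix(w)
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Communication edges by exhaustive triple loop over groups x groups x
# pairs; returns a sorted data.frame.
bruteNetwork <- function(calls, lig, rec) {
  groups <- colnames(calls)
  out <- list()
  for (b in groups)
    for (r in groups)
      for (p in seq_along(lig)) {
        lOK <- lig[p] %in% rownames(calls) && calls[lig[p], b]
        rOK <- rec[p] %in% rownames(calls) && calls[rec[p], r]
        if (lOK && rOK)
          out[[length(out) + 1L]] <- data.frame(
            broadcaster = b, receiver = r, ligand = lig[p],
            receptor = rec[p], stringsAsFactors = FALSE)
      }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(broadcaster = character(), receiver = character(),
               ligand = character(), receptor = character(),
               stringsAsFactors = FALSE)
  df <- df[order(df$broadcaster, df$receiver, df$ligand, df$receptor), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random symmetric binary weight graph with no isolated node (n >= 3).
randomWeightGraph <- function(n) {
  repeat {
    a <- matrix(stats::rbinom(n * n, 1L, 0.3), n, n)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    diag(a) <- 0
    if (all(rowSums(a) > 0)) break
  }
  new("WeightGraph", w = methods::as(Matrix::Matrix(a, sparse = TRUE),
                                     "CsparseMatrix"))
}

# Random call matrix + pair list for small network instances.
randomNetInstance <- function(maxGroups = 5L, maxPairs = 20L) {
  nGroups <- sample(2:maxGroups, 1L)
  nGenes <- sample(4:12, 1L)
  nPairs <- sample(1:maxPairs, 1L)
  genes <- sprintf("G%02d", seq_len(nGenes))
  groups <- LETTERS[seq_len(nGroups)]
  calls <- matrix(stats::runif(nGenes * nGroups) < 0.4, nGenes, nGroups,
                  dimnames = list(genes, groups))
  lig <- sample(genes, nPairs, replace = TRUE)
  rec <- sample(genes, nPairs, replace = TRUE)
  keep <- !duplicated(paste(lig, rec))
  list(calls = calls, lig = lig[keep], rec = rec[keep])
}

# Minimal ExpressionProfile from an integer detection-count matrix.
profileFrom <- function(nExpr, nCells, groups, conditions) {
  new("ExpressionProfile", nExpr = nExpr, nCells = as.integer(nCells),
      keys = S4Vectors::DataFrame(group = groups, condition = conditions,
                                  row.names = colnames(nExpr)))
}

# Minimal Moran table for filter-rule tests.
fakeMoranTable <- function(gene, I, stage1, condition = "Normal") {
  S4Vectors::DataFrame(gene = gene, condition = condition, I = I,
                       p = 0.001, p_adj = 0.001,
                       pct_expressed = 0.5, stage1 = stage1)
}
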