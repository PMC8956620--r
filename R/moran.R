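#' Symmetrized k-nearest-neighbour weight graph on a 2-D embedding
#'
#' Builds a directed kNN graph by Euclidean distance on the supplied
#' embedding coordinates, then symmetrizes by union with binary weights.
#' Ties in distance are broken deterministically by (distance, cell index),
#' so the graph is reproducible across platforms. Duplicate identical
#' coordinates are allowed; self-weights are always zero.
#'
#' @param coords numeric matrix, cells x 2 (embedding coordinates).
#' @param k neighbours per cell before symmetrization; must satisfy
#'   \code{1 <= k < n}. Default 15.
#' @return A [WeightGraph-class].
#' @examples
#' g <- knnWeights(cbind(1:5, 0), k = 1)
#' totalWeight(g)
#' @importFrom Matrix sparseMatrix
#' @export
knnWeights <- function(coords, k = 15L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 cells to build a neighbour graph")
  if (k < 1L) stop("'k' must be at least 1")
  if (k >= n) stop("'k' must be smaller than the number of cells (",
                   n, ")")
  d <- as.matrix(stats::dist(coords))
  idx <- seq_len(n)
  nb <- vapply(idx, function(i) {
    di <- d[i, ]
    di[i] <- Inf                       # never a self-neighbour
    order(di, idx)[seq_len(k)]         # ties broken by cell index
  }, integer(k))
  a <- Matrix::sparseMatrix(i = rep(idx, each = k), j = as.integer(nb),
                            x = 1, dims = c(n, n))
  w <- methods::as((a + Matrix::t(a)) > 0, "dMatrix") * 1
  w <- methods::as(w, "CsparseMatrix")
  if (!is.null(rownames(coords))) dimnames(w) <- list(rownames(coords),
                                                      rownames(coords))
  new("WeightGraph", w = w)
}

#' Moran's I spatial autocorrelation statistic
#'
#' \deqn{I = \frac{n}{W} \cdot
#'   \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x)}
#'        {\sum_i (x_i - \bar x)^2}}
#' I ranges from about -1 (perfect dispersion: neighbours systematically
#' dissimilar) through 0 (no spatial autocorrelation; the exact null
#' expectation is \eqn{-1/(n-1)}) to +1 (perfect positive autocorrelation:
#' expression concentrated in a focal region of the embedding). The
#' statistic is invariant to affine transforms \eqn{a x + b}, \eqn{a \neq
#' 0}.
#'
#' @param x numeric vector of per-cell expression values, length n.
#' @param g a [WeightGraph-class] (or a plain symmetric weight matrix with
#'   zero diagonal).
#' @return Moran's I (scalar).
#' @examples
#' g <- knnWeights(cbind(c(0, 1), 0), k = 1)
#' moransI(c(0, 1), g)  # -1
#' @export
moransI <- function(x, g) {
  w <- if (methods::is(g, "WeightGraph")) weightMatrix(g) else g
  n <- length(x)
  if (nrow(w) != n)
    stop("length(x) must equal the number of cells in the graph")
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0)
    stop("Moran's I is undefined for a constant expression vector")
  W <- sum(w)
  num <- as.numeric(Matrix::crossprod(z, w %*% z))
  (n / W) * num / ss
}

#' Permutation (or analytic) test for positive spatial autocorrelation
#'
#' Tests \eqn{H_0}: no spatial autocorrelation against one-sided positive
#' autocorrelation. The default permutation test randomly relabels cells
#' \code{nPerm} times and reports \eqn{p = (1 + \#\{I_{perm} \ge
#' I_{obs}\})/(1 + nPerm)}; it is seeded and exactly reproducible. The
#' analytic alternative uses the normal approximation under the
#' randomization assumption (mean \eqn{-1/(n-1)} and the standard
#' randomization variance).
#'
#' @param x per-cell expression vector.
#' @param g a [WeightGraph-class].
#' @param nPerm number of permutations (>= 99); default 999.
#' @param seed optional integer seed applied locally for the permutations.
#' @param method \code{"permutation"} (default) or \code{"normal"}.
#' @return list with elements \code{I} (observed statistic), \code{p}
#'   (one-sided p-value), \code{meanPermI} and \code{sdPermI} (mean and sd
#'   of the permuted statistics; NA for the analytic method) and
#'   \code{method}.
#' @examples
#' g <- knnWeights(cbind(seq_len(30), 0), k = 2)
#' moransTest(seq_len(30) + rnorm(30, sd = 0.1), g, nPerm = 99, seed = 1)$p
#' @export
moransTest <- function(x, g, nPerm = 999L, seed = NULL,
                       method = c("permutation", "normal")) {
  method <- match.arg(method)
  w <- weightMatrix(g)
  n <- length(x)
  iObs <- moransI(x, g)
  if (method == "normal") {
    mom <- .moranMoments(x, w)
    p <- stats::pnorm(iObs, mean = mom$mean, sd = sqrt(mom$var),
                      lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
    return(list(I = iObs, p = p, meanPermI = NA_real_,
                sdPermI = NA_real_, method = method))
  }
  if (nPerm < 99L) stop("'nPerm' must be at least 99")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  z <- x - mean(x)
  ss <- sum(z^2)
  W <- sum(w)
  zp <- vapply(seq_len(nPerm), function(b) sample(z), numeric(n))
  nums <- Matrix::colSums(zp * (w %*% zp))
  iPerm <- (n / W) * nums / ss
  p <- (1 + sum(iPerm >= iObs)) / (1 + nPerm)
  list(I = iObs, p = p, meanPermI = mean(iPerm),
       sdPermI = stats::sd(iPerm), method = method)
}

# Randomization-assumption moments of Moran's I (standard closed forms)
.moranMoments <- function(x, w) {
  n <- length(x)
  S0 <- sum(w)
  S1 <- sum((w + Matrix::t(w))^2) / 2
  rs <- Matrix::rowSums(w); cs <- Matrix::colSums(w)
  S2 <- sum((rs + cs)^2)
  z <- x - mean(x)
  b2 <- n * sum(z^4) / sum(z^2)^2
  eI <- -1 / (n - 1)
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
          ((n - 1) * (n - 2) * (n - 3) * S0^2) - eI^2
  list(mean = eI, var = varI)
}

#' Per-gene spatial differential-expression table for one cell type and
#' condition
#'
#' Subsets the experiment to one cell group and one condition, builds a kNN
#' weight graph on its embedding, and for every gene detected in at least
#' \code{minPct} of the cells computes Moran's I, a one-sided permutation
#' p-value, a Benjamini-Hochberg adjusted p-value (family = the genes
#' tested within this cell type x condition), and the detection fraction.
#' The stage-1 call is \code{I > 0 & p_adj <= alpha & pct >= minPct}.
#' Expression feeds the statistic as library-size-normalized log1p counts
#' by default (each cell scaled to the median library size); raw counts are
#' available via \code{transform = "counts"}. Genes with zero variance
#' after transformation are dropped (the statistic is undefined).
#'
#' @param sce SingleCellExperiment with \code{counts}, colData columns
#'   \code{group} and \code{condition}, and an embedding in
#'   \code{reducedDims}.
#' @param cellType group label to analyse.
#' @param condition condition label to analyse.
#' @param k neighbours for [knnWeights()]; default 15.
#' @param nPerm permutations per gene; default 999.
#' @param seed integer seed governing all permutations in this table.
#' @param alpha adjusted-p significance level; default 0.05.
#' @param minPct minimum detection fraction to test a gene; default 0.01.
#' @param transform \code{"lognorm"} (default) or \code{"counts"}.
#' @param embedName reducedDim to use; defaults to the first one.
#' @return \code{DataFrame} with columns gene, condition, I, p, p_adj,
#'   pct_expressed, stage1; parameters recorded in \code{metadata()}.
#' @seealso [conservativeFilter()]
#' @importFrom SingleCellExperiment reducedDim reducedDimNames
#' @export
spatialDETable <- function(sce, cellType, condition, k = 15L, nPerm = 999L,
                           seed = NULL, alpha = 0.05, minPct = 0.01,
                           transform = c("lognorm", "counts"),
                           embedName = NULL) {
  transform <- match.arg(transform)
  cd <- SummarizedExperiment::colData(sce)
  sel <- cd$group == cellType & cd$condition == condition
  if (sum(sel) < k + 1L)
    stop("need at least k + 1 = ", k + 1L, " cells for group '", cellType,
         "' in condition '", condition, "'; found ", sum(sel))
  sub <- sce[, sel]
  if (is.null(embedName))
    embedName <- SingleCellExperiment::reducedDimNames(sub)[1L]
  coords <- SingleCellExperiment::reducedDim(sub, embedName)
  g <- knnWeights(coords, k = k)

  m <- SummarizedExperiment::assay(sub, "counts")
  pct <- Matrix::rowSums(m > 0) / ncol(m)
  testable <- which(pct + 1e-9 * 1 >= minPct)
  expr <- if (transform == "lognorm") {
    lib <- Matrix::colSums(m)
    lib[lib == 0] <- 1
    log1p(Matrix::t(Matrix::t(m) * (stats::median(lib) / lib)))
  } else m

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  res <- vector("list", length(testable))
  for (t in seq_along(testable)) {
    gi <- testable[t]
    x <- as.numeric(expr[gi, ])
    if (stats::var(x) == 0) next     # statistic undefined; skip gene
    mt <- moransTest(x, g, nPerm = nPerm)
    res[[t]] <- data.frame(gene = rownames(m)[gi], I = mt$I, p = mt$p,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(gene = character(), I = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  out <- S4Vectors::DataFrame(
    gene = res$gene, condition = rep(condition, nrow(res)),
    I = res$I, p = res$p,
    p_adj = stats::p.adjust(res$p, method = "BH"),
    pct_expressed = pct[match(res$gene, rownames(m))])
  out$stage1 <- out$I > 0 & out$p_adj <= alpha &
    out$pct_expressed + 1e-9 >= minPct
  S4Vectors::metadata(out) <- list(cell_type = cellType,
                                   condition = condition, k = k,
                                   n_perm = nPerm, alpha = alpha,
                                   min_pct = minPct, transform = transform,
                                   n_cells = ncol(m), seed = seed)
  out
}

#' Conservative two-condition filter on Moran tables
#'
#' From the stage-1 tables of one cell type in the control and disease
#' conditions, nominates genes of interest: a gene available (stage-1
#' significant, by default) in a single condition passes when its I exceeds
#' \code{iSingle}; a gene available in both passes when |I_control -
#' I_disease| exceeds \code{iDelta}. Both comparisons are strict. Whether
#' "available" means stage-1 significant or merely tested is configurable,
#' since the wording of such filters is ambiguous; the rule applied is
#' recorded on the result.
#'
#' @param tableN,tableD [spatialDETable()] outputs for the control and
#'   disease condition of the same cell type.
#' @param iSingle threshold on I for single-condition genes; default 0.1.
#' @param iDelta threshold on |I_N - I_D| for both-condition genes;
#'   default 0.1.
#' @param presence \code{"stage1"} (default) or \code{"tested"}.
#' @return \code{DataFrame} with columns gene, I_normal, I_disease,
#'   present_normal, present_disease, rule, pass.
#' @export
conservativeFilter <- function(tableN, tableD, iSingle = 0.1,
                               iDelta = 0.1,
                               presence = c("stage1", "tested")) {
  presence <- match.arg(presence)
  avail <- function(tab) {
    if (presence == "stage1") tab$gene[tab$stage1] else tab$gene
  }
  gN <- avail(tableN); gD <- avail(tableD)
  genes <- sort(union(gN, gD))
  iN <- tableN$I[match(genes, tableN$gene)]
  iD <- tableD$I[match(genes, tableD$gene)]
  inN <- genes %in% gN; inD <- genes %in% gD
  rule <- ifelse(inN & inD, "both", "single")
  pass <- logical(length(genes))
  single <- rule == "single"
  iSing <- ifelse(inN, iN, iD)
  pass[single] <- iSing[single] > iSingle
  pass[!single] <- abs(iN[!single] - iD[!single]) > iDelta
  out <- S4Vectors::DataFrame(gene = genes, I_normal = iN, I_disease = iD,
                              present_normal = inN, present_disease = inD,
                              rule = rule, pass = pass)
  S4Vectors::metadata(out) <- list(i_single = iSingle, i_delta = iDelta,
                                   presence = presence)
  out
}
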