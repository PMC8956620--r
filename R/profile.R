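#' Detection fraction per gene and (group, condition) key
#'
#' For every gene and every combination of the requested grouping columns,
#' counts the cells with a raw count above zero and divides by the cells in
#' the key. No normalization enters this computation: "expressed in a cell"
#' means raw count > 0, and cells are pooled across samples within each
#' key. Keys with zero cells are dropped (they cannot occur when keys are
#' derived from observed cells, but empty factor levels are guarded
#' against).
#'
#' @param sce SingleCellExperiment with a \code{counts} assay and the
#'   grouping columns in its colData.
#' @param groupBy colData column names defining the keys; default
#'   \code{c("group", "condition")}. A single column (e.g. \code{"group"})
#'   profiles within one condition subset.
#' @return An [ExpressionProfile-class].
#' @examples
#' sim <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 1))
#' prof <- expressedFraction(sim$sce)
#' head(exprFraction(prof))
#' @importFrom SummarizedExperiment assay colData
#' @export
expressedFraction <- function(sce, groupBy = c("group", "condition")) {
  cd <- SummarizedExperiment::colData(sce)
  miss <- setdiff(groupBy, colnames(cd))
  if (length(miss))
    stop("colData is missing grouping column(s): ",
         paste(miss, collapse = ", "))
  m <- SummarizedExperiment::assay(sce, "counts")
  keyParts <- lapply(groupBy, function(col) as.character(cd[[col]]))
  key <- do.call(paste, c(keyParts, sep = "|"))
  fac <- factor(key, levels = unique(key))
  nCells <- as.integer(table(fac))
  detected <- m > 0
  ind <- Matrix::sparseMatrix(i = seq_along(fac), j = as.integer(fac),
                              x = 1, dims = c(length(fac), nlevels(fac)))
  nExpr <- as.matrix(detected %*% ind)
  storage.mode(nExpr) <- "integer"
  dimnames(nExpr) <- list(rownames(m), levels(fac))
  first <- !duplicated(fac)
  keys <- S4Vectors::DataFrame(lapply(stats::setNames(keyParts, groupBy),
                                      function(v) v[first]))
  rownames(keys) <- levels(fac)
  new("ExpressionProfile", nExpr = nExpr, nCells = nCells, keys = keys)
}

#' Binary expressed/not-expressed calls at a detection threshold
#'
#' A gene is called expressed in a key when its detection fraction is at
#' least \code{threshold} (inclusive: a fraction of exactly 0.20 passes the
#' 20\% rule). The comparison is performed on the integer counts
#' (\code{nExpr >= threshold * nCells}) with an epsilon guarding the exact
#' boundary, so thresholds such as 0.2 that are not representable in binary
#' floating point still behave as the rational rule.
#'
#' @param profile an [ExpressionProfile-class].
#' @param threshold detection-fraction threshold in (0, 1]; default 0.20.
#' @return logical matrix genes x keys with attributes \code{threshold} and
#'   \code{keys}.
#' @examples
#' sim <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 1))
#' calls <- expressedCall(expressedFraction(sim$sce), threshold = 0.20)
#' colSums(calls)
#' @export
expressedCall <- function(profile, threshold = 0.20) {
  if (!methods::is(profile, "ExpressionProfile"))
    stop("'profile' must be an ExpressionProfile")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  cut <- threshold * profile@nCells
  # nExpr and nCells are integers; a fraction equal to the threshold up to
  # one part in 1e9 is treated as equal, protecting the inclusive boundary
  eps <- 1e-9 * pmax(1, profile@nCells)
  call <- sweep(profile@nExpr, 2L, cut - eps, ">=")
  dimnames(call) <- dimnames(profile@nExpr)
  attr(call, "threshold") <- threshold
  attr(call, "keys") <- profile@keys
  call
}

#' Split condition-pooled calls into one call matrix per condition
#'
#' Convenience for the per-condition network build: from a profile computed
#' with \code{groupBy = c("group", "condition")}, returns a named list of
#' gene x group logical matrices, one per condition.
#'
#' @param profile an [ExpressionProfile-class] keyed by group and condition.
#' @param threshold detection-fraction threshold in (0, 1].
#' @return named list of logical matrices (genes x groups), one per
#'   condition, each carrying the threshold attribute.
#' @export
callsByCondition <- function(profile, threshold = 0.20) {
  keys <- profile@keys
  if (!all(c("group", "condition") %in% colnames(keys)))
    stop("profile must be keyed by 'group' and 'condition'")
  call <- expressedCall(profile, threshold)
  out <- lapply(unique(keys$condition), function(cond) {
    sel <- which(keys$condition == cond)
    m <- call[, sel, drop = FALSE]
    colnames(m) <- keys$group[sel]
    attr(m, "threshold") <- threshold
    m
  })
  stats::setNames(out, unique(keys$condition))
}
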