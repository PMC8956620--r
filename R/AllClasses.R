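#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

# ---------------------------------------------------------------------------
# LRPairList
# ---------------------------------------------------------------------------

#' Curated ligand-receptor pair list
#'
#' An ordered, deduplicated set of directed (ligand gene, receptor gene)
#' symbol pairs. Direction matters: \code{(A, B)} and \code{(B, A)} are
#' distinct pairs, and a gene may appear as a ligand in some pairs and as a
#' receptor in others. Gene identity is by symbol string, case-sensitive;
#' no alias resolution is attempted.
#'
#' @slot ligand character vector of ligand gene symbols.
#' @slot receptor character vector of receptor gene symbols, parallel to
#'   \code{ligand}.
#'
#' @seealso [readLRPairs()], [buildNetwork()]
#' @export
setClass("LRPairList",
  representation(ligand = "character", receptor = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@ligand) != length(object@receptor))
      msg <- c(msg, "ligand and receptor vectors must have equal length")
    if (any(!nzchar(object@ligand)) || any(is.na(object@ligand)))
      msg <- c(msg, "ligand symbols must be nonempty and non-NA")
    if (any(!nzchar(object@receptor)) || any(is.na(object@receptor)))
      msg <- c(msg, "receptor symbols must be nonempty and non-NA")
    if (anyDuplicated(paste(object@ligand, object@receptor, sep = "\r")))
      msg <- c(msg, "duplicate (ligand, receptor) tuples are not allowed")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct an LRPairList
#'
#' Duplicated (ligand, receptor) tuples are collapsed, keeping first
#' occurrence order.
#'
#' @param ligand character vector of ligand gene symbols.
#' @param receptor character vector of receptor gene symbols.
#' @return An [LRPairList-class] object.
#' @examples
#' LRPairList(c("COL1A1", "FN1", "COL1A1"), c("ITGB1", "ITGB1", "ITGB1"))
#' @export
LRPairList <- function(ligand = character(), receptor = character()) {
  ligand <- as.character(ligand)
  receptor <- as.character(receptor)
  if (length(ligand) != length(receptor))
    stop("'ligand' and 'receptor' must have equal length")
  key <- paste(ligand, receptor, sep = "\r")
  keep <- !duplicated(key)
  new("LRPairList", ligand = ligand[keep], receptor = receptor[keep])
}

#' @describeIn LRPairList-class number of pairs.
#' @param x an \code{LRPairList}.
#' @export
setMethod("length", "LRPairList", function(x) length(x@ligand))

#' @rdname LRPairList-class
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))

#' @describeIn LRPairList-class ligand gene symbols (with multiplicity).
#' @export
setMethod("ligands", "LRPairList", function(x) x@ligand)

#' @rdname LRPairList-class
#' @export
setGeneric("receptors", function(x) standardGeneric("receptors"))

#' @describeIn LRPairList-class receptor gene symbols (with multiplicity).
#' @export
setMethod("receptors", "LRPairList", function(x) x@receptor)

#' @describeIn LRPairList-class coerce to a two-column data.frame.
#' @param row.names,optional,... passed on for S3 compatibility; ignored.
#' @export
setMethod("as.data.frame", "LRPairList",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(ligand = x@ligand, receptor = x@receptor,
               stringsAsFactors = FALSE)
  })

setMethod("show", "LRPairList", function(object) {
  cat("LRPairList with", length(object), "directed ligand-receptor pairs\n")
  n <- min(length(object), 5L)
  if (n > 0L) {
    for (i in seq_len(n))
      cat(" ", object@ligand[i], "->", object@receptor[i], "\n")
    if (length(object) > n) cat("  ...\n")
  }
})

# ---------------------------------------------------------------------------
# ExpressionProfile
# ---------------------------------------------------------------------------

#' Per-group detection-fraction profile
#'
#' For each gene and each (group, condition) key, the number of cells with a
#' raw count above zero and the total number of cells in the key. The
#' detection fraction is stored as an exact integer ratio
#' (\code{nExpr / nCells}) so that threshold comparisons at boundaries such
#' as 20\% are free of floating-point artifacts.
#'
#' @slot nExpr integer matrix, genes x keys: cells with count > 0.
#' @slot nCells integer vector, cells per key.
#' @slot keys DataFrame with one row per key and the grouping columns used
#'   (e.g. \code{group}, \code{condition}).
#'
#' @seealso [expressedFraction()], [expressedCall()]
#' @export
setClass("ExpressionProfile",
  representation(nExpr = "matrix", nCells = "integer", keys = "DataFrame"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@nExpr) != length(object@nCells))
      msg <- c(msg, "ncol(nExpr) must equal length(nCells)")
    if (nrow(object@keys) != length(object@nCells))
      msg <- c(msg, "nrow(keys) must equal length(nCells)")
    if (any(object@nCells < 1L))
      msg <- c(msg, "every key must have at least one cell")
    if (any(object@nExpr < 0L) ||
        any(object@nExpr > rep(object@nCells, each = nrow(object@nExpr))))
      msg <- c(msg, "nExpr entries must lie in [0, nCells] for their key")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname ExpressionProfile-class
#' @export
setGeneric("exprFraction", function(x) standardGeneric("exprFraction"))

#' @describeIn ExpressionProfile-class detection fractions in [0, 1]
#'   (genes x keys).
#' @param x an \code{ExpressionProfile}.
#' @export
setMethod("exprFraction", "ExpressionProfile", function(x) {
  sweep(x@nExpr, 2L, x@nCells, "/")
})

#' @rdname ExpressionProfile-class
#' @export
setGeneric("profileCells", function(x) standardGeneric("profileCells"))

#' @describeIn ExpressionProfile-class cells per key, named by key label.
#' @export
setMethod("profileCells", "ExpressionProfile", function(x) {
  stats::setNames(x@nCells, colnames(x@nExpr))
})

#' @rdname ExpressionProfile-class
#' @export
setGeneric("profileKeys", function(x) standardGeneric("profileKeys"))

#' @describeIn ExpressionProfile-class the key table (grouping columns).
#' @export
setMethod("profileKeys", "ExpressionProfile", function(x) x@keys)

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile:", nrow(object@nExpr), "genes x",
      length(object@nCells), "keys\n")
  cat("  keys:", paste(utils::head(colnames(object@nExpr), 6L),
                       collapse = ", "),
      if (length(object@nCells) > 6L) "..." else "", "\n")
  cat("  cells per key:", paste(utils::head(object@nCells, 6L),
                                collapse = ", "),
      if (length(object@nCells) > 6L) "..." else "", "\n")
})

# ---------------------------------------------------------------------------
# CommNetwork
# ---------------------------------------------------------------------------

#' Directed ligand-receptor communication network for one condition
#'
#' Nodes are cell groups (cell types or clusters); each edge is one curated
#' (ligand, receptor) pair whose ligand passed the detection-fraction
#' threshold in the broadcasting group and whose receptor passed it in the
#' receiving group, under the network's condition. Parallel edges (several
#' pairs on the same ordered group pair) and self-loops (autocrine
#' signalling) are both meaningful and allowed.
#'
#' @slot condition condition label (e.g. \code{"Normal"}).
#' @slot nodes character vector of group labels.
#' @slot edges DataFrame with columns broadcaster, receiver, ligand,
#'   receptor; one row per expressed pair on an ordered group pair.
#' @slot calls logical matrix (ligand/receptor genes x nodes) of the
#'   expressed calls the network was built from; genes absent from the count
#'   matrix appear as all-FALSE rows.
#' @slot pairs the [LRPairList-class] used.
#' @slot threshold the detection-fraction threshold applied.
#'
#' @seealso [buildNetwork()], [diffNetworks()], [pairCounts()]
#' @export
setClass("CommNetwork",
  representation(condition = "character", nodes = "character",
                 edges = "DataFrame", calls = "matrix",
                 pairs = "LRPairList", threshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@condition) != 1L)
      msg <- c(msg, "condition must be a single label")
    if (anyDuplicated(object@nodes))
      msg <- c(msg, "node labels must be unique")
    need <- c("broadcaster", "receiver", "ligand", "receptor")
    if (!all(need %in% colnames(object@edges)))
      msg <- c(msg, "edges must have broadcaster/receiver/ligand/receptor")
    else {
      if (nrow(object@edges) &&
          (!all(object@edges$broadcaster %in% object@nodes) ||
           !all(object@edges$receiver %in% object@nodes)))
        msg <- c(msg, "edge endpoints must be network nodes")
      if (anyDuplicated(do.call(paste,
            c(as.list(as.data.frame(object@edges[, need])), sep = "\r"))))
        msg <- c(msg, "duplicate edges are not allowed")
    }
    if (!is.logical(object@calls))
      msg <- c(msg, "calls must be a logical matrix")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname CommNetwork-class
#' @export
setGeneric("commEdges", function(x) standardGeneric("commEdges"))

#' @describeIn CommNetwork-class edge table (broadcaster, receiver, ligand,
#'   receptor).
#' @param x a \code{CommNetwork}.
#' @export
setMethod("commEdges", "CommNetwork", function(x) x@edges)

#' @rdname CommNetwork-class
#' @export
setGeneric("commNodes", function(x) standardGeneric("commNodes"))

#' @describeIn CommNetwork-class group labels.
#' @export
setMethod("commNodes", "CommNetwork", function(x) x@nodes)

#' @rdname CommNetwork-class
#' @export
setGeneric("commCondition", function(x) standardGeneric("commCondition"))

#' @describeIn CommNetwork-class condition label.
#' @export
setMethod("commCondition", "CommNetwork", function(x) x@condition)

#' @rdname CommNetwork-class
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @describeIn CommNetwork-class matrix \code{C[b, r]}: number of distinct
#'   expressed pairs from broadcaster \code{b} to receiver \code{r}.
#' @export
setMethod("pairCounts", "CommNetwork", function(x) {
  C <- matrix(0L, length(x@nodes), length(x@nodes),
              dimnames = list(broadcaster = x@nodes, receiver = x@nodes))
  if (nrow(x@edges)) {
    tab <- table(factor(x@edges$broadcaster, levels = x@nodes),
                 factor(x@edges$receiver, levels = x@nodes))
    C[] <- as.integer(tab)
  }
  C
})

setMethod("show", "CommNetwork", function(object) {
  cat("CommNetwork [", object@condition, "]: ",
      length(object@nodes), " groups, ",
      nrow(object@edges), " expressed ligand-receptor edges\n", sep = "")
  cat("  threshold: detection fraction >= ", object@threshold, "\n", sep = "")
  cat("  curated pairs considered:", length(object@pairs), "\n")
})

# ---------------------------------------------------------------------------
# DiffCommReport
# ---------------------------------------------------------------------------

#' Differential comparison of two communication networks
#'
#' Set algebra on the edge multigraphs of a control and a disease network
#' sharing node set and pair list: per ordered (broadcaster, receiver) group
#' pair, the pairs gained (disease only), lost (control only) and persisted
#' (both), plus global totals, zeroed ligands (ligands expressed in control
#' whose call fell below threshold in disease, per broadcaster) and fold
#' changes where both counts are positive.
#'
#' @slot conditions character of length 2: control then disease label.
#' @slot byPair DataFrame, one row per ordered group pair, with columns
#'   broadcaster, receiver, n_normal, n_disease, n_gained, n_lost,
#'   n_persisted, fold_change (NA unless both counts > 0).
#' @slot gained,lost,persisted DataFrames of edges
#'   (broadcaster, receiver, ligand, receptor).
#' @slot zeroedLigands DataFrame (group, ligand).
#' @slot totals named numeric: total expressed pairs per condition.
#' @seealso [diffNetworks()]
#' @export
setClass("DiffCommReport",
  representation(conditions = "character", byPair = "DataFrame",
                 gained = "DataFrame", lost = "DataFrame",
                 persisted = "DataFrame", zeroedLigands = "DataFrame",
                 totals = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@conditions) != 2L)
      msg <- c(msg, "conditions must have length 2")
    bp <- object@byPair
    if (nrow(bp)) {
      if (!isTRUE(all(bp$n_gained + bp$n_persisted == bp$n_disease)))
        msg <- c(msg, "gained + persisted must equal n_disease")
      if (!isTRUE(all(bp$n_lost + bp$n_persisted == bp$n_normal)))
        msg <- c(msg, "lost + persisted must equal n_normal")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname DiffCommReport-class
#' @export
setGeneric("byPairCounts", function(x) standardGeneric("byPairCounts"))

#' @describeIn DiffCommReport-class per-ordered-pair count table.
#' @param x a \code{DiffCommReport}.
#' @export
setMethod("byPairCounts", "DiffCommReport", function(x) x@byPair)

#' @rdname DiffCommReport-class
#' @export
setGeneric("gainedEdges", function(x) standardGeneric("gainedEdges"))

#' @describeIn DiffCommReport-class edges present only in the disease
#'   network.
#' @export
setMethod("gainedEdges", "DiffCommReport", function(x) x@gained)

#' @rdname DiffCommReport-class
#' @export
setGeneric("lostEdges", function(x) standardGeneric("lostEdges"))

#' @describeIn DiffCommReport-class edges present only in the control
#'   network.
#' @export
setMethod("lostEdges", "DiffCommReport", function(x) x@lost)

#' @rdname DiffCommReport-class
#' @export
setGeneric("persistedEdges", function(x) standardGeneric("persistedEdges"))

#' @describeIn DiffCommReport-class edges present in both networks.
#' @export
setMethod("persistedEdges", "DiffCommReport", function(x) x@persisted)

#' @rdname DiffCommReport-class
#' @export
setGeneric("zeroedLigands", function(x) standardGeneric("zeroedLigands"))

#' @describeIn DiffCommReport-class ligands expressed in control but not in
#'   disease, per broadcasting group.
#' @export
setMethod("zeroedLigands", "DiffCommReport", function(x) x@zeroedLigands)

#' @rdname DiffCommReport-class
#' @export
setGeneric("commTotals", function(x) standardGeneric("commTotals"))

#' @describeIn DiffCommReport-class total expressed pairs per condition.
#' @export
setMethod("commTotals", "DiffCommReport", function(x) x@totals)

setMethod("show", "DiffCommReport", function(object) {
  cat("DiffCommReport: ", object@conditions[1L], " vs ",
      object@conditions[2L], "\n", sep = "")
  cat("  total expressed pairs: ", object@totals[1L], " (",
      object@conditions[1L], ") / ", object@totals[2L], " (",
      object@conditions[2L], ")\n", sep = "")
  cat("  gained:", nrow(object@gained), " lost:", nrow(object@lost),
      " persisted:", nrow(object@persisted), "\n")
  cat("  zeroed ligands:", nrow(object@zeroedLigands), "\n")
})

# ---------------------------------------------------------------------------
# WeightGraph
# ---------------------------------------------------------------------------

#' Spatial weight graph over cells
#'
#' Symmetric nonnegative weight matrix over cells with a zero diagonal,
#' produced by union-symmetrized k-nearest-neighbour search on 2-D embedding
#' coordinates with binary weights. The total weight \eqn{W = \sum_{ij}
#' w_{ij}} normalizes Moran's I.
#'
#' @slot w sparse symmetric weight matrix (dgCMatrix), zero diagonal.
#' @seealso [knnWeights()], [moransI()]
#' @export
setClass("WeightGraph",
  representation(w = "Matrix"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@w) != ncol(object@w))
      msg <- c(msg, "weight matrix must be square")
    if (any(Matrix::diag(object@w) != 0))
      msg <- c(msg, "self-weights must be zero")
    if (!Matrix::isSymmetric(object@w))
      msg <- c(msg, "weight matrix must be symmetric")
    if (any(object@w@x < 0))
      msg <- c(msg, "weights must be nonnegative")
    if (nrow(object@w) >= 2L && any(Matrix::rowSums(object@w) == 0))
      msg <- c(msg, "every cell must have at least one neighbour")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname WeightGraph-class
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @describeIn WeightGraph-class the sparse weight matrix.
#' @param x a \code{WeightGraph}.
#' @export
setMethod("weightMatrix", "WeightGraph", function(x) x@w)

#' @rdname WeightGraph-class
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' @describeIn WeightGraph-class total weight \eqn{W}.
#' @export
setMethod("totalWeight", "WeightGraph", function(x) sum(x@w))

setMethod("show", "WeightGraph", function(object) {
  n <- nrow(object@w)
  cat("WeightGraph over", n, "cells;",
      length(object@w@x), "directed weight entries; W =",
      sum(object@w), "\n")
})
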