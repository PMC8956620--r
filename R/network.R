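#' Build a directed ligand-receptor communication network
#'
#' Complete enumeration over ordered group pairs and curated pairs: an edge
#' (b, r, ligand, receptor) exists iff the ligand is called expressed in
#' broadcaster b and the receptor in receiver r, under one condition.
#' Self-loops (b = r, autocrine signalling) are allowed. Genes in the pair
#' list that are absent from the call matrix are treated as not expressed
#' (reported via \code{message()}), never as an error: curated lists always
#' exceed the detected gene space.
#'
#' @param calls logical gene x group matrix for one condition, as produced
#'   by [expressedCall()] or [callsByCondition()]; rownames are gene
#'   symbols, colnames are group labels.
#' @param pairs an [LRPairList-class].
#' @param condition condition label stored on the network.
#' @param groups group labels to use as nodes; defaults to
#'   \code{colnames(calls)}. Must be nonempty.
#' @param threshold detection threshold to record on the network; taken
#'   from the calls attribute when present.
#' @return A [CommNetwork-class].
#' @examples
#' calls <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2,
#'                 dimnames = list(c("COL1A1", "ITGB1"), c("F", "L")))
#' net <- buildNetwork(calls, LRPairList("COL1A1", "ITGB1"), "Normal")
#' pairCounts(net)
#' @export
buildNetwork <- function(calls, pairs, condition,
                         groups = colnames(calls), threshold = NULL) {
  if (is.null(groups) || length(groups) == 0L)
    stop("group list must be nonempty")
  if (!all(groups %in% colnames(calls)))
    stop("groups absent from call matrix: ",
         paste(setdiff(groups, colnames(calls)), collapse = ", "))
  if (is.null(threshold))
    threshold <- attr(calls, "threshold") %||% NA_real_
  calls <- calls[, groups, drop = FALSE]

  lrGenes <- unique(c(ligands(pairs), receptors(pairs)))
  absent <- setdiff(lrGenes, rownames(calls))
  if (length(absent))
    message(length(absent), " ligand/receptor gene(s) absent from the ",
            "matrix; treated as not expressed")
  full <- matrix(FALSE, length(lrGenes), length(groups),
                 dimnames = list(lrGenes, groups))
  present <- intersect(lrGenes, rownames(calls))
  full[present, ] <- calls[present, , drop = FALSE]

  lig <- ligands(pairs)
  rec <- receptors(pairs)
  bList <- vector("list", length(pairs))
  for (p in seq_along(lig)) {
    bs <- which(full[lig[p], ])
    rs <- which(full[rec[p], ])
    if (length(bs) && length(rs)) {
      grid <- expand.grid(b = bs, r = rs, KEEP.OUT.ATTRS = FALSE)
      bList[[p]] <- data.frame(
        broadcaster = groups[grid$b], receiver = groups[grid$r],
        ligand = lig[p], receptor = rec[p], stringsAsFactors = FALSE)
    }
  }
  ed <- do.call(rbind, bList)
  if (is.null(ed))
    ed <- data.frame(broadcaster = character(), receiver = character(),
                     ligand = character(), receptor = character(),
                     stringsAsFactors = FALSE)
  ed <- ed[order(ed$broadcaster, ed$receiver, ed$ligand, ed$receptor), ,
           drop = FALSE]
  rownames(ed) <- NULL
  new("CommNetwork", condition = as.character(condition), nodes = groups,
      edges = S4Vectors::DataFrame(ed), calls = full, pairs = pairs,
      threshold = as.numeric(threshold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count ordered communication pathways between two node sets
#'
#' The number of ordered (broadcaster, receiver) pathways among the union
#' of two node sets, loops included: \eqn{|A \cup B|^2}. With 13
#' cardiomyocyte and 8 fibroblast subtypes this is 441.
#'
#' @param nodesA,nodesB nonempty character vectors of group labels.
#' @return integer pathway count.
#' @examples
#' countPathways(paste0("CM", 1:13), paste0("Fib", 1:8))  # 441
#' @export
countPathways <- function(nodesA, nodesB) {
  if (length(nodesA) == 0L || length(nodesB) == 0L)
    stop("node lists must be nonempty")
  n <- length(union(nodesA, nodesB))
  n * n
}

#' Differential comparison of control and disease networks
#'
#' Per ordered (broadcaster, receiver) group pair, partitions the union of
#' the two edge sets into gained (disease only), lost (control only) and
#' persisted pairs, so that gained + persisted = n_disease and lost +
#' persisted = n_normal on every ordered pair. Fold changes are reported
#' only where both counts are positive; gains from zero are left NA and can
#' be read off the gained table. Zeroed ligands -- ligand genes called
#' expressed in the control condition whose call fell below threshold in
#' disease -- are listed per broadcasting group.
#'
#' @param netN control-condition [CommNetwork-class].
#' @param netD disease-condition [CommNetwork-class]; must share node set
#'   and pair-list provenance with \code{netN}.
#' @return A [DiffCommReport-class].
#' @examples
#' sim <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 1))
#' nets <- callsByCondition(expressedFraction(sim$sce), 0.20)
#' netN <- buildNetwork(nets$Normal, sim$pairs, "Normal")
#' netD <- buildNetwork(nets$Disease, sim$pairs, "Disease")
#' diffNetworks(netN, netD)
#' @export
diffNetworks <- function(netN, netD) {
  if (!setequal(commNodes(netN), commNodes(netD)) ||
      length(commNodes(netN)) != length(commNodes(netD)))
    stop("networks must share the same node set")
  if (!identical(as.data.frame(netN@pairs), as.data.frame(netD@pairs)))
    stop("networks must be built from the same ligand-receptor list")
  nodes <- commNodes(netN)
  edN <- as.data.frame(commEdges(netN))
  edD <- as.data.frame(commEdges(netD))
  keyOf <- function(ed) paste(ed$broadcaster, ed$receiver, ed$ligand,
                              ed$receptor, sep = "\r")
  kN <- keyOf(edN); kD <- keyOf(edD)
  gained <- edD[!(kD %in% kN), , drop = FALSE]
  lost <- edN[!(kN %in% kD), , drop = FALSE]
  persisted <- edN[kN %in% kD, , drop = FALSE]

  pairKey <- function(ed) paste(ed$broadcaster, ed$receiver, sep = "\r")
  grid <- expand.grid(broadcaster = nodes, receiver = nodes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$broadcaster, grid$receiver), , drop = FALSE]
  gKey <- paste(grid$broadcaster, grid$receiver, sep = "\r")
  cnt <- function(ed) as.integer(table(factor(pairKey(ed), levels = gKey)))
  bp <- data.frame(grid,
                   n_normal = cnt(edN), n_disease = cnt(edD),
                   n_gained = cnt(gained), n_lost = cnt(lost),
                   n_persisted = cnt(persisted),
                   stringsAsFactors = FALSE)
  bp$fold_change <- ifelse(bp$n_normal > 0 & bp$n_disease > 0,
                           bp$n_disease / bp$n_normal, NA_real_)
  rownames(bp) <- NULL

  # zeroed ligands: broadcaster-side calls, control TRUE -> disease FALSE
  ligGenes <- unique(ligands(netN@pairs))
  zl <- data.frame(group = character(), ligand = character(),
                   stringsAsFactors = FALSE)
  for (g in nodes) {
    dropped <- ligGenes[netN@calls[ligGenes, g] & !netD@calls[ligGenes, g]]
    if (length(dropped))
      zl <- rbind(zl, data.frame(group = g, ligand = sort(dropped),
                                 stringsAsFactors = FALSE))
  }
  totals <- stats::setNames(c(nrow(edN), nrow(edD)),
                            c(commCondition(netN), commCondition(netD)))
  sortEd <- function(ed) {
    ed <- ed[order(ed$broadcaster, ed$receiver, ed$ligand, ed$receptor), ,
             drop = FALSE]
    rownames(ed) <- NULL
    S4Vectors::DataFrame(ed)
  }
  new("DiffCommReport",
      conditions = c(commCondition(netN), commCondition(netD)),
      byPair = S4Vectors::DataFrame(bp),
      gained = sortEd(gained), lost = sortEd(lost),
      persisted = sortEd(persisted),
      zeroedLigands = S4Vectors::DataFrame(zl), totals = totals)
}

#' Per-group ligand broadcasting and receptor presentation summary
#'
#' For each group: the number of distinct ligand genes it broadcasts (in at
#' least one edge as broadcaster) and distinct receptor genes it presents,
#' the same quantities with multiplicity (edge-slot counts), and its
#' outgoing/incoming edge totals. Both the distinct-gene and the
#' with-multiplicity readings of "quantity of ligands" are reported.
#'
#' @param net a [CommNetwork-class].
#' @return data.frame with one row per group.
#' @examples
#' calls <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE), 3,
#'                 dimnames = list(c("COL1A1", "FN1", "ITGB1"), c("F", "L")))
#' net <- buildNetwork(calls, LRPairList(c("COL1A1", "FN1"),
#'                                       c("ITGB1", "ITGB1")), "Normal")
#' ligandBroadcastSummary(net)
#' @export
ligandBroadcastSummary <- function(net) {
  ed <- as.data.frame(commEdges(net))
  nodes <- commNodes(net)
  out <- data.frame(
    group = nodes,
    ligands_distinct = vapply(nodes, function(g)
      length(unique(ed$ligand[ed$broadcaster == g])), integer(1)),
    ligands_total = vapply(nodes, function(g)
      sum(ed$broadcaster == g), integer(1)),
    receptors_distinct = vapply(nodes, function(g)
      length(unique(ed$receptor[ed$receiver == g])), integer(1)),
    receptors_total = vapply(nodes, function(g)
      sum(ed$receiver == g), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
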