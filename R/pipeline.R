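#' Run the full communication + spatial-DE pipeline
#'
#' Orchestrates QC filtering, detection-fraction profiling, per-condition
#' network construction, the differential network report and (optionally)
#' the Moran's-I spatial discovery stage for chosen cell groups, writing
#' every artifact plus a provenance record into \code{outDir}. Defaults
#' follow the analysis this package implements: detection threshold 0.20,
#' QC bounds (3 cells/gene, 200-2000 genes/nucleus), Moran parameters k =
#' 15, 999 permutations, alpha 0.05, minimum detection 1\%, conservative
#' thresholds 0.1. All outputs are fully sorted, so a rerun with the same
#' inputs and config is bit-identical.
#'
#' @param sce SingleCellExperiment with counts, colData group/condition,
#'   and (for the spatial stage) an embedding in reducedDims.
#' @param pairs an [LRPairList-class].
#' @param outDir output directory; created if missing.
#' @param conditions length-2 character: control then disease label.
#' @param threshold detection threshold in (0, 1]; default 0.20.
#' @param qc list of QC thresholds (minCells, minGenes, maxGenes) or NULL
#'   to skip QC.
#' @param spatialGroups groups to run the spatial stage on; NULL (default)
#'   skips it.
#' @param k,nPerm,alpha,minPct,iSingle,iDelta Moran-stage parameters.
#' @param seed integer seed for the permutation tests; required when the
#'   spatial stage runs.
#' @return invisible list with all in-memory stage outputs (sce, profile,
#'   networks, diff report, moran tables, spatial calls).
#' @examples
#' sim <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 1))
#' out <- runPipeline(sim$sce, sim$pairs, tempfile("run"), qc = NULL)
#' commTotals(out$diff)
#' @export
runPipeline <- function(sce, pairs, outDir,
                        conditions = c("Normal", "Disease"),
                        threshold = 0.20,
                        qc = list(minCells = 3L, minGenes = 200L,
                                  maxGenes = 2000L),
                        spatialGroups = NULL, k = 15L, nPerm = 999L,
                        alpha = 0.05, minPct = 0.01, iSingle = 0.1,
                        iDelta = 0.1, seed = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("config error: threshold must lie in (0, 1]")
  if (length(conditions) != 2L)
    stop("config error: exactly two conditions required")
  if (!is.null(spatialGroups) && is.null(seed))
    stop("config error: the spatial stage requires a seed")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  log <- function(stage, ...) message("[", stage, "] ", ...)

  if (!is.null(qc)) {
    sce <- qcFilter(sce, qc$minCells, qc$minGenes, qc$maxGenes)
    rep <- S4Vectors::metadata(sce)$qc
    log("qc", rep$n_genes_in, " -> ", rep$n_genes_out, " genes; ",
        rep$n_cells_in, " -> ", rep$n_cells_out, " cells")
    .writeJSON(rep, file.path(outDir, "qc_report.json"))
  }

  prof <- expressedFraction(sce, groupBy = c("group", "condition"))
  log("profile", nrow(prof@nExpr), " genes x ", length(prof@nCells),
      " group-condition keys")
  fr <- exprFraction(prof)
  utils::write.table(
    data.frame(gene = rownames(fr), fr[, order(colnames(fr)), drop = FALSE],
               check.names = FALSE),
    file.path(outDir, "expression_profile.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(key = sort(colnames(fr)),
               n_cells = profileCells(prof)[sort(colnames(fr))]),
    file.path(outDir, "profile_n_cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- callsByCondition(prof, threshold)
  miss <- setdiff(conditions, names(calls))
  if (length(miss))
    stop("conditions absent from the data: ", paste(miss, collapse = ", "))
  nets <- lapply(conditions, function(cond)
    buildNetwork(calls[[cond]], pairs, cond, threshold = threshold))
  names(nets) <- conditions
  for (cond in conditions) {
    log("network", cond, ": ", nrow(commEdges(nets[[cond]])),
        " expressed pairs")
    writeReports(nets[[cond]],
                 file.path(outDir, paste0("network_", cond, ".csv")), "csv")
    writeReports(nets[[cond]],
                 file.path(outDir, paste0("network_", cond, ".json")),
                 "json")
  }
  diff <- diffNetworks(nets[[1L]], nets[[2L]])
  log("diff", "gained ", nrow(gainedEdges(diff)), ", lost ",
      nrow(lostEdges(diff)), ", persisted ", nrow(persistedEdges(diff)))
  writeReports(diff, file.path(outDir, "diff_report.csv"), "csv")
  writeReports(diff, file.path(outDir, "diff_report.json"), "json")

  moran <- list(); calls2 <- NULL
  if (!is.null(spatialGroups)) {
    for (gp in spatialGroups) {
      tabs <- lapply(conditions, function(cond)
        spatialDETable(sce, gp, cond, k = k, nPerm = nPerm, seed = seed,
                       alpha = alpha, minPct = minPct))
      names(tabs) <- conditions
      for (cond in conditions)
        utils::write.table(as.data.frame(tabs[[cond]]),
                           file.path(outDir, sprintf("moran_%s_%s.tsv",
                                                     gp, cond)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      calls2 <- conservativeFilter(tabs[[1L]], tabs[[2L]],
                                   iSingle = iSingle, iDelta = iDelta)
      utils::write.table(as.data.frame(calls2),
                         file.path(outDir, sprintf("spatial_calls_%s.tsv",
                                                   gp)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      moran[[gp]] <- tabs
      log("spatial", gp, ": ",
          sum(tabs[[1L]]$stage1), "/", sum(tabs[[2L]]$stage1),
          " stage-1 genes; ", sum(calls2$pass), " pass conservative filter")
    }
  }

  prov <- list(package = "scCommNet",
               version = as.character(utils::packageVersion("scCommNet")),
               r_version = R.version.string,
               conditions = as.list(conditions), threshold = threshold,
               qc = qc, k = k, n_perm = nPerm, alpha = alpha,
               min_pct = minPct, i_single = iSingle, i_delta = iDelta,
               seed = seed)
  .writeJSON(prov, file.path(outDir, "provenance.json"))
  invisible(list(sce = sce, profile = prof, networks = nets, diff = diff,
                 moran = moran, spatialCalls = calls2))
}

#' Write a simulated dataset to disk as the standard file set
#'
#' Writes the 10x-style MTX triplet, the cell-metadata TSV, the
#' ligand-receptor pair CSV and the ground-truth JSON for a
#' [generateDataset()] result, so a pipeline run can start from files.
#'
#' @param sim a [generateDataset()] result.
#' @param dir output directory; created if missing.
#' @return \code{dir}, invisibly.
#' @importFrom Matrix writeMM
#' @export
writeDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(sim$sce, "counts")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  cd <- SummarizedExperiment::colData(sim$sce)
  emb <- SingleCellExperiment::reducedDim(sim$sce, "EMBED")
  utils::write.table(
    data.frame(cell_id = colnames(m), group = cd$group,
               condition = cd$condition,
               embed_x = emb[, 1L], embed_y = emb[, 2L]),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.csv(as.data.frame(sim$pairs),
                   file.path(dir, "lr_pairs.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- sim$truth
  .writeJSON(list(
    totals = as.list(commTotals(tr$diff)),
    n_gained = nrow(gainedEdges(tr$diff)),
    n_lost = nrow(lostEdges(tr$diff)),
    spatial_labels = lapply(seq_len(nrow(tr$spatialLabels)), function(i)
      as.list(as.data.frame(tr$spatialLabels[i, ])))),
    file.path(dir, "ground_truth.json"))
  invisible(dir)
}
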