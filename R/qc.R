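#' Gene-level QC: keep genes detected in enough nuclei
#'
#' Retains exactly the genes with a nonzero count in at least
#' \code{minCells} cells ("expressed" means count > 0); the bound is
#' inclusive, so with the default of 3 a gene detected in exactly three
#' nuclei is kept. The cell set is unchanged.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay.
#' @param minCells minimum number of cells with count > 0; default 3.
#' @return The filtered experiment.
#' @seealso [filterNuclei()], [qcFilter()]
#' @importFrom SummarizedExperiment assay
#' @export
filterGenes <- function(sce, minCells = 3L) {
  stopifnot(minCells >= 0)
  m <- SummarizedExperiment::assay(sce, "counts")
  keep <- Matrix::rowSums(m > 0) >= minCells
  sce[keep, ]
}

#' Nucleus-level QC: bound the number of detected genes per nucleus
#'
#' Retains exactly the cells whose number of genes with count > 0 lies in
#' \code{[minGenes, maxGenes]}, both bounds inclusive: a nucleus with
#' exactly 200 (or exactly 2000) detected genes is kept under the defaults,
#' while 199 or 2001 are removed. The lower bound removes droplets carrying
#' only ambient RNA; the upper bound removes likely doublets. The gene set
#' is unchanged.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay.
#' @param minGenes inclusive lower bound; default 200.
#' @param maxGenes inclusive upper bound; default 2000 (use \code{Inf} to
#'   disable).
#' @return The filtered experiment; a warning (not an error) if no cell
#'   survives.
#' @seealso [filterGenes()], [qcFilter()]
#' @export
filterNuclei <- function(sce, minGenes = 200L, maxGenes = 2000L) {
  stopifnot(minGenes >= 0, minGenes <= maxGenes)
  m <- SummarizedExperiment::assay(sce, "counts")
  ngenes <- Matrix::colSums(m > 0)
  keep <- ngenes >= minGenes & ngenes <= maxGenes
  if (!any(keep)) warning("no nuclei pass the gene-count bounds")
  sce[, keep]
}

#' Apply both QC rules and record a report
#'
#' Applies the gene filter and the nucleus filter in a configurable order
#' (genes first by default, so per-nucleus detected-gene counts are taken on
#' the gene-filtered matrix) and stores a QC report in
#' \code{metadata(sce)$qc}: dimensions in and out, thresholds exactly as
#' applied, and the order used.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay.
#' @param minCells gene filter threshold (default 3).
#' @param minGenes,maxGenes nucleus filter bounds (defaults 200, 2000).
#' @param order \code{"genes_first"} (default) or \code{"nuclei_first"}.
#' @return The filtered experiment with the report attached.
#' @examples
#' sim <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 1))
#' sceQC <- qcFilter(sim$sce, minGenes = 0, maxGenes = Inf)
#' S4Vectors::metadata(sceQC)$qc
#' @export
qcFilter <- function(sce, minCells = 3L, minGenes = 200L, maxGenes = 2000L,
                     order = c("genes_first", "nuclei_first")) {
  order <- match.arg(order)
  nIn <- dim(sce)
  out <- if (order == "genes_first") {
    filterNuclei(filterGenes(sce, minCells), minGenes, maxGenes)
  } else {
    filterGenes(filterNuclei(sce, minGenes, maxGenes), minCells)
  }
  S4Vectors::metadata(out)$qc <- list(
    n_genes_in = nIn[1L], n_genes_out = nrow(out),
    n_cells_in = nIn[2L], n_cells_out = ncol(out),
    min_cells_per_gene = minCells,
    min_genes_per_cell = minGenes,
    max_genes_per_cell = maxGenes,
    filter_order = order)
  out
}
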