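#' Read a 10x-style MTX triplet into a SingleCellExperiment
#'
#' Loads a sparse gene x cell UMI count matrix stored as a MatrixMarket
#' coordinate file together with its aligned features and barcodes files
#' (one record per line, gzip transparently supported). Gene and cell order
#' follow the files. Duplicate gene symbols are collapsed by summing their
#' rows (with a warning); duplicate barcodes are an error.
#'
#' @param matrixPath path to the MatrixMarket (.mtx or .mtx.gz) file.
#' @param featuresPath path to the features/genes file; the gene symbol is
#'   taken from column \code{featureColumn}.
#' @param barcodesPath path to the barcodes file (one barcode per line).
#' @param featureColumn 1-based column of the features file holding the
#'   gene symbol. 10x features.tsv files carry the symbol in column 2;
#'   plain one-column gene lists use 1. Default 1.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a
#'   \code{counts} assay (sparse, nonnegative integer).
#' @examples
#' dir <- system.file("extdata", "toy10x", package = "scCommNet")
#' sce <- readMatrix10x(file.path(dir, "matrix.mtx"),
#'                      file.path(dir, "features.tsv"),
#'                      file.path(dir, "barcodes.tsv"))
#' dim(sce)
#' @importFrom Matrix readMM sparseMatrix
#' @importFrom SummarizedExperiment assay
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @export
readMatrix10x <- function(matrixPath, featuresPath, barcodesPath,
                          featureColumn = 1L) {
  m <- Matrix::readMM(.maybeGz(matrixPath))
  feat <- utils::read.table(.maybeGz(featuresPath), sep = "\t",
                            header = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  if (featureColumn > ncol(feat))
    stop("features file has ", ncol(feat), " columns; featureColumn = ",
         featureColumn)
  genes <- as.character(feat[[featureColumn]])
  barcodes <- readLines(.maybeGz(barcodesPath))
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(genes) != nrow(m))
    stop("matrix declares ", nrow(m), " genes but features file lists ",
         length(genes))
  if (length(barcodes) != ncol(m))
    stop("matrix declares ", ncol(m), " cells but barcodes file lists ",
         length(barcodes))
  if (anyDuplicated(barcodes))
    stop("duplicate cell barcodes: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (any(vals < 0)) stop("negative counts in matrix file")
  if (any(vals != round(vals))) stop("non-integer counts in matrix file")
  m <- methods::as(m, "CsparseMatrix")
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dups),
            " duplicated gene symbol(s) by summation: ",
            paste(utils::head(dups, 5L), collapse = ", "),
            if (length(dups) > 5L) ", ..." else "")
    fac <- factor(genes, levels = unique(genes))
    ind <- Matrix::sparseMatrix(i = as.integer(fac), j = seq_along(genes),
                                x = 1, dims = c(nlevels(fac), length(genes)))
    m <- methods::as(ind %*% m, "CsparseMatrix")
    genes <- levels(fac)
  }
  dimnames(m) <- list(genes, barcodes)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

.maybeGz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Attach per-cell metadata and embedding to a SingleCellExperiment
#'
#' Joins a cell table (cell id, group, condition, 2-D embedding coordinates)
#' to a count container by barcode. Every cell in the experiment must be
#' present in the table; extra table rows are dropped.
#'
#' @param sce a SingleCellExperiment with cell barcodes as column names.
#' @param cellTable data.frame with columns \code{cell_id}, \code{group},
#'   \code{condition}, \code{embed_x}, \code{embed_y}.
#' @param embedName name under which the embedding is stored in
#'   \code{reducedDims}. Default \code{"EMBED"}.
#' @return The experiment with \code{group} and \code{condition} in its
#'   colData and the embedding in \code{reducedDims}.
#' @importFrom SummarizedExperiment colData colData<-
#' @importFrom SingleCellExperiment reducedDim<-
#' @export
attachCellMeta <- function(sce, cellTable, embedName = "EMBED") {
  need <- c("cell_id", "group", "condition", "embed_x", "embed_y")
  miss <- setdiff(need, colnames(cellTable))
  if (length(miss))
    stop("cellTable is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cellTable$cell_id))
    stop("duplicate cell_id in cellTable")
  idx <- match(colnames(sce), cellTable$cell_id)
  if (anyNA(idx)) {
    absent <- colnames(sce)[is.na(idx)]
    stop("cells absent from cellTable: ",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) ", ..." else "")
  }
  emb <- as.matrix(cellTable[idx, c("embed_x", "embed_y")])
  if (any(!is.finite(emb)))
    stop("embedding coordinates must be finite")
  rownames(emb) <- colnames(sce)
  SummarizedExperiment::colData(sce)$group <-
    as.character(cellTable$group[idx])
  SummarizedExperiment::colData(sce)$condition <-
    as.character(cellTable$condition[idx])
  SingleCellExperiment::reducedDim(sce, embedName) <- emb
  sce
}

#' Read a cell-metadata table
#'
#' @param path TSV/CSV (optionally gzipped) with columns cell_id, group,
#'   condition, embed_x, embed_y.
#' @param sep field separator; \code{"\t"} by default.
#' @return data.frame.
#' @export
readCellTable <- function(path, sep = "\t") {
  df <- utils::read.table(.maybeGz(path), sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("cell_id", "group", "condition", "embed_x", "embed_y")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a curated ligand-receptor pair list
#'
#' Reads a two-column delimited table of (ligand gene, receptor gene)
#' symbols and returns the deduplicated ordered pair set. Direction matters.
#' The row count read and the post-deduplication count are reported via
#' \code{message()}.
#'
#' @param path delimited file (optionally gzipped); first column ligand,
#'   second column receptor.
#' @param header does the file carry a header row? Default TRUE.
#' @param sep field separator; auto-detected between comma and tab when
#'   \code{NULL} (default).
#' @return An [LRPairList-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("ligand,receptor", "COL1A1,ITGB1", "FN1,ITGB1",
#'              "COL1A1,ITGB1"), f)
#' readLRPairs(f)
#' @export
readLRPairs <- function(path, header = TRUE, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(.maybeGz(path), n = 1L)
    if (!length(first)) stop("empty ligand-receptor file: ", path)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- tryCatch(
    utils::read.table(.maybeGz(path), sep = sep, header = header,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = ""),
    error = function(e) stop("cannot parse ligand-receptor file: ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty ligand-receptor file: ", path)
  if (ncol(df) < 2L)
    stop("ligand-receptor file must have at least two columns")
  lr <- LRPairList(df[[1L]], df[[2L]])
  message("read ", nrow(df), " ligand-receptor rows; ",
          length(lr), " unique directed pairs after deduplication")
  lr
}

#' Write communication-network reports
#'
#' Serializes a [CommNetwork-class] or [DiffCommReport-class] either as a
#' fully sorted edge-list CSV (columns condition, broadcaster, receiver,
#' ligand, receptor) or as a JSON summary carrying per-ordered-pair counts
#' and totals. Output ordering is fully sorted on all key columns, so two
#' writes of the same object are byte-identical and reports diff cleanly.
#'
#' @param x a \code{CommNetwork} or \code{DiffCommReport}.
#' @param path output file path.
#' @param format \code{"csv"} (edge list) or \code{"json"} (summary).
#' @return \code{path}, invisibly.
#' @export
writeReports <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (methods::is(x, "CommNetwork")) {
    if (format == "csv") .writeEdgeCSV(.networkEdgeDF(x), path)
    else .writeJSON(.networkSummary(x), path)
  } else if (methods::is(x, "DiffCommReport")) {
    if (format == "csv") {
      cols <- c("broadcaster", "receiver", "ligand", "receptor")
      block <- function(status, ed) {
        ed <- as.data.frame(ed)
        if (nrow(ed) == 0L) return(NULL)
        cbind(status = status, ed[, cols])
      }
      df <- rbind(block("gained", x@gained), block("lost", x@lost),
                  block("persisted", x@persisted))
      if (is.null(df))
        df <- data.frame(status = character(), broadcaster = character(),
                         receiver = character(), ligand = character(),
                         receptor = character())
      df <- df[do.call(order, df), , drop = FALSE]
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else .writeJSON(.diffSummary(x), path)
  } else stop("writeReports() handles CommNetwork and DiffCommReport only")
  invisible(path)
}

.networkEdgeDF <- function(net) {
  ed <- as.data.frame(commEdges(net))
  data.frame(condition = rep(commCondition(net), nrow(ed)),
             broadcaster = ed$broadcaster, receiver = ed$receiver,
             ligand = ed$ligand, receptor = ed$receptor,
             stringsAsFactors = FALSE)
}

.writeEdgeCSV <- function(df, path) {
  df <- df[do.call(order, df), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.networkSummary <- function(net) {
  C <- pairCounts(net)
  idx <- which(C > 0, arr.ind = TRUE)
  idx <- idx[order(rownames(C)[idx[, 1L]], colnames(C)[idx[, 2L]]), ,
             drop = FALSE]
  list(condition = commCondition(net),
       threshold = net@threshold,
       n_groups = length(commNodes(net)),
       total_pairs = nrow(commEdges(net)),
       pair_counts = lapply(seq_len(nrow(idx)), function(i) {
         list(broadcaster = rownames(C)[idx[i, 1L]],
              receiver = colnames(C)[idx[i, 2L]],
              n_pairs = unname(C[idx[i, 1L], idx[i, 2L]]))
       }))
}

.diffSummary <- function(rep) {
  bp <- as.data.frame(rep@byPair)
  bp <- bp[bp$n_normal + bp$n_disease > 0, , drop = FALSE]
  bp <- bp[order(bp$broadcaster, bp$receiver), , drop = FALSE]
  zl <- as.data.frame(rep@zeroedLigands)
  zl <- zl[order(zl$group, zl$ligand), , drop = FALSE]
  list(conditions = as.list(stats::setNames(as.list(rep@conditions),
                                            c("control", "disease"))),
       totals = as.list(rep@totals),
       n_gained = nrow(rep@gained), n_lost = nrow(rep@lost),
       n_persisted = nrow(rep@persisted),
       by_pair = lapply(seq_len(nrow(bp)), function(i) as.list(bp[i, ])),
       zeroed_ligands = lapply(seq_len(nrow(zl)),
                               function(i) as.list(zl[i, ])))
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an edge-list CSV back into a data.frame
#'
#' Inverse of the CSV branch of [writeReports()] for a single network:
#' reading a written edge list reproduces the edge multiset.
#'
#' @param path CSV written by \code{writeReports(..., format = "csv")}.
#' @return data.frame with one row per edge.
#' @export
readEdgeList <- function(path) {
  utils::read.csv(.maybeGz(path), stringsAsFactors = FALSE)
}
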