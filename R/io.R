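#' Read a gene-by-cell expression matrix
#'
#' Accepts either a directory holding a Matrix Market triplet
#' (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`, as written by
#' [write_fixture()]) or the path of a dense TSV with genes as rows: first
#' column gene names, header row of cell barcodes. Duplicate gene names are
#' suffixed deterministically (".1", ".2", ...).
#'
#' @param path fixture directory or dense TSV file.
#' @return sparse genes x cells `dgCMatrix` with gene rownames and cell
#'   colnames.
#' @export
read_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes_f <- file.path(path, "genes.tsv")
    bc_f <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes_f, bc_f)) {
      if (!file.exists(f)) {
        stop(sprintf("missing fixture file '%s'", f), call. = FALSE)
      }
    }
    m <- methods::as(methods::as(Matrix::readMM(mtx), "generalMatrix"),
                     "CsparseMatrix")
    genes <- utils::read.table(genes_f, sep = "\t", header = FALSE,
                               colClasses = "character", quote = "")
    barcodes <- readLines(bc_f)
    if (nrow(genes) != nrow(m)) {
      stop(sprintf("genes.tsv has %d lines but matrix.mtx declares %d genes",
                   nrow(genes), nrow(m)), call. = FALSE)
    }
    if (length(barcodes) != ncol(m)) {
      stop(sprintf(
        "barcodes.tsv has %d lines but matrix.mtx declares %d cells",
        length(barcodes), ncol(m)), call. = FALSE)
    }
    gene_names <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
    dimnames(m) <- list(make.unique(gene_names, sep = "."), barcodes)
    m
  } else if (file.exists(path)) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             row.names = NULL, check.names = FALSE,
                             quote = "")
    gene_names <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- make.unique(gene_names, sep = ".")
    methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                            "generalMatrix"), "CsparseMatrix")
  } else {
    stop(sprintf("no such file or directory: '%s'", path), call. = FALSE)
  }
}

#' Read per-cell labels written as a two-column TSV (barcode, label)
#'
#' @param path labels.tsv path.
#' @return named character vector (names = barcodes).
#' @export
read_cell_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("labels file needs two tab-separated columns",
                          call. = FALSE)
  stats::setNames(tab[[2]], tab[[1]])
}
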