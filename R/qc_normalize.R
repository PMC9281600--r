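#' Cell quality-control thresholds
#'
#' Defaults follow the common practice for droplet scRNA-seq of this kind:
#' keep cells with at least 200 and at most 4000 detected genes and at most
#' 5% mitochondrial counts. A gene is "detected" when its count exceeds zero;
#' the mitochondrial fraction is the count share of genes whose name starts
#' with `mito_prefix`.
#'
#' @param min_genes_per_cell,max_genes_per_cell detected-gene bounds
#'   (inclusive: kept cells satisfy `min <= detected <= max`).
#' @param max_mito_fraction maximum mitochondrial count fraction (inclusive).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200L,
                          max_genes_per_cell = 4000L,
                          max_mito_fraction = 0.05,
                          mito_prefix = "MT-") {
  check_scalar(min_genes_per_cell, "min_genes_per_cell", min = 0,
               integerish = TRUE)
  if (!is.numeric(max_genes_per_cell) || length(max_genes_per_cell) != 1L ||
      is.na(max_genes_per_cell) || max_genes_per_cell < min_genes_per_cell) {
    stop("`max_genes_per_cell` must be a number >= min_genes_per_cell (Inf allowed)",
         call. = FALSE)
  }
  check_scalar(max_mito_fraction, "max_mito_fraction", min = 0, max = 1)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_genes_per_cell = max_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "QCThresholds")
}

#' Filter low-quality cells
#'
#' Removes cells failing any of the three rules in [qc_thresholds()], then
#' drops genes left with zero counts across the kept cells. A cell with zero
#' total counts has detected = 0 and mitochondrial fraction 0 (never a
#' division by zero) and fails `LOW_GENES`.
#'
#' @param counts genes x cells count matrix with gene names.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `counts` (filtered matrix) and `report`, a `QCReport`
#'   carrying `n_cells_in`, `n_cells_kept`, `n_genes_kept` and a per-cell
#'   data.frame (`barcode`, `detected_genes`, `mito_fraction`, `kept`,
#'   `reasons` — comma-joined codes from LOW_GENES, HIGH_GENES, HIGH_MITO).
#' @export
apply_qc_filters <- function(counts, thresholds = qc_thresholds()) {
  check_expression_matrix(counts, require_names = FALSE)
  stopifnot(inherits(thresholds, "QCThresholds"))
  if (nrow(counts) == 0L) stop("matrix has zero genes", call. = FALSE)
  check_expression_matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)

  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), thresholds$mito_prefix)
  mito_total <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else {
    numeric(ncol(counts))
  }
  mito_fraction <- ifelse(total > 0, mito_total / total, 0)

  low <- detected < thresholds$min_genes_per_cell
  high <- detected > thresholds$max_genes_per_cell
  himito <- mito_fraction > thresholds$max_mito_fraction
  kept <- !(low | high | himito)

  reasons <- vapply(seq_along(kept), function(i) {
    paste(c(if (low[i]) "LOW_GENES", if (high[i]) "HIGH_GENES",
            if (himito[i]) "HIGH_MITO"), collapse = ",")
  }, character(1))

  out <- counts[, kept, drop = FALSE]
  nonzero_gene <- Matrix::rowSums(out) > 0
  out <- out[nonzero_gene, , drop = FALSE]

  report <- structure(list(
    n_cells_in = ncol(counts),
    n_cells_kept = sum(kept),
    n_genes_kept = nrow(out),
    cells = data.frame(barcode = colnames(counts),
                       detected_genes = as.integer(detected),
                       mito_fraction = as.numeric(mito_fraction),
                       kept = kept, reasons = reasons,
                       stringsAsFactors = FALSE, row.names = NULL)
  ), class = "QCReport")
  list(counts = out, report = report)
}

#' Write a QC report as TSV
#' @param report a `QCReport`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "QCReport"))
  utils::write.table(report$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Log-normalize counts
#'
#' value(g, c) = ln(1 + count(g, c) / total(c) * scale_factor). Zeros map to
#' zeros, so the sparsity pattern is preserved; the transform is invariant to
#' rescaling all counts within a cell.
#'
#' @param counts genes x cells count matrix; every cell must have positive
#'   total counts (run QC first).
#' @param scale_factor library-size scaling factor (default 1e5).
#' @return normalized matrix of the same class and dimnames.
#' @export
log_normalize <- function(counts, scale_factor = 1e5) {
  check_expression_matrix(counts, require_names = FALSE)
  check_scalar(scale_factor, "scale_factor", min = .Machine$double.eps)
  total <- Matrix::colSums(counts)
  if (any(total <= 0)) {
    stop("some cells have zero total counts; run apply_qc_filters() first",
         call. = FALSE)
  }
  if (methods::is(counts, "CsparseMatrix")) {
    out <- counts
    percol <- diff(out@p)
    out@x <- log1p(out@x / rep.int(total, percol) * scale_factor)
    out
  } else {
    log1p(sweep(as_dense(counts), 2L, total, `/`) * scale_factor)
  }
}

#' Select highly variable genes
#'
#' Ranks genes by their variance in log-normalized space (descending), with
#' ties broken by gene name so the ordering is deterministic.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param n_top number of genes to return (clipped to the gene count).
#' @return character vector of gene names, most variable first.
#' @export
select_hvg <- function(normalized, n_top = 2000L) {
  check_expression_matrix(normalized)
  check_scalar(n_top, "n_top", min = 1, integerish = TRUE)
  n <- ncol(normalized)
  if (n < 2L) stop("need at least two cells to rank gene variance",
                   call. = FALSE)
  m <- Matrix::rowMeans(normalized)
  m2 <- Matrix::rowMeans(normalized^2)
  v <- (m2 - m^2) * n / (n - 1)
  ord <- order(-v, rownames(normalized), method = "radix")
  rownames(normalized)[ord][seq_len(min(n_top, nrow(normalized)))]
}

#' Principal component analysis of cells
#'
#' Centers (and by default unit-scales) each gene across cells, then computes
#' the top components of the cells x genes matrix. Component signs are fixed
#' so the largest-magnitude gene loading of each component is positive.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param genes optional gene subset (e.g. from [select_hvg()]).
#' @param n_components number of components (must not exceed
#'   `min(n_cells, n_genes)`).
#' @param scale. unit-scale genes before decomposition (zero-variance genes
#'   are left unscaled).
#' @return list with `embedding` (cells x components), `rotation` (genes x
#'   components), `sdev` and `var_explained` (fraction of total variance per
#'   retained component).
#' @export
compute_pca <- function(normalized, genes = NULL, n_components = 40L,
                        scale. = TRUE) {
  check_expression_matrix(normalized)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(normalized))
    if (length(missing) > 0) {
      stop(sprintf("genes not in matrix: %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
    normalized <- normalized[genes, , drop = FALSE]
  }
  x <- t(as_dense(normalized))  # cells x genes
  check_scalar(n_components, "n_components", min = 1, integerish = TRUE)
  if (n_components > min(dim(x))) {
    stop(sprintf("n_components (%d) exceeds min(n_cells, n_genes) = %d",
                 n_components, min(dim(x))), call. = FALSE)
  }
  ctr <- colMeans(x)
  x <- sweep(x, 2L, ctr, `-`)
  if (scale.) {
    sds <- sqrt(colSums(x^2) / (nrow(x) - 1))
    sds[sds == 0] <- 1
    x <- sweep(x, 2L, sds, `/`)
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE,
                      rank. = n_components)
  rot <- pc$rotation
  emb <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      emb[, j] <- -emb[, j]
    }
  }
  list(embedding = emb, rotation = rot, sdev = pc$sdev,
       var_explained = pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2))
}

#' Graph-based cell clustering
#'
#' Builds a shared-nearest-neighbor graph in embedding space (Jaccard overlap
#' of k-nearest-neighbor sets, pruned below `prune`) and partitions it by
#' Leiden modularity optimization at the given resolution. Labels are
#' 0..K-1, ordered by decreasing cluster size.
#'
#' @param embedding cells x components matrix (or the list returned by
#'   [compute_pca()]).
#' @param resolution modularity resolution; larger values give more clusters.
#' @param n_neighbors neighborhood size (includes the cell itself).
#' @param prune discard SNN edges with Jaccard overlap below this value.
#' @param seed RNG seed for the community search.
#' @return integer vector of cluster labels named by cell.
#' @export
cluster_cells <- function(embedding, resolution = 1.5, n_neighbors = 20L,
                          prune = 1 / 15, seed = 0L) {
  if (is.list(embedding) && !is.null(embedding$embedding)) {
    embedding <- embedding$embedding
  }
  stopifnot(is.matrix(embedding))
  if (!all(is.finite(embedding))) stop("embedding must be finite",
                                       call. = FALSE)
  check_scalar(resolution, "resolution", min = .Machine$double.eps)
  n <- nrow(embedding)
  if (n < n_neighbors + 1L) {
    stop(sprintf("need more than n_neighbors (%d) cells, got %d",
                 n_neighbors, n), call. = FALSE)
  }
  d <- as.matrix(stats::dist(embedding))
  # k nearest including self; ties resolved by index order for determinism
  nn <- t(apply(d, 1L, function(row) {
    order(row, method = "radix")[seq_len(n_neighbors)]
  }))
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = n_neighbors),
    j = as.vector(t(nn)), x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(adj)
  snn <- inter / (2 * n_neighbors - inter)
  snn <- methods::as(methods::as(snn, "generalMatrix"), "CsparseMatrix")
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  comm <- local_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 10L))
  member <- igraph::membership(comm)
  sizes <- table(member)
  new_id <- stats::setNames(seq_along(sizes) - 1L,
                            names(sort(sizes, decreasing = TRUE)))
  out <- as.integer(new_id[as.character(member)])
  names(out) <- rownames(embedding)
  out
}

#' Marker table for marker-based annotation
#'
#' A named list mapping a cell-type name to its marker genes. The default
#' carries the osteochondral-lineage markers used for periosteum-derived
#' cells: mitotic cells (MKI67, AURKA, CDC20, CDK1), pro-hematopoietic
#' osteochondral progenitors (ANGPTL7), BMPR2+ osteochondral progenitors
#' (POSTN, BMPR2), CD34+ osteochondral progenitors (POSTN, CD34) and
#' osteochondral progenitors (POSTN, PDGFRB, THY1).
#'
#' @param markers named list (type -> character vector of marker genes).
#' @return validated `MarkerTable` (named list).
#' @export
marker_table <- function(markers = list(
    "mitotic cell" = c("MKI67", "AURKA", "CDC20", "CDK1"),
    "pro-hematopoietic osteochondral progenitor" = "ANGPTL7",
    "BMPR2+ osteochondral progenitor" = c("POSTN", "BMPR2"),
    "CD34+ osteochondral progenitor" = c("POSTN", "CD34"),
    "osteochondral progenitor" = c("POSTN", "PDGFRB", "THY1"))) {
  if (length(markers) == 0L || is.null(names(markers)) ||
      any(names(markers) == "")) {
    stop("marker table must be a non-empty named list", call. = FALSE)
  }
  for (ty in names(markers)) {
    if (length(markers[[ty]]) == 0L || anyDuplicated(markers[[ty]])) {
      stop(sprintf("markers for '%s' must be non-empty and unique", ty),
           call. = FALSE)
    }
  }
  structure(markers, class = "MarkerTable")
}

#' Annotate clusters with cell types from marker expression
#'
#' Scores each (cluster, type) pair as the mean over the type's markers of
#' (fraction of cluster cells detecting the marker) x (mean normalized marker
#' expression in the cluster, min-max scaled across clusters). Each cluster
#' gets the highest-scoring type; ties go to the type listed first in the
#' marker table. Cells inherit their cluster's type.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param clusters per-cell cluster labels (from [cluster_cells()]).
#' @param markers a [marker_table()].
#' @return list with `cluster_types` (named by cluster label), `cell_types`
#'   (named by cell) and `scores` (clusters x types matrix).
#' @export
annotate_cell_types <- function(normalized, clusters,
                                markers = marker_table()) {
  check_expression_matrix(normalized)
  if (!inherits(markers, "MarkerTable")) markers <- marker_table(markers)
  if (length(clusters) != ncol(normalized)) {
    stop("clusters length must equal the number of cells", call. = FALSE)
  }
  present <- lapply(names(markers), function(ty) {
    markers[[ty]][markers[[ty]] %in% rownames(normalized)]
  })
  names(present) <- names(markers)
  missing <- unlist(lapply(names(markers), function(ty) {
    setdiff(markers[[ty]], present[[ty]])
  }))
  if (length(missing) > 0) {
    warning(sprintf("dropping markers absent from the matrix: %s",
                    paste(unique(missing), collapse = ", ")), call. = FALSE)
  }
  if (all(lengths(present) == 0L)) {
    stop("no marker of any type is present in the matrix", call. = FALSE)
  }
  cl_levels <- sort(unique(clusters))
  types <- names(markers)
  marker_genes <- unique(unlist(present, use.names = FALSE))
  x <- as_dense(normalized[marker_genes, , drop = FALSE])

  frac <- matrix(0, length(marker_genes), length(cl_levels),
                 dimnames = list(marker_genes, as.character(cl_levels)))
  mexp <- frac
  for (ci in seq_along(cl_levels)) {
    idx <- which(clusters == cl_levels[ci])
    frac[, ci] <- rowMeans(x[, idx, drop = FALSE] > 0)
    mexp[, ci] <- rowMeans(x[, idx, drop = FALSE])
  }
  # min-max scale mean expression per gene across clusters; a gene flat
  # across clusters contributes its detection fraction unmodulated
  rng <- apply(mexp, 1L, range)
  span <- rng[2, ] - rng[1, ]
  scaled <- (mexp - rng[1, ]) / ifelse(span > 0, span, 1)
  scaled[span == 0, ] <- 1

  scores <- matrix(NA_real_, length(cl_levels), length(types),
                   dimnames = list(as.character(cl_levels), types))
  for (ty in types) {
    g <- present[[ty]]
    scores[, ty] <- if (length(g) == 0L) {
      -Inf
    } else {
      colMeans((frac * scaled)[g, , drop = FALSE])
    }
  }
  best <- apply(scores, 1L, which.max)  # first max wins: marker-table order
  cluster_types <- stats::setNames(types[best], as.character(cl_levels))
  cell_types <- stats::setNames(cluster_types[as.character(clusters)],
                                colnames(normalized))
  list(cluster_types = cluster_types, cell_types = cell_types,
       scores = scores)
}
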