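#' Rank genes within each cell
#'
#' Within each cell, the most highly expressed gene gets rank 1. Ties —
#' ubiquitous in zero-inflated count data — are broken by a seeded uniform
#' shuffle so the ranking is unbiased yet reproducible; every column is a
#' full permutation of 1..n_genes.
#'
#' @param matrix genes x cells expression matrix (counts or normalized;
#'   the downstream score is invariant to any within-cell monotone
#'   transform).
#' @param seed RNG seed for tie-breaking.
#' @return integer genes x cells rank matrix.
#' @export
rank_genes_per_cell <- function(matrix, seed = 0L) {
  check_expression_matrix(matrix, require_names = FALSE)
  x <- as_dense(matrix)
  if (!all(is.finite(x))) stop("matrix must be finite", call. = FALSE)
  # the tie-break stream is keyed per cell (by barcode when available), so
  # reordering cells permutes the rank columns without changing any of them
  keys <- if (is.null(colnames(x))) {
    as.character(seq_len(ncol(x)))
  } else {
    colnames(x)
  }
  out <- vapply(seq_len(ncol(x)), function(j) {
    cell_seed <- (as.integer(seed) %% 1000003L) * 2038L + string_seed(keys[j])
    local_seed(cell_seed %% .Machine$integer.max,
               as.integer(rank(-x[, j], ties.method = "random")))
  }, integer(nrow(x)))
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Internal: resolve a regulon's scoreable gene set against a rank matrix.
#' @noRd
regulon_gene_set <- function(ranks, reg) {
  genes <- unique(c(reg$tf_name, reg$targets))
  present <- genes[genes %in% rownames(ranks)]
  if (length(present) == 0L) {
    stop(sprintf("no gene of regulon '%s' is present in the matrix",
                 reg$tf_name), call. = FALSE)
  }
  if (length(present) < length(genes)) {
    warning(sprintf("regulon '%s': dropping %d gene(s) absent from matrix",
                    reg$tf_name, length(genes) - length(present)),
            call. = FALSE)
  }
  present
}

#' Regulon activity score per cell (area under the recovery curve)
#'
#' For each cell, walk down the cell's gene ranking over the top
#' `ceiling(top_fraction * n_genes)` positions and accumulate how many
#' regulon genes have been recovered at each step; the score is the area
#' under this step curve divided by the maximum achievable area for the
#' regulon's (present) gene count, so a score of 1 — all regulon genes packed
#' at the very top — is attainable for any regulon size.
#'
#' @param ranks rank matrix from [rank_genes_per_cell()].
#' @param reg a [regulon()]; the scored gene set is the TF plus its targets
#'   (genes absent from the matrix are dropped with a warning).
#' @param top_fraction fraction of top-ranked genes the curve is evaluated
#'   over (default 0.05).
#' @return numeric per-cell score vector in [0, 1].
#' @export
aucell_score <- function(ranks, reg, top_fraction = 0.05) {
  stopifnot(inherits(reg, "Regulon"))
  check_scalar(top_fraction, "top_fraction", min = 1e-12, max = 1)
  genes <- regulon_gene_set(ranks, reg)
  k <- ceiling(top_fraction * nrow(ranks))
  r <- as_dense(ranks[genes, , drop = FALSE])
  # a regulon gene at rank r contributes to the curve at positions r..k
  area <- colSums(pmax(k - r + 1, 0))
  m <- length(genes)
  max_area <- sum(pmin(seq_len(k), m))
  unname(area / max_area)
}

#' Score every regulon in every cell
#'
#' @param matrix genes x cells expression matrix.
#' @param regulons a `RegulonSet`.
#' @param top_fraction see [aucell_score()].
#' @param seed tie-break seed for the shared gene ranking.
#' @return regulons x cells activity matrix (rows in `RegulonSet` order,
#'   named by TF), all values in [0, 1]; `top_fraction` stored as an
#'   attribute.
#' @export
score_all <- function(matrix, regulons, top_fraction = 0.05, seed = 0L) {
  stopifnot(inherits(regulons, "RegulonSet"))
  if (length(regulons) == 0L) stop("empty RegulonSet", call. = FALSE)
  ranks <- rank_genes_per_cell(matrix, seed = seed)
  out <- t(vapply(regulons, function(reg) {
    aucell_score(ranks, reg, top_fraction = top_fraction)
  }, numeric(ncol(ranks))))
  colnames(out) <- colnames(matrix)
  attr(out, "top_fraction") <- top_fraction
  out
}

#' Internal: deterministic one-dimensional 2-means (Lloyd, min/max init).
#' @noRd
two_means_1d <- function(x) {
  c1 <- min(x); c2 <- max(x)
  for (iter in 1:100) {
    to2 <- abs(x - c2) < abs(x - c1)
    n1 <- mean(x[!to2]); n2 <- mean(x[to2])
    if (isTRUE(all.equal(c(c1, c2), c(n1, n2), tolerance = 1e-12))) break
    c1 <- n1; c2 <- n2
  }
  c(c1, c2)
}

#' Binarize regulon activity
#'
#' Decides, per regulon, which cells count as "activated" (score strictly
#' above a per-regulon threshold). `bimodal_midpoint` fits two components to
#' the score distribution (deterministic one-dimensional 2-means) and
#' thresholds at the midpoint of the component means, falling back to the
#' 0.99 score quantile when the row is degenerate (fewer than two distinct
#' values). `global_quantile` thresholds each row at its `quantile` score
#' quantile.
#'
#' @param activity regulons x cells activity matrix.
#' @param method "bimodal_midpoint" (default) or "global_quantile".
#' @param quantile quantile used by `global_quantile` and by the degenerate
#'   fallback.
#' @return list with `binary` (logical matrix), `thresholds` (per regulon)
#'   and `method`.
#' @export
binarize_activity <- function(activity,
                              method = c("bimodal_midpoint",
                                         "global_quantile"),
                              quantile = 0.99) {
  method <- match.arg(method)
  check_scalar(quantile, "quantile", min = 0, max = 1)
  activity <- as_dense(activity)
  thresholds <- apply(activity, 1L, function(row) {
    if (method == "global_quantile") {
      stats::quantile(row, quantile, names = FALSE)
    } else if (length(unique(row)) < 2L) {
      stats::quantile(row, quantile, names = FALSE)  # degenerate fallback
    } else {
      mean(two_means_1d(row))
    }
  })
  binary <- sweep(activity, 1L, thresholds, `>`)
  list(binary = binary, thresholds = thresholds, method = method)
}

#' Keep regulons activated in more than a minimum fraction of cells
#'
#' @param binary logical regulons x cells matrix (from
#'   [binarize_activity()]).
#' @param min_cell_fraction strict lower bound on the activated-cell
#'   fraction (default 0.01: "more than 1% of cells").
#' @param regulons optional `RegulonSet` to subset alongside.
#' @return list with `kept` (regulon names), `regulons` (subset, if
#'   supplied) and `report` (data.frame: regulon, active_fraction, kept).
#' @export
filter_active_regulons <- function(binary, min_cell_fraction = 0.01,
                                   regulons = NULL) {
  check_scalar(min_cell_fraction, "min_cell_fraction", min = 0, max = 1)
  frac <- rowMeans(binary)
  keep <- frac > min_cell_fraction  # strict: exactly at the cutoff is out
  report <- data.frame(regulon = rownames(binary),
                       active_fraction = as.numeric(frac),
                       kept = keep, stringsAsFactors = FALSE,
                       row.names = NULL)
  out <- list(kept = rownames(binary)[keep], report = report)
  if (!is.null(regulons)) {
    stopifnot(inherits(regulons, "RegulonSet"))
    out$regulons <- regulon_set(unname(regulons[names(regulons) %in%
                                                  out$kept]),
                                provenance = attr(regulons, "provenance"))
  }
  out
}
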