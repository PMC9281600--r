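#' Pairwise Pearson correlation of regulon activity profiles
#'
#' @param activity regulons x cells activity matrix (at least two cells).
#' @return symmetric regulons x regulons correlation matrix with unit
#'   diagonal; a zero-variance activity row gets correlation 0 with every
#'   other regulon (with a warning).
#' @export
pcc_matrix <- function(activity) {
  activity <- as_dense(activity)
  if (ncol(activity) < 2L) {
    stop("need at least two cells to correlate activity profiles",
         call. = FALSE)
  }
  sds <- apply(activity, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance activity row(s) set to 0 correlation: %s",
                    paste(rownames(activity)[sds == 0], collapse = ", ")),
            call. = FALSE)
  }
  pcc <- suppressWarnings(stats::cor(t(activity)))
  pcc[is.na(pcc)] <- 0
  diag(pcc) <- 1
  pcc
}

#' Connection specificity index matrix
#'
#' CSI(A, B) is the fraction, over all n regulons C (A and B included), of
#' regulons whose correlation with both A and B falls below PCC(A, B) minus
#' the margin. It rewards pairs whose co-activity is specific to each other
#' rather than shared promiscuously; the self-terms C = A and C = B have
#' correlation 1 and fail the condition naturally. The diagonal is set to 1.
#'
#' @param pcc symmetric correlation matrix from [pcc_matrix()].
#' @param margin correlation margin (default 0.05).
#' @return symmetric CSI matrix with entries in [0, 1] and unit diagonal.
#' @export
csi_matrix <- function(pcc, margin = 0.05) {
  stopifnot(is.matrix(pcc))
  if (!isSymmetric(unname(pcc), tol = 1e-9)) {
    stop("pcc must be symmetric", call. = FALSE)
  }
  check_scalar(margin, "margin", min = 0, max = 2 - 1e-12)
  n <- nrow(pcc)
  csi <- matrix(0, n, n, dimnames = dimnames(pcc))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b < a) next
      cut <- pcc[a, b] - margin
      csi[a, b] <- csi[b, a] <- sum(pcc[a, ] < cut & pcc[b, ] < cut) / n
    }
  }
  diag(csi) <- 1
  csi
}

#' Cut the CSI matrix into regulon modules
#'
#' Agglomerative hierarchical clustering (default complete linkage) on the
#' Euclidean distances between CSI rows, cut into exactly `n_modules`
#' modules. Modules are renamed M1..Mk in decreasing size order, ties broken
#' by the lexicographically smallest member name, so the labeling is
#' deterministic and invariant to regulon order.
#'
#' @param csi CSI matrix from [csi_matrix()].
#' @param n_modules number of modules to cut (default 8).
#' @param linkage `stats::hclust` agglomeration method (default "complete").
#' @return list of class `ModulePartition` with `modules` (named character
#'   vector regulon -> module id), `sizes` (named integer vector) and
#'   `members` (list module -> regulon names).
#' @export
cluster_modules <- function(csi, n_modules = 8L, linkage = "complete") {
  stopifnot(is.matrix(csi))
  check_scalar(n_modules, "n_modules", min = 1, integerish = TRUE)
  if (n_modules > nrow(csi)) {
    stop(sprintf("n_modules (%d) exceeds the number of regulons (%d)",
                 n_modules, nrow(csi)), call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(csi), method = linkage)
  raw <- stats::cutree(hc, k = n_modules)
  groups <- split(names(raw), raw)
  sizes <- lengths(groups)
  first_member <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-sizes, first_member, method = "radix")
  groups <- groups[ord]
  names(groups) <- sprintf("M%d", seq_along(groups))
  modules <- stats::setNames(
    rep(names(groups), lengths(groups)),
    unlist(groups, use.names = FALSE))[names(raw)]
  structure(list(modules = modules,
                 sizes = stats::setNames(lengths(groups), names(groups)),
                 members = groups),
            class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
  cat(sprintf("ModulePartition: %d regulons in %d modules (%s)\n",
              length(x$modules), length(x$sizes),
              paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Module activity per cell type
#'
#' The activity of a module in a cell type is the average of the activity
#' scores of the module's member regulons across all cells of that type.
#'
#' @param activity regulons x cells activity matrix.
#' @param partition a [cluster_modules()] partition covering all activity
#'   rows.
#' @param cell_types per-cell type labels (no empty types allowed).
#' @return list with `scores` (modules x cell-types matrix) and
#'   `top_types` (per module, a data.frame of cell types sorted by score
#'   descending, ties broken by type name).
#' @export
module_activity <- function(activity, partition, cell_types) {
  stopifnot(inherits(partition, "ModulePartition"))
  activity <- as_dense(activity)
  if (!all(rownames(activity) %in% names(partition$modules))) {
    stop("partition does not cover every activity row", call. = FALSE)
  }
  if (ncol(activity) != length(cell_types)) {
    stop("cell_types length must equal the number of cells", call. = FALSE)
  }
  labels <- as.character(cell_types)
  types <- sort(unique(labels))
  if (any(table(labels) == 0)) stop("empty cell type", call. = FALSE)
  mods <- names(partition$sizes)
  scores <- matrix(NA_real_, length(mods), length(types),
                   dimnames = list(mods, types))
  for (m in mods) {
    members <- intersect(partition$members[[m]], rownames(activity))
    sub <- activity[members, , drop = FALSE]
    for (ty in types) {
      scores[m, ty] <- mean(sub[, labels == ty, drop = FALSE])
    }
  }
  top_types <- lapply(mods, function(m) {
    ord <- order(-scores[m, ], colnames(scores), method = "radix")
    data.frame(cell_type = colnames(scores)[ord],
               score = scores[m, ord], rank = seq_along(ord),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  list(scores = scores, top_types = stats::setNames(top_types, mods))
}
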