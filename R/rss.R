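#' Internal: validate a probability vector (non-negative, sums to 1).
#' @noRd
check_probability_vector <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2, using base-2
#' logarithms so the value lies in [0, 1]: 0 for identical distributions, 1
#' for disjoint supports. Terms with p_i = 0 contribute 0.
#'
#' @param p,q equal-length probability vectors (non-negative, summing to 1).
#' @return JSD in [0, 1].
#' @export
#' @examples
#' jsd(c(0.5, 0.5), c(0.5, 0.5))  # 0
#' jsd(c(1, 0), c(0, 1))          # 1
jsd <- function(p, q) {
  if (length(p) != length(q)) {
    stop("p and q must have equal length", call. = FALSE)
  }
  check_probability_vector(p, "p")
  check_probability_vector(q, "q")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity score for one cell type
#'
#' The regulon's per-cell activity is normalized to sum to 1; the cell type
#' is encoded as a 0/1 indicator also normalized to sum to 1; the score is
#' 1 - sqrt(JSD) between the two distributions. The smaller the divergence,
#' the larger the score: 1 means the activity is uniform over exactly the
#' type's cells, 0 means activity and type have disjoint support.
#'
#' @param activity_row per-cell non-negative activity scores (positive sum).
#' @param type_indicator per-cell 0/1 membership (at least one 1); a logical
#'   vector is accepted.
#' @return RSS in [0, 1].
#' @export
regulon_specificity_score <- function(activity_row, type_indicator) {
  type_indicator <- as.numeric(type_indicator)
  if (length(activity_row) != length(type_indicator)) {
    stop("activity_row and type_indicator must have equal length",
         call. = FALSE)
  }
  if (any(activity_row < 0) || any(!is.finite(activity_row))) {
    stop("activity_row must be finite and non-negative", call. = FALSE)
  }
  if (sum(activity_row) <= 0) {
    stop("all-zero activity row: RSS is undefined", call. = FALSE)
  }
  if (!all(type_indicator %in% c(0, 1))) {
    stop("type_indicator must be 0/1", call. = FALSE)
  }
  if (sum(type_indicator) == 0) {
    stop("empty cell type: RSS is undefined", call. = FALSE)
  }
  p <- activity_row / sum(activity_row)
  q <- type_indicator / sum(type_indicator)
  1 - sqrt(jsd(p, q))
}

#' Regulon specificity scores for all regulons and cell types
#'
#' @param activity regulons x cells activity matrix (rows named by TF).
#' @param cell_types per-cell type labels covering every cell (character or
#'   factor; factor level order is kept, otherwise types are sorted).
#' @return regulons x cell-types matrix of RSS values in [0, 1]; all-zero
#'   activity rows are dropped with a warning.
#' @export
rss_matrix <- function(activity, cell_types) {
  activity <- as_dense(activity)
  if (ncol(activity) != length(cell_types)) {
    stop("cell_types length must equal the number of cells", call. = FALSE)
  }
  if (anyNA(cell_types)) stop("cell_types must not contain NA",
                              call. = FALSE)
  types <- if (is.factor(cell_types)) {
    levels(droplevels(cell_types))
  } else if (is.character(cell_types)) {
    sort(unique(cell_types))
  } else {
    stop("unknown label encoding: use character or factor cell types",
         call. = FALSE)
  }
  zero <- rowSums(activity) <= 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero activity row(s): %s", sum(zero),
                    paste(rownames(activity)[zero], collapse = ", ")),
            call. = FALSE)
    activity <- activity[!zero, , drop = FALSE]
  }
  labels <- as.character(cell_types)
  out <- matrix(NA_real_, nrow(activity), length(types),
                dimnames = list(rownames(activity), types))
  for (ty in types) {
    ind <- as.numeric(labels == ty)
    for (i in seq_len(nrow(activity))) {
      out[i, ty] <- regulon_specificity_score(activity[i, ], ind)
    }
  }
  out
}

#' Top-k most specific regulons per cell type
#'
#' @param table regulons x cell-types RSS matrix (from [rss_matrix()]).
#' @param k list length per type (clipped to the regulon count).
#' @return named list (per type) of data.frames with `regulon`, `rss`,
#'   `rank`; sorted by RSS descending, ties broken by regulon name.
#' @export
top_regulons_per_type <- function(table, k = 5L) {
  check_scalar(k, "k", min = 1, integerish = TRUE)
  k <- min(k, nrow(table))
  out <- lapply(colnames(table), function(ty) {
    ord <- order(-table[, ty], rownames(table), method = "radix")
    idx <- ord[seq_len(k)]
    data.frame(regulon = rownames(table)[idx], rss = table[idx, ty],
               rank = seq_len(k), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  stats::setNames(out, colnames(table))
}
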