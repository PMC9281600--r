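#' VEGF-positivity gate rule
#'
#' A cell is gated POSITIVE when at least `min_positive` of the marker genes
#' have expression strictly above `positivity_threshold`. The default rule —
#' at least two of VEGFA, VEGFB, VEGFC detected on raw counts — defines
#' angiogenesis-related (VEGF+) cells.
#'
#' @param marker_genes ordered marker gene names.
#' @param min_positive minimum number of positive markers.
#' @param positivity_threshold expression value a marker must exceed to count
#'   as positive (0 on raw counts = any detection; normalization preserves
#'   zeros, so the default is equivalent on normalized values).
#' @return list of class `GateRule`.
#' @export
gate_rule <- function(marker_genes = c("VEGFA", "VEGFB", "VEGFC"),
                      min_positive = 2L, positivity_threshold = 0) {
  if (length(marker_genes) < 1L || anyDuplicated(marker_genes)) {
    stop("marker_genes must be non-empty and unique", call. = FALSE)
  }
  check_scalar(min_positive, "min_positive", min = 1,
               max = length(marker_genes), integerish = TRUE)
  check_scalar(positivity_threshold, "positivity_threshold")
  structure(list(marker_genes = marker_genes,
                 min_positive = as.integer(min_positive),
                 positivity_threshold = positivity_threshold),
            class = "GateRule")
}

#' Classify cells as VEGF+ / VEGF-
#'
#' @param counts genes x cells matrix carrying all marker genes (a missing
#'   marker is an error, not a silent drop).
#' @param rule a [gate_rule()].
#' @return data.frame with `barcode`, `n_positive_markers` and `status`
#'   ("POSITIVE" / "NEGATIVE").
#' @export
#' @examples
#' m <- matrix(c(3, 1, 0, 0, 0, 0), nrow = 3,
#'             dimnames = list(c("VEGFA", "VEGFB", "VEGFC"), c("c1", "c2")))
#' classify_vegf(m)
classify_vegf <- function(counts, rule = gate_rule()) {
  check_expression_matrix(counts)
  stopifnot(inherits(rule, "GateRule"))
  absent <- setdiff(rule$marker_genes, rownames(counts))
  if (length(absent) > 0) {
    stop(sprintf("gate marker gene(s) absent from matrix: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  sub <- as_dense(counts[rule$marker_genes, , drop = FALSE])
  n_pos <- colSums(sub > rule$positivity_threshold)
  status <- ifelse(n_pos >= rule$min_positive, "POSITIVE", "NEGATIVE")
  data.frame(barcode = colnames(counts),
             n_positive_markers = as.integer(n_pos),
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-tabulate gate status against cell types
#'
#' @param status per-cell status vector ("POSITIVE"/"NEGATIVE") or the
#'   data.frame from [classify_vegf()].
#' @param cell_types per-cell type labels (same length/order).
#' @return integer matrix, cell types x c("POSITIVE", "NEGATIVE"); entries
#'   sum to the number of cells.
#' @export
gate_summary <- function(status, cell_types) {
  if (is.data.frame(status)) status <- status$status
  if (length(status) != length(cell_types)) {
    stop("status and cell_types must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(status), c("POSITIVE", "NEGATIVE"))
  if (length(bad) > 0) {
    stop(sprintf("unknown gate status value(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  types <- sort(unique(as.character(cell_types)))
  out <- matrix(0L, length(types), 2L,
                dimnames = list(types, c("POSITIVE", "NEGATIVE")))
  for (i in seq_along(status)) {
    out[as.character(cell_types[i]), status[i]] <-
      out[as.character(cell_types[i]), status[i]] + 1L
  }
  out
}
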