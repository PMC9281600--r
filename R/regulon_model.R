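#' Construct a regulon
#'
#' A regulon is a transcription factor together with the non-empty set of
#' target genes it is inferred to regulate — the unit scored per cell by the
#' recovery-curve activity score.
#'
#' @param tf_name TF gene name.
#' @param targets character vector of target genes (TF excluded, unique).
#' @param weights optional per-target numeric weights (same length).
#' @return list of class `Regulon`.
#' @export
regulon <- function(tf_name, targets, weights = NULL) {
  if (!is.character(tf_name) || length(tf_name) != 1L || tf_name == "") {
    stop("tf_name must be a single non-empty gene name", call. = FALSE)
  }
  if (length(targets) == 0L) {
    stop(sprintf("regulon '%s' has an empty target set", tf_name),
         call. = FALSE)
  }
  if (anyDuplicated(targets)) {
    stop(sprintf("regulon '%s' has duplicate targets", tf_name),
         call. = FALSE)
  }
  if (tf_name %in% targets) {
    stop(sprintf("regulon '%s' lists its own TF among the targets", tf_name),
         call. = FALSE)
  }
  if (!is.null(weights) && length(weights) != length(targets)) {
    stop("weights must match targets in length", call. = FALSE)
  }
  structure(list(tf_name = tf_name, targets = as.character(targets),
                 weights = weights), class = "Regulon")
}

#' Construct a set of regulons
#'
#' @param regulons list of [regulon()] objects with unique TF names.
#' @param provenance "imported" (read from file) or "built" (derived by the
#'   correlation-based builder; never motif-validated).
#' @return list of class `RegulonSet`; elements named by TF.
#' @export
regulon_set <- function(regulons, provenance = c("imported", "built")) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(regulons))
  for (r in regulons) {
    if (!inherits(r, "Regulon")) stop("all elements must be Regulon objects",
                                      call. = FALSE)
  }
  tfs <- vapply(regulons, `[[`, character(1), "tf_name")
  if (anyDuplicated(tfs)) {
    stop(sprintf("duplicate TF name(s): %s",
                 paste(unique(tfs[duplicated(tfs)]), collapse = ", ")),
         call. = FALSE)
  }
  names(regulons) <- tfs
  structure(regulons, provenance = provenance, class = "RegulonSet")
}

#' @export
print.RegulonSet <- function(x, ...) {
  sizes <- vapply(x, function(r) length(r$targets), integer(1))
  cat(sprintf("RegulonSet of %d regulons (%s); target-set sizes %s..%s\n",
              length(x), attr(x, "provenance"),
              if (length(x)) min(sizes) else NA,
              if (length(x)) max(sizes) else NA))
  invisible(x)
}

#' Read regulons from a GMT-like file
#'
#' One line per regulon, tab-separated: TF name, description, then one or
#' more target genes. Duplicate TF lines and target-less lines are errors.
#'
#' @param path input file.
#' @param provenance provenance tag to attach (default "imported").
#' @return a `RegulonSet`.
#' @export
read_regulons <- function(path, provenance = "imported") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  regs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("line %d of '%s' has no target genes (TF '%s')",
                   i, path, fields[1]), call. = FALSE)
    }
    regs[[i]] <- regulon(fields[1], fields[-(1:2)])
  }
  regulon_set(regs, provenance = provenance)
}

#' Write regulons to a GMT-like file
#'
#' @param regulons a `RegulonSet`.
#' @param path output file.
#' @export
write_regulons <- function(regulons, path) {
  stopifnot(inherits(regulons, "RegulonSet"))
  lines <- vapply(regulons, function(r) {
    paste(c(r$tf_name, sprintf("%d targets", length(r$targets)), r$targets),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build regulons by TF-target co-expression
#'
#' A simplified, correlation-based regulon builder: for each TF, the targets
#' are the genes whose Pearson correlation with the TF (on log-normalized
#' values) reaches `r_threshold`, ranked by correlation (ties broken by gene
#' name) and truncated to `max_targets`; TFs with fewer than `min_targets`
#' surviving targets are dropped. This stand-in replaces motif-based target
#' pruning, which needs external cis-regulatory databases; the returned set
#' is tagged `provenance = "built"` so its regulons are never presented as
#' motif-validated.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param tf_list candidate TF gene names (must be present in the matrix).
#' @param min_targets minimum surviving target count (default 10).
#' @param max_targets maximum targets kept per TF (default 918).
#' @param r_threshold minimum Pearson correlation (default 0.3). A gene or TF
#'   with zero variance has undefined correlation, treated as 0.
#' @return a `RegulonSet` with provenance "built" (possibly empty).
#' @export
build_coexpression_regulons <- function(normalized, tf_list,
                                        min_targets = 10L,
                                        max_targets = 918L,
                                        r_threshold = 0.3) {
  check_expression_matrix(normalized)
  if (length(tf_list) == 0L) stop("tf_list is empty", call. = FALSE)
  absent <- setdiff(tf_list, rownames(normalized))
  if (length(absent) > 0) {
    stop(sprintf("TF(s) absent from matrix: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  check_scalar(min_targets, "min_targets", min = 1, integerish = TRUE)
  check_scalar(max_targets, "max_targets", min = min_targets,
               integerish = TRUE)

  x <- as_dense(normalized)
  xt <- t(x)  # cells x genes, for vectorized correlation
  regs <- list()
  for (tf in tf_list) {
    tf_vec <- xt[, tf]
    if (stats::sd(tf_vec) == 0) next  # undefined correlation -> no targets
    r <- suppressWarnings(as.vector(stats::cor(tf_vec, xt)))
    names(r) <- colnames(xt)
    r[is.na(r)] <- 0  # zero-variance genes
    r <- r[setdiff(names(r), tf)]
    hits <- r[r >= r_threshold]
    if (length(hits) == 0L) next
    ord <- order(-hits, names(hits), method = "radix")
    hits <- hits[ord][seq_len(min(length(hits), max_targets))]
    if (length(hits) < min_targets) next
    regs[[tf]] <- regulon(tf, names(hits), weights = unname(hits))
  }
  regulon_set(unname(regs), provenance = "built")
}
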