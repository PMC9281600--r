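#' Default plan for planted regulons
#'
#' One transcription-factor regulon per cell type. Each planted regulon is a
#' TF plus `n_targets` target genes whose negative-binomial means are elevated
#' `effect_size`-fold in the cells of `target_cell_type`.
#'
#' @param n_types number of cell types (one regulon each).
#' @param n_targets targets per regulon.
#' @param effect_size fold elevation of the TF and its targets in the target
#'   type; must exceed 1.
#' @return data.frame with columns `tf_name`, `n_targets`, `target_cell_type`
#'   (1-based type index) and `effect_size`.
#' @export
default_regulon_plan <- function(n_types = 5L, n_targets = 40L,
                                 effect_size = 6) {
  data.frame(
    tf_name = sprintf("TF%d", seq_len(n_types)),
    n_targets = as.integer(n_targets),
    target_cell_type = seq_len(n_types),
    effect_size = effect_size,
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic single-cell dataset generator
#'
#' The generator emulates the statistical structure the downstream stages
#' assume: a handful of discrete cell types of very unequal sizes, per-cell
#' library-size variation, a small set of mitochondrially named genes, a
#' planted TF regulon per type (TF and targets co-elevated in that type),
#' three VEGF-like marker genes expressed in random cell subsets, and
#' independent dropout.
#'
#' @param n_cells,n_genes dataset dimensions (genes x cells).
#' @param type_proportions positive fractions summing to 1, one per cell type.
#'   The default mirrors a five-type population with two dominant types and a
#'   ~1% minority type.
#' @param n_mito_genes number of genes carrying the mitochondrial name prefix.
#' @param regulon_plan data.frame as returned by [default_regulon_plan()].
#' @param vegf_marker_plan list with `markers` (three gene names) and
#'   `positive_fraction` (scalar or one value per marker): each marker is
#'   planted as "on" in an independent Bernoulli fraction of cells.
#' @param base_mean baseline negative-binomial mean per gene per cell (before
#'   library-size and effect scaling).
#' @param dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2).
#' @param dropout_rate independent probability, in [0, 1), of zeroing any
#'   count after sampling.
#' @param marker_mean negative-binomial mean of a planted-positive marker
#'   gene; high by default so planted positivity is essentially always
#'   detected.
#' @param lib_sd standard deviation of log-normal per-cell library-size
#'   factors.
#' @param mito_scale,mito_scale_cell_fraction scale the mitochondrial gene
#'   means by `mito_scale` in a random `mito_scale_cell_fraction` of cells,
#'   to create QC failures on demand.
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @param seed RNG seed; identical seeds yield bitwise-identical datasets.
#' @return a list of class `SynthConfig`.
#' @export
synth_config <- function(n_cells = 1000L,
                         n_genes = 2000L,
                         type_proportions = c(0.41, 0.48, 0.05, 0.05, 0.01),
                         n_mito_genes = 10L,
                         regulon_plan = default_regulon_plan(
                           n_types = length(type_proportions)),
                         vegf_marker_plan = list(
                           markers = c("VEGFA", "VEGFB", "VEGFC"),
                           positive_fraction = 0.3),
                         base_mean = 0.5,
                         dispersion = 0.5,
                         dropout_rate = 0.2,
                         marker_mean = 50,
                         lib_sd = 0.25,
                         mito_scale = 1,
                         mito_scale_cell_fraction = 0,
                         mito_prefix = "MT-",
                         seed = 1L) {
  check_scalar(n_cells, "n_cells", min = 1, integerish = TRUE)
  check_scalar(n_genes, "n_genes", min = 1, integerish = TRUE)
  check_scalar(n_mito_genes, "n_mito_genes", min = 0, integerish = TRUE)
  check_scalar(base_mean, "base_mean", min = .Machine$double.eps)
  check_scalar(dispersion, "dispersion", min = .Machine$double.eps)
  check_scalar(dropout_rate, "dropout_rate", min = 0, max = 1 - 1e-12)
  check_scalar(marker_mean, "marker_mean", min = 0)
  check_scalar(lib_sd, "lib_sd", min = 0)

  if (length(type_proportions) < 1L || any(type_proportions <= 0)) {
    stop("`type_proportions` must all be positive", call. = FALSE)
  }
  if (abs(sum(type_proportions) - 1) > 1e-9) {
    stop("`type_proportions` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  n_types <- length(type_proportions)

  stopifnot(is.data.frame(regulon_plan),
            all(c("tf_name", "n_targets", "target_cell_type",
                  "effect_size") %in% names(regulon_plan)))
  if (anyDuplicated(regulon_plan$tf_name)) {
    stop("regulon_plan TF names must be unique", call. = FALSE)
  }
  if (any(regulon_plan$target_cell_type < 1) ||
      any(regulon_plan$target_cell_type > n_types)) {
    stop("regulon_plan target_cell_type indices must reference a valid type",
         call. = FALSE)
  }
  if (any(regulon_plan$effect_size <= 1)) {
    stop("regulon_plan effect sizes must exceed 1", call. = FALSE)
  }

  markers <- vegf_marker_plan$markers
  if (length(markers) != 3L || anyDuplicated(markers)) {
    stop("vegf_marker_plan must name three distinct marker genes",
         call. = FALSE)
  }
  pf <- rep_len(vegf_marker_plan$positive_fraction, 3L)
  if (any(pf < 0) || any(pf > 1)) {
    stop("marker positive fractions must lie in [0, 1]", call. = FALSE)
  }
  vegf_marker_plan$positive_fraction <- pf

  n_planted <- nrow(regulon_plan) + sum(regulon_plan$n_targets) +
    n_mito_genes + length(markers)
  if (n_genes < n_planted) {
    stop(sprintf(
      "n_genes (%d) is smaller than the %d planted genes (regulons + mito + markers)",
      n_genes, n_planted), call. = FALSE)
  }

  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    type_proportions = as.numeric(type_proportions),
    n_mito_genes = as.integer(n_mito_genes),
    regulon_plan = regulon_plan, vegf_marker_plan = vegf_marker_plan,
    base_mean = base_mean, dispersion = dispersion,
    dropout_rate = dropout_rate, marker_mean = marker_mean,
    lib_sd = lib_sd, mito_scale = mito_scale,
    mito_scale_cell_fraction = mito_scale_cell_fraction,
    mito_prefix = mito_prefix, seed = as.integer(seed)
  ), class = "SynthConfig")
}

#' Generate a synthetic gene-by-cell count matrix with planted ground truth
#'
#' Counts are negative binomial with per-cell log-normal library-size factors.
#' Cells of a regulon's target type have the TF and all its targets elevated
#' by the planned effect size on the mean; planted-positive marker cells
#' express that marker at `marker_mean`, all other cells at mean 0; dropout is
#' independent Bernoulli zero-inflation applied after sampling.
#'
#' @param config a [synth_config()] object.
#' @return list with `counts` (sparse genes x cells `dgCMatrix` of
#'   non-negative integers) and `truth`, a `GroundTruth` list carrying
#'   `cell_type_labels`, `regulon_memberships` (TF -> target gene set),
#'   `regulon_target_type` (TF -> type name), `vegf_true_status` (per-cell
#'   logical: planted positive for at least two of the three markers) and
#'   `marker_positive` (cells x markers logical).
#' @export
#' @examples
#' sim <- generate_dataset(synth_config(n_cells = 200, n_genes = 400,
#'                                      seed = 7))
#' dim(sim$counts)
#' table(sim$truth$cell_type_labels)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  local_seed(config$seed, {
    n_cells <- config$n_cells
    n_genes <- config$n_genes
    plan <- config$regulon_plan
    n_types <- length(config$type_proportions)
    type_names <- sprintf("type%d", seq_len(n_types))

    tf_genes <- plan$tf_name
    target_genes <- lapply(seq_len(nrow(plan)), function(i) {
      sprintf("%s.tg%02d", plan$tf_name[i], seq_len(plan$n_targets[i]))
    })
    names(target_genes) <- tf_genes
    mito_genes <- if (config$n_mito_genes > 0) {
      sprintf("%sG%d", config$mito_prefix, seq_len(config$n_mito_genes))
    } else character(0)
    marker_genes <- config$vegf_marker_plan$markers
    planted <- c(tf_genes, unlist(target_genes, use.names = FALSE),
                 mito_genes, marker_genes)
    filler <- sprintf("G%05d", seq_len(n_genes - length(planted)))
    gene_names <- c(planted, filler)
    barcodes <- sprintf("cell%05d", seq_len(n_cells))

    type_idx <- sample.int(n_types, n_cells, replace = TRUE,
                           prob = config$type_proportions)
    labels <- stats::setNames(type_names[type_idx], barcodes)

    lib <- exp(stats::rnorm(n_cells, 0, config$lib_sd))

    # mean matrix: baseline, then regulon elevation, marker planting, mito
    # scaling
    mu <- matrix(config$base_mean, n_genes, n_cells,
                 dimnames = list(gene_names, barcodes))
    for (i in seq_len(nrow(plan))) {
      members <- c(plan$tf_name[i], target_genes[[plan$tf_name[i]]])
      in_type <- type_idx == plan$target_cell_type[i]
      mu[members, in_type] <- mu[members, in_type] * plan$effect_size[i]
    }
    pf <- config$vegf_marker_plan$positive_fraction
    marker_positive <- matrix(FALSE, n_cells, 3L,
                              dimnames = list(barcodes, marker_genes))
    for (j in 1:3) {
      marker_positive[, j] <- stats::runif(n_cells) < pf[j]
      mu[marker_genes[j], ] <- ifelse(marker_positive[, j],
                                      config$marker_mean, 0)
    }
    if (length(mito_genes) > 0 && config$mito_scale_cell_fraction > 0) {
      boosted <- stats::runif(n_cells) < config$mito_scale_cell_fraction
      mu[mito_genes, boosted] <- mu[mito_genes, boosted] * config$mito_scale
    }
    mu <- sweep(mu, 2L, lib, `*`)

    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
      n_genes, n_cells, dimnames = dimnames(mu))
    if (config$dropout_rate > 0) {
      counts[stats::runif(length(counts)) < config$dropout_rate] <- 0L
    }

    truth <- structure(list(
      cell_type_labels = labels,
      regulon_memberships = target_genes,
      regulon_target_type = stats::setNames(
        type_names[plan$target_cell_type], plan$tf_name),
      vegf_true_status = stats::setNames(rowSums(marker_positive) >= 2L,
                                         barcodes),
      marker_positive = marker_positive,
      type_names = type_names
    ), class = "GroundTruth")

    list(counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
         truth = truth)
  })
}

#' Write a count matrix (and optional truth labels) as a plain-text fixture
#'
#' Writes the standard Matrix Market triplet layout: `matrix.mtx`,
#' `genes.tsv` (gene id, gene name), `barcodes.tsv`, and, when truth labels
#' are supplied, `labels.tsv` (barcode, cell type). Round-trips losslessly
#' through [read_matrix()].
#'
#' @param counts genes x cells count matrix.
#' @param directory output directory (created if needed).
#' @param truth optional `GroundTruth` (or a per-cell character vector of
#'   labels) to write as `labels.tsv`.
#' @return the directory, invisibly.
#' @export
write_fixture <- function(counts, directory, truth = NULL) {
  check_expression_matrix(counts, require_names = FALSE)
  if (is.null(rownames(counts))) {
    stop("counts must carry gene rownames", call. = FALSE)
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0L) {
    stop("counts must carry cell colnames", call. = FALSE)
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(directory)) {
      stop(sprintf("cannot create fixture directory '%s'", directory),
           call. = FALSE)
    }
  }
  sp <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(directory, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(counts), name = rownames(counts)),
    file.path(directory, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(if (is.null(colnames(counts))) character(0) else
               colnames(counts),
             file.path(directory, "barcodes.tsv"))
  if (!is.null(truth)) {
    labels <- if (inherits(truth, "GroundTruth")) {
      truth$cell_type_labels
    } else {
      truth
    }
    if (length(labels) != ncol(counts)) {
      stop("truth labels length must equal the number of cells",
           call. = FALSE)
    }
    utils::write.table(
      data.frame(barcode = colnames(counts), type = as.character(labels)),
      file.path(directory, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(directory)
}
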