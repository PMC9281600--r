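#' Pipeline configuration
#'
#' Collects every stage parameter with the package defaults: QC at 200-4000
#' detected genes and 5% mitochondrial counts, LogNormalize with scale
#' factor 1e5, 2000 highly variable genes, 40 principal components, Leiden
#' clustering at resolution 1.5, the >=2-of-3 VEGF gate, recovery-curve
#' scoring over the top 5% of ranks, the strict >1%-of-cells activation
#' filter, CSI margin 0.05 and an 8-module cut.
#'
#' @param input path to a count-matrix fixture (directory with
#'   `matrix.mtx`/`genes.tsv`/`barcodes.tsv`, or a dense TSV); may be NULL
#'   when a counts matrix is handed to [run_pipeline()] directly.
#' @param out_dir output directory for stage TSVs, `manifest.json` and
#'   `run.log`.
#' @param labels optional per-cell type labels: a `labels.tsv` path or a
#'   named character vector. When absent, cells are clustered and — if
#'   `markers` is given — annotated; otherwise cluster ids serve as labels.
#' @param markers optional [marker_table()] for cluster annotation.
#' @param regulon_file optional GMT-like regulon file; when NULL, regulons
#'   are built by co-expression from `tf_list`.
#' @param tf_list candidate TFs for the co-expression builder.
#' @param qc a [qc_thresholds()] object.
#' @param gate a [gate_rule()] object.
#' @param scale_factor,hvg_n_top,pca_n_components,cluster_resolution,cluster_n_neighbors
#'   normalization / dimensionality / clustering settings.
#' @param regulon_min_targets,regulon_max_targets,regulon_r_threshold
#'   co-expression builder settings.
#' @param aucell_top_fraction,binarize_method,min_cell_fraction scoring and
#'   activation-filter settings.
#' @param csi_margin,n_modules,csi_linkage module-detection settings.
#' @param score_cells score regulons on the VEGF-positive subpopulation (the
#'   study design; default) or on all QC-passing cells.
#' @param seed single global seed; stage seeds are derived by fixed offsets.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(input = NULL, out_dir,
                            labels = NULL, markers = NULL,
                            regulon_file = NULL, tf_list = NULL,
                            qc = qc_thresholds(), gate = gate_rule(),
                            scale_factor = 1e5, hvg_n_top = 2000L,
                            pca_n_components = 40L,
                            cluster_resolution = 1.5,
                            cluster_n_neighbors = 20L,
                            regulon_min_targets = 10L,
                            regulon_max_targets = 918L,
                            regulon_r_threshold = 0.3,
                            aucell_top_fraction = 0.05,
                            binarize_method = "bimodal_midpoint",
                            min_cell_fraction = 0.01,
                            csi_margin = 0.05, n_modules = 8L,
                            csi_linkage = "complete",
                            score_cells = c("vegf_positive", "all"),
                            seed = 0L) {
  score_cells <- match.arg(score_cells)
  if (is.null(regulon_file) && is.null(tf_list)) {
    stop("provide either `regulon_file` or `tf_list` (co-expression builder)",
         call. = FALSE)
  }
  for (p in c(input, regulon_file,
              if (is.character(labels) && length(labels) == 1L) labels)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("configured path does not exist: '%s'", p), call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "PipelineConfig")
}

write_tsv_matrix <- function(m, path, row_label = "id") {
  df <- data.frame(rownames(m), as_dense(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(row_label, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full regulon pipeline
#'
#' Sequences the stages in study order — QC, normalization, VEGF gating,
#' cell labeling (provided labels, or clustering + optional annotation),
#' regulon acquisition (file or co-expression builder), recovery-curve
#' activity scoring, binarization and the >1%-of-cells activation filter,
#' JSD specificity scores, and CSI module detection — writing every stage
#' output as TSV plus a JSON run manifest.
#'
#' @param config a [pipeline_config()].
#' @param counts optional genes x cells count matrix, overriding
#'   `config$input`.
#' @return invisibly, a list with `manifest` (stage counts, config echo,
#'   seed, timings) and `results` (the in-memory stage objects).
#' @export
run_pipeline <- function(config, counts = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  log_lines <- character(0)
  stage_time <- list()
  log_stage <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    stage_time[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  if (is.null(counts)) {
    if (is.null(config$input)) {
      stop("no input: set config$input or pass `counts`", call. = FALSE)
    }
    counts <- timed("read", read_matrix(config$input))
  }
  log_stage("read", "matrix: %d genes x %d cells", nrow(counts),
            ncol(counts))

  qc <- timed("qc", apply_qc_filters(counts, config$qc))
  kept <- qc$counts
  log_stage("qc", "%d/%d cells kept, %d genes kept",
            qc$report$n_cells_kept, qc$report$n_cells_in,
            qc$report$n_genes_kept)
  write_qc_report(qc$report, file.path(config$out_dir, "qc_report.tsv"))

  normalized <- timed("normalize", log_normalize(kept, config$scale_factor))

  gate <- timed("gate", classify_vegf(kept, config$gate))
  n_pos <- sum(gate$status == "POSITIVE")
  log_stage("gate", "%d VEGF+ / %d VEGF- cells", n_pos,
            nrow(gate) - n_pos)
  utils::write.table(gate, file.path(config$out_dir, "gate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  labels <- timed("label", {
    if (!is.null(config$labels)) {
      lab <- if (is.character(config$labels) && length(config$labels) == 1L &&
                 file.exists(config$labels)) {
        read_cell_labels(config$labels)
      } else {
        config$labels
      }
      missing <- setdiff(colnames(kept), names(lab))
      if (length(missing) > 0) {
        stop(sprintf("labels missing for %d kept cell(s)", length(missing)))
      }
      lab[colnames(kept)]
    } else {
      hvg <- select_hvg(normalized, config$hvg_n_top)
      ncomp <- min(config$pca_n_components, length(hvg) - 1L,
                   ncol(normalized) - 1L)
      pca <- compute_pca(normalized, genes = hvg, n_components = ncomp)
      cl <- cluster_cells(pca$embedding,
                          resolution = config$cluster_resolution,
                          n_neighbors = config$cluster_n_neighbors,
                          seed = config$seed + 1L)
      if (is.null(config$markers)) {
        stats::setNames(sprintf("cluster%d", cl), names(cl))
      } else {
        annotate_cell_types(normalized, cl, config$markers)$cell_types
      }
    }
  })
  log_stage("label", "%d cell types/clusters", length(unique(labels)))
  utils::write.table(
    data.frame(barcode = colnames(kept), label = as.character(labels)),
    file.path(config$out_dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  summ <- gate_summary(gate, labels)
  write_tsv_matrix(summ, file.path(config$out_dir, "gate_summary.tsv"),
                   row_label = "cell_type")

  regulons <- timed("regulons", {
    if (!is.null(config$regulon_file)) {
      read_regulons(config$regulon_file)
    } else {
      tfs <- intersect(config$tf_list, rownames(normalized))
      if (length(tfs) == 0L) stop("no configured TF present after QC")
      build_coexpression_regulons(
        normalized, tfs, min_targets = config$regulon_min_targets,
        max_targets = config$regulon_max_targets,
        r_threshold = config$regulon_r_threshold)
    }
  })
  log_stage("regulons", "%d regulons (%s)", length(regulons),
            attr(regulons, "provenance"))
  if (length(regulons) == 0L) {
    stop("stage 'regulons' failed: no regulon survived the builder",
         call. = FALSE)
  }
  write_regulons(regulons, file.path(config$out_dir, "regulons.gmt"))

  score_idx <- if (config$score_cells == "vegf_positive") {
    which(gate$status == "POSITIVE")
  } else {
    seq_len(ncol(kept))
  }
  if (length(score_idx) == 0L) {
    stop("stage 'score' failed: no cell selected for scoring", call. = FALSE)
  }
  score_mat <- normalized[, score_idx, drop = FALSE]
  score_labels <- as.character(labels)[score_idx]

  activity <- timed("score", score_all(score_mat, regulons,
                                       top_fraction = config$aucell_top_fraction,
                                       seed = config$seed + 2L))
  log_stage("score", "activity matrix: %d regulons x %d cells",
            nrow(activity), ncol(activity))
  write_tsv_matrix(activity, file.path(config$out_dir, "activity.tsv"),
                   row_label = "regulon")

  bin <- timed("binarize", binarize_activity(activity,
                                             method = config$binarize_method))
  act_filter <- timed("filter", filter_active_regulons(
    bin$binary, min_cell_fraction = config$min_cell_fraction,
    regulons = regulons))
  log_stage("filter", "%d/%d regulons active in > %.1f%% of cells",
            length(act_filter$kept), nrow(activity),
            100 * config$min_cell_fraction)
  utils::write.table(act_filter$report,
                     file.path(config$out_dir, "activity_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(act_filter$kept) == 0L) {
    stop("stage 'filter' failed: no regulon passed the activation filter",
         call. = FALSE)
  }
  activity_kept <- activity[act_filter$kept, , drop = FALSE]

  rss_tab <- timed("rss", rss_matrix(activity_kept, score_labels))
  write_tsv_matrix(rss_tab, file.path(config$out_dir, "rss.tsv"),
                   row_label = "regulon")

  csi <- timed("csi", {
    pcc <- pcc_matrix(activity_kept)
    csi_matrix(pcc, margin = config$csi_margin)
  })
  write_tsv_matrix(csi, file.path(config$out_dir, "csi.tsv"),
                   row_label = "regulon")
  k_mod <- min(config$n_modules, nrow(csi))
  partition <- timed("modules", cluster_modules(csi, n_modules = k_mod,
                                                linkage = config$csi_linkage))
  log_stage("modules", "%d modules: %s", length(partition$sizes),
            paste(sprintf("%s=%d", names(partition$sizes), partition$sizes),
                  collapse = ", "))
  utils::write.table(
    data.frame(regulon = names(partition$modules),
               module = unname(partition$modules)),
    file.path(config$out_dir, "modules.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  mod_act <- timed("module_activity",
                   module_activity(activity_kept, partition, score_labels))
  write_tsv_matrix(mod_act$scores,
                   file.path(config$out_dir, "module_activity.tsv"),
                   row_label = "module")

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("regulonpipe")),
    seed = config$seed,
    counts = list(
      cells_in = qc$report$n_cells_in,
      cells_kept = qc$report$n_cells_kept,
      genes_kept = qc$report$n_genes_kept,
      vegf_positive = n_pos,
      vegf_negative = nrow(gate) - n_pos,
      cells_scored = length(score_idx),
      regulons_in = length(regulons),
      regulons_kept = length(act_filter$kept),
      modules = length(partition$sizes)),
    config = list(
      input = config$input, score_cells = config$score_cells,
      scale_factor = config$scale_factor, hvg_n_top = config$hvg_n_top,
      pca_n_components = config$pca_n_components,
      cluster_resolution = config$cluster_resolution,
      aucell_top_fraction = config$aucell_top_fraction,
      min_cell_fraction = config$min_cell_fraction,
      csi_margin = config$csi_margin, n_modules = config$n_modules),
    stage_seconds = stage_time
  ), class = "RunManifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(manifest = manifest, results = list(
    qc = qc$report, gate = gate, labels = labels, regulons = regulons,
    activity = activity, activation = act_filter, rss = rss_tab,
    csi = csi, partition = partition, module_activity = mod_act)))
}
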