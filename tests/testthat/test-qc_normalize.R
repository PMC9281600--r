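test_that("QC keeps and drops cells exactly at the documented boundaries", {
  res <- apply_qc_filters(build_qc_matrix(), qc_thresholds())
  cells <- res$report$cells
  rownames(cells) <- cells$barcode
  expect_false(cells["det199", "kept"])
  expect_equal(cells["det199", "reasons"], "LOW_GENES")
  expect_true(cells["det200", "kept"])
  expect_true(cells["det4000", "kept"])
  expect_false(cells["det4001", "kept"])
  expect_equal(cells["det4001", "reasons"], "HIGH_GENES")
  expect_true(cells["mito049", "kept"])
  expect_true(cells["mito050", "kept"])  # exactly 5% is not "more than 5%"
  expect_false(cells["mito051", "kept"])
  expect_equal(cells["mito051", "reasons"], "HIGH_MITO")
  expect_equal(res$report$n_cells_kept, 4)
  expect_lte(res$report$n_cells_kept, res$report$n_cells_in)
})

test_that("a zero-count cell fails LOW_GENES without division by zero", {
  m <- named_matrix(c(5, 3, 0, 0), c("g1", "g2"), c("ok", "empty"))
  res <- apply_qc_filters(m, qc_thresholds(min_genes_per_cell = 1))
  cells <- res$report$cells
  expect_false(cells$kept[cells$barcode == "empty"])
  expect_match(cells$reasons[cells$barcode == "empty"], "LOW_GENES")
  expect_equal(cells$mito_fraction[cells$barcode == "empty"], 0)
  expect_error(apply_qc_filters(m[0, , drop = FALSE]), "zero genes")
})

test_that("tightening thresholds never increases cells kept, and filtering is idempotent", {
  sim <- generate_dataset(synth_config(n_cells = 300, n_genes = 300,
                                       seed = 4))
  kept_at <- function(min_genes, max_mito) {
    apply_qc_filters(sim$counts,
                     qc_thresholds(min_genes_per_cell = min_genes,
                                   max_mito_fraction = max_mito)
    )$report$n_cells_kept
  }
  n_prev <- Inf
  for (mg in c(0, 50, 100, 150, 200)) {
    n <- kept_at(mg, 0.05)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (mm in c(0.2, 0.1, 0.05, 0.01, 0)) {
    n <- kept_at(50, mm)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  th <- qc_thresholds(min_genes_per_cell = 50)
  once <- apply_qc_filters(sim$counts, th)
  twice <- apply_qc_filters(once$counts, th)
  expect_equal(as.matrix(twice$counts), as.matrix(once$counts))
  expect_equal(twice$report$n_cells_kept, once$report$n_cells_kept)
})

test_that("log-normalization matches its closed form and preserves structure", {
  m <- named_matrix(c(0, 7, 0, 0, 4, 1), c("g1", "g2", "g3"),
                    c("single", "mixed"))
  norm <- log_normalize(m, scale_factor = 1e5)
  expect_equal(norm["g1", "single"], 0)             # zeros map to zeros
  expect_equal(norm["g2", "single"], log(1 + 1e5))  # one gene holds all
  expect_equal(norm["g2", "mixed"], log(1 + 4 / 5 * 1e5))
  # scale invariance: doubling every count in a cell changes nothing
  expect_equal(log_normalize(m * 2), log_normalize(m))
  # within-cell rank order is preserved
  sim <- generate_dataset(synth_config(
    n_cells = 30, n_genes = 120, regulon_plan = default_regulon_plan(5, 10),
    seed = 6))
  kept <- apply_qc_filters(sim$counts,
                           qc_thresholds(min_genes_per_cell = 1))$counts
  n2 <- log_normalize(kept)
  j <- 1
  expect_equal(order(as.matrix(n2)[, j]), order(as.matrix(kept)[, j]))
  # zero-total cell is an instruction to run QC
  expect_error(log_normalize(named_matrix(c(1, 0), "g1", c("a", "b"))),
               "apply_qc_filters")
  # sparse and dense inputs agree
  expect_equal(as.matrix(log_normalize(kept)),
               log_normalize(as.matrix(kept)))
})

test_that("highly variable genes are ranked by variance with deterministic ties", {
  m <- rbind(bimodal = rep(c(0, 5), each = 5),
             flat1 = rep(2, 10), flat2 = rep(3, 10))
  colnames(m) <- sprintf("c%d", 1:10)
  expect_equal(select_hvg(m, 1), "bimodal")
  expect_equal(length(select_hvg(m, 99)), 3)  # n_top clipped
  set.seed(8)
  toy <- matrix(rpois(10 * 30, 4), 10, 30,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:30)))
  vars <- apply(toy, 1, var)
  expect_equal(select_hvg(toy, 10),
               rownames(toy)[order(-vars, rownames(toy))])
})

test_that("PCA matches the eigendecomposition oracle and fixes signs", {
  # rank-1 data: all variance on one line in gene space
  set.seed(11)
  t_ <- rnorm(30)
  line <- rbind(g1 = 2 * t_, g2 = -1 * t_, g3 = 0.5 * t_)
  colnames(line) <- sprintf("c%d", 1:30)
  pc <- compute_pca(line, n_components = 2, scale. = FALSE)
  expect_gte(pc$var_explained[1], 0.999)
  # duplicated cells get identical embedding rows
  dup <- cbind(line, line[, 1, drop = FALSE])
  colnames(dup) <- c(colnames(line), "dup")
  pc2 <- compute_pca(dup, n_components = 2, scale. = FALSE)
  expect_equal(pc2$embedding["c1", ], pc2$embedding["dup", ])
  # eigenvalue oracle on a 5x4 toy (genes x cells -> covariance of cells
  # in gene space)
  set.seed(12)
  toy <- matrix(rnorm(20), 5, 4,
                dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:4)))
  pc3 <- compute_pca(toy, n_components = 3, scale. = FALSE)
  ev <- eigen(cov(t(toy)), symmetric = TRUE)$values
  expect_equal(pc3$sdev[1:3]^2, ev[1:3], tolerance = 1e-10)
  # sign convention: the largest-magnitude loading is positive
  for (j in 1:3) {
    expect_gt(pc3$rotation[which.max(abs(pc3$rotation[, j])), j], 0)
  }
  expect_error(compute_pca(toy, n_components = 10), "exceeds")
})

test_that("graph clustering separates planted blobs", {
  skip_if_not_installed("mclust")
  set.seed(7)
  blob <- function(center, n) {
    sweep(matrix(rnorm(n * 2, sd = 0.05), n, 2), 2, center, `+`)
  }
  two <- rbind(blob(c(0, 0), 60), blob(c(10, 10), 60))
  rownames(two) <- sprintf("c%03d", 1:120)
  truth2 <- rep(0:1, each = 60)
  cl2 <- cluster_cells(two, resolution = 0.1, n_neighbors = 10, seed = 1)
  expect_equal(sort(unique(cl2)), seq_len(max(cl2) + 1L) - 1L)
  expect_equal(length(unique(cl2)), 2)
  expect_equal(mclust::adjustedRandIndex(cl2, truth2), 1)
  # resolution -> 0 collapses a single blob to one cluster
  one <- blob(c(0, 0), 80)
  rownames(one) <- sprintf("c%03d", 1:80)
  expect_equal(length(unique(cluster_cells(one, resolution = 1e-4,
                                           n_neighbors = 10, seed = 1))), 1)
  # three blobs: near-perfect recovery and K monotone in resolution
  three <- rbind(blob(c(0, 0), 100), blob(c(8, 0), 100), blob(c(0, 8), 100))
  rownames(three) <- sprintf("c%03d", 1:300)
  truth3 <- rep(1:3, each = 100)
  cl3 <- cluster_cells(three, resolution = 0.5, n_neighbors = 15, seed = 1)
  expect_gte(mclust::adjustedRandIndex(cl3, truth3), 0.95)
  ks <- vapply(c(0.001, 0.5, 1, 2, 4), function(res) {
    length(unique(cluster_cells(three, resolution = res, n_neighbors = 15,
                                seed = 1)))
  }, numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(cluster_cells(three[1:5, ], n_neighbors = 10), "n_neighbors")
})

test_that("marker annotation recovers the expected cell types", {
  # two clusters: one expressing the mitotic program, one POSTN/CD34
  set.seed(15)
  genes <- c("MKI67", "AURKA", "CDC20", "CDK1", "POSTN", "CD34", "ANGPTL7",
             "BMPR2", "PDGFRB", "THY1", sprintf("G%02d", 1:10))
  n_per <- 40
  m <- matrix(rpois(length(genes) * 2 * n_per, 0.05), length(genes),
              2 * n_per, dimnames = list(genes, sprintf("c%02d", 1:(2 * n_per))))
  mitotic <- 1:n_per
  cd34 <- (n_per + 1):(2 * n_per)
  m[c("MKI67", "AURKA", "CDC20", "CDK1"), mitotic] <- rpois(4 * n_per, 8)
  m[c("POSTN", "CD34"), cd34] <- rpois(2 * n_per, 8)
  clusters <- rep(0:1, each = n_per)
  ann <- annotate_cell_types(m, clusters, marker_table())
  expect_equal(unname(ann$cluster_types["0"]), "mitotic cell")
  expect_equal(unname(ann$cluster_types["1"]),
               "CD34+ osteochondral progenitor")
  expect_equal(dim(ann$scores), c(2L, 5L))
  # missing markers are dropped with a warning; all-missing is an error
  expect_warning(
    annotate_cell_types(m[setdiff(genes, "THY1"), ], clusters,
                        marker_table()),
    "THY1")
  expect_error(
    suppressWarnings(annotate_cell_types(m[sprintf("G%02d", 1:10), ],
                                         clusters, marker_table())),
    "no marker")
})

test_that("planted cell types are recovered end-to-end from counts", {
  skip_if_not_installed("mclust")
  sim <- generate_dataset(synth_config(
    n_cells = 1000, n_genes = 600,
    type_proportions = c(0.3, 0.3, 0.2, 0.1, 0.1),
    regulon_plan = default_regulon_plan(5, 30, 6), seed = 17))
  qc <- apply_qc_filters(sim$counts, qc_thresholds(min_genes_per_cell = 20))
  norm <- log_normalize(qc$counts)
  hvg <- select_hvg(norm, 300)
  pca <- compute_pca(norm, genes = hvg, n_components = 20)
  cl <- cluster_cells(pca$embedding, resolution = 0.5, seed = 1)
  truth <- sim$truth$cell_type_labels[colnames(qc$counts)]
  expect_gte(mclust::adjustedRandIndex(cl, truth), 0.9)
  # annotate clusters from the planted programs (three targets per type)
  markers <- marker_table(stats::setNames(
    lapply(sprintf("TF%d", 1:5), function(tf) {
      sim$truth$regulon_memberships[[tf]][1:3]
    }), sprintf("type%d", 1:5)))
  ann <- suppressWarnings(annotate_cell_types(norm, cl, markers))
  agree <- mean(ann$cell_types == truth)
  expect_gte(agree, 0.9)
})
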