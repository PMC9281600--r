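# Independent oracles and fixture builders, deliberately written as plain
# loops so they share no code path with the implementation they check.

# Jensen-Shannon divergence by direct term-by-term summation (base 2).
oracle_jsd <- function(p, q) {
  total <- 0
  for (i in seq_along(p)) {
    m <- (p[i] + q[i]) / 2
    if (p[i] > 0) total <- total + 0.5 * p[i] * (log(p[i] / m) / log(2))
    if (q[i] > 0) total <- total + 0.5 * q[i] * (log(q[i] / m) / log(2))
  }
  total
}

# Recovery-curve area by explicit enumeration of the step curve: walk rank
# positions 1..k, count regulon genes recovered so far, sum, and divide by
# the best achievable area for a set of this size.
oracle_aucell <- function(gene_ranks, k) {
  area <- 0
  for (x in seq_len(k)) {
    area <- area + sum(gene_ranks <= x)
  }
  best <- 0
  for (x in seq_len(k)) {
    best <- best + min(x, length(gene_ranks))
  }
  area / best
}

# A rank matrix whose single cell places the m regulon genes (rows 1..m) at
# the given rank positions; remaining ranks go to filler genes in order.
rank_column <- function(n_genes, positions) {
  m <- length(positions)
  ranks <- integer(n_genes)
  ranks[seq_len(m)] <- positions
  ranks[(m + 1):n_genes] <- setdiff(seq_len(n_genes), positions)
  matrix(ranks, ncol = 1,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)), "cell1"))
}

# Planted regulons from generator truth, as an imported RegulonSet.
truth_regulon_set <- function(truth) {
  regulon_set(lapply(names(truth$regulon_memberships), function(tf) {
    regulon(tf, truth$regulon_memberships[[tf]])
  }), provenance = "imported")
}

# Block-structured activity matrix: rows within a block share a latent
# per-cell signal plus small independent noise, so within-block correlation
# is high and between-block correlation near zero.
block_activity <- function(block_sizes, n_cells, noise_sd = 0.1) {
  rows <- list()
  block_of <- integer(0)
  for (b in seq_along(block_sizes)) {
    latent <- runif(n_cells)
    for (j in seq_len(block_sizes[b])) {
      rows[[length(rows) + 1L]] <- latent + rnorm(n_cells, 0, noise_sd)
      block_of <- c(block_of, b)
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("R%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("c%03d", seq_len(n_cells))
  list(activity = m, blocks = block_of)
}

# Dense count matrix with gene/cell names for hand-built QC cases.
named_matrix <- function(data, genes, cells) {
  matrix(data, nrow = length(genes),
         dimnames = list(genes, cells))
}

# Hand-built matrix: 5000 genes (20 mitochondrial), cells constructed to sit
# exactly on the detected-gene and mitochondrial-fraction QC boundaries.
build_qc_matrix <- function() {
  genes <- c(sprintf("MT-G%d", 1:20), sprintf("G%04d", 1:4980))
  cells <- c("det199", "det200", "det4000", "det4001",
             "mito049", "mito050", "mito051")
  m <- matrix(0, length(genes), length(cells),
              dimnames = list(genes, cells))
  non_mito <- 21:5000
  m[non_mito[1:199], "det199"] <- 1
  m[non_mito[1:200], "det200"] <- 1
  m[non_mito[1:4000], "det4000"] <- 1
  m[c(non_mito[1:4000], 1), "det4001"] <- 1
  # 1000 total counts each: one mito gene carries 49/50/51 counts
  m[1, "mito049"] <- 49; m[non_mito[1:951], "mito049"] <- 1
  m[1, "mito050"] <- 50; m[non_mito[1:950], "mito050"] <- 1
  m[1, "mito051"] <- 51; m[non_mito[1:949], "mito051"] <- 1
  m
}
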