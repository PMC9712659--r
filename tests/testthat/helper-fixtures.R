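# small in-code fixtures shared across test files

# dense matrix -> named sparse gene-by-cell counts
mk_counts <- function(m, genes = NULL, cells = NULL) {
  m <- as.matrix(m)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- cells %||% colnames(m) %||% sprintf("c%02d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# a norm-like matrix holding arbitrary given values (bypasses normalization
# when a test only needs fixed expression values)
mk_expr <- function(m, genes = NULL, cells = NULL) {
  Matrix::Matrix(mk_counts(m, genes, cells), sparse = TRUE)
}

# 10 cells with totals 100, 200, ..., 1000 and 2 detected features each
fixture_percentile_cells <- function() {
  mk_counts(rbind(seq(99, 999, by = 100), rep(1, 10)))
}

# deterministic QC fixture with planted violations of every filter
fixture_qc <- function() {
  set.seed(42)
  n_cells <- 40
  counts <- matrix(rpois(30 * n_cells, lambda = 5), nrow = 30)
  counts <- mk_counts(counts,
                      genes = c(sprintf("g%02d", 1:27), "rare1", "rare2", "mt-Co1"),
                      cells = sprintf("c%02d", 1:n_cells))
  # genes detected in exactly 9 (below cutoff) and exactly 10 cells
  counts["rare1", ] <- 0; counts["rare1", 1:9] <- 1
  counts["rare2", ] <- 0; counts["rare2", 1:10] <- 1
  # two cells pushed far outside the count percentiles
  counts[1:27, "c39"] <- 0
  counts["g01", "c40"] <- 10000
  meta <- data.frame(cell_id = colnames(counts),
                     doublet_score = rep(0.1, n_cells))
  meta$doublet_score[meta$cell_id %in% c("c05", "c06")] <- c(0.5, 0.7)
  list(counts = counts, meta = meta,
       truth = list(genes_removed = "rare1",
                    mito_removed = "mt-Co1",
                    doublets_removed = "c06"))
}
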