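#' Remove genes not detected in a minimum number of cells
#'
#' A gene is retained iff its count is non-zero in at least \code{min_cells}
#' cells (default 10, the conventional droplet-QC threshold).
#'
#' @param counts gene-by-cell count matrix
#' @param min_cells minimum number of cells with non-zero count
#' @return the filtered count matrix
#' @export
filter_genes_min_cells <- function(counts, min_cells = 10) {
  counts <- validate_counts(counts)
  stopifnot(min_cells >= 0)
  keep <- Matrix::rowSums(counts > 0) >= min_cells
  counts[keep, , drop = FALSE]
}

#' Filter cells by total-count and detected-feature percentiles
#'
#' Percentile thresholds are computed on the pre-filter distribution by
#' linear interpolation between order statistics (quantile type 7) for both
#' the per-cell total count and the per-cell number of detected features.
#' The interval is inclusive: cells sitting exactly on a threshold are
#' retained. By default a cell is removed when EITHER metric falls outside
#' its interval (\code{mode = "either"}); \code{mode = "both"} removes a
#' cell only when both do.
#'
#' @param counts gene-by-cell count matrix
#' @param lower_pct,upper_pct percentile bounds (default 10 and 90)
#' @param mode "either" (default) or "both": whether one or both
#'   out-of-range metrics are required to remove a cell
#' @return the filtered count matrix
#' @export
filter_cells_percentile <- function(counts, lower_pct = 10, upper_pct = 90,
                                    mode = c("either", "both")) {
  counts <- validate_counts(counts)
  mode <- match.arg(mode)
  stopifnot(lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  if (ncol(counts) == 0) format_error("empty matrix: no cells to filter")
  totals <- Matrix::colSums(counts)
  nfeat <- Matrix::colSums(counts > 0)
  in_rng <- function(x) {
    lo <- pctl(x, lower_pct); hi <- pctl(x, upper_pct)
    x >= lo & x <= hi
  }
  ok_t <- in_rng(totals); ok_f <- in_rng(nfeat)
  keep <- if (mode == "either") ok_t & ok_f else ok_t | ok_f
  counts[, keep, drop = FALSE]
}

#' Remove doublets by a precomputed doublet score
#'
#' Cells whose score is strictly greater than the threshold are removed; a
#' score exactly at the threshold is retained. The score itself (e.g. a
#' hybrid doublet score) is an input computed upstream, not by this package.
#'
#' @param counts gene-by-cell count matrix
#' @param meta per-cell data.frame with cell_id and doublet_score
#' @param threshold removal threshold (default 0.5)
#' @return the filtered count matrix
#' @export
remove_doublets <- function(counts, meta, threshold = 0.5) {
  counts <- validate_counts(counts)
  meta <- validate_meta(meta, counts)
  if (is.null(meta$doublet_score) || anyNA(meta$doublet_score)) {
    format_error("doublet_score missing for one or more cells")
  }
  counts[, meta$doublet_score <= threshold, drop = FALSE]
}

#' Remove mitochondrial genes by symbol prefix
#'
#' @param counts gene-by-cell count matrix
#' @param prefix symbol prefix, matched case-insensitively (default "mt-")
#' @return the filtered count matrix
#' @export
remove_mito_genes <- function(counts, prefix = "mt-") {
  counts <- validate_counts(counts)
  keep <- !startsWith(tolower(rownames(counts)), tolower(prefix))
  counts[keep, , drop = FALSE]
}

#' Log-normalize counts
#'
#' Each entry becomes \code{log(1 + count / cell_total * scale_factor)}
#' (natural log, scale factor 10,000 by default). Zeros map to zero, so the
#' sparsity pattern is preserved and normalized values are scale-invariant
#' within a cell.
#'
#' @param counts gene-by-cell count matrix
#' @param scale_factor library-size scale factor
#' @return a sparse gene-by-cell matrix of log-normalized expression
#' @export
lognormalize <- function(counts, scale_factor = 10000) {
  counts <- validate_counts(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop("cells with zero total count present; filter cells before normalizing")
  }
  norm <- as_dgc(counts)
  # column index of each stored entry in a dgCMatrix
  col_of <- rep(seq_len(ncol(norm)), diff(norm@p))
  norm@x <- log1p(norm@x / totals[col_of] * scale_factor)
  norm
}

#' Scale genes to zero mean and unit variance, with clipping
#'
#' Per-gene z-score using the sample (n-1) standard deviation; genes with
#' zero variance are set to all-zero; values are clipped to
#' \code{[-clip_max, clip_max]}. Returns a dense matrix.
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param clip_max clipping bound (default 10)
#' @return dense gene-by-cell matrix of scaled expression
#' @export
scale_genes <- function(norm, clip_max = 10) {
  if (ncol(norm) < 2) stop("scaling requires at least 2 cells")
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  out <- (x - mu) / ifelse(sd == 0, 1, sd)
  out[sd == 0, ] <- 0
  out[out > clip_max] <- clip_max
  out[out < -clip_max] <- -clip_max
  out
}

#' Select highly variable genes by a mean-variance trend
#'
#' Genes are ranked by the residual of log10(variance) about a degree-2
#' polynomial trend in log10(mean), fitted over genes with positive mean
#' and variance; the top \code{n_top} by residual are returned. This is a
#' deterministic polynomial-trend surrogate for local-regression
#' variance-stabilizing selection.
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param n_top number of genes to return (default 5000, capped at the
#'   number of eligible genes)
#' @return character vector of gene symbols, most variable first
#' @export
select_variable_genes <- function(norm, n_top = 5000) {
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  v <- rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  ok <- mu > 0
  if (sum(ok) < 10) stop("fewer than 10 genes with positive mean expression")
  fit_ok <- ok & v > 0
  df <- data.frame(lm = log10(mu[fit_ok]), lv = log10(v[fit_ok]))
  fit <- stats::lm(lv ~ poly(lm, 2, raw = TRUE), data = df)
  resid <- setNames(rep(-Inf, nrow(x)), rownames(x))
  resid[fit_ok] <- stats::residuals(fit)
  n_top <- min(n_top, sum(ok))
  ord <- order(resid, decreasing = TRUE)
  head(rownames(x)[ord], n_top)
}

#' Run the full QC / normalization pipeline in its fixed order
#'
#' All filters (gene detection, cell percentile, doublet score,
#' mitochondrial prefix) are computed on the raw matrix in a single pass and
#' then applied jointly — thresholds are not re-estimated on intermediate
#' matrices — followed by log-normalization. Re-running the filters on their
#' own output with the same thresholds is idempotent.
#'
#' @param counts gene-by-cell count matrix
#' @param meta per-cell metadata (needed when \code{doublet_threshold} is
#'   not NULL)
#' @param min_cells gene-detection threshold
#' @param lower_pct,upper_pct cell percentile bounds
#' @param doublet_threshold doublet-score cutoff, or NULL to skip
#' @param mito_prefix mitochondrial symbol prefix, or NULL to skip
#' @param scale_factor log-normalization scale factor
#' @return list with \code{counts} (filtered), \code{norm} (log-normalized),
#'   \code{meta} (aligned metadata) and \code{log} (cell/gene counts after
#'   each stage)
#' @export
preprocess <- function(counts, meta = NULL, min_cells = 10,
                       lower_pct = 10, upper_pct = 90,
                       doublet_threshold = 0.5, mito_prefix = "mt-",
                       scale_factor = 10000) {
  counts <- validate_counts(counts)
  stages <- list(input = dim(counts))
  # all keep-sets are computed on the raw matrix, then applied jointly
  raw <- counts
  counts <- filter_genes_min_cells(counts, min_cells)
  stages$gene_filter <- dim(counts)
  keep_cells <- colnames(filter_cells_percentile(raw, lower_pct, upper_pct))
  counts <- counts[, colnames(counts) %in% keep_cells, drop = FALSE]
  stages$cell_filter <- dim(counts)
  if (!is.null(doublet_threshold)) {
    if (is.null(meta)) stop("meta with doublet_score required for doublet removal")
    counts <- remove_doublets(counts, meta[meta$cell_id %in% colnames(counts), ,
                                           drop = FALSE], doublet_threshold)
    stages$doublet_filter <- dim(counts)
  }
  if (!is.null(mito_prefix)) {
    counts <- remove_mito_genes(counts, mito_prefix)
    stages$mito_filter <- dim(counts)
  }
  norm <- lognormalize(counts, scale_factor)
  out_meta <- if (!is.null(meta)) {
    validate_meta(meta[meta$cell_id %in% colnames(counts), , drop = FALSE], counts)
  }
  list(counts = counts, norm = norm, meta = out_meta, log = stages)
}
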