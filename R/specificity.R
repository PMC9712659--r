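#' Gene-specificity index matrix across clusters
#'
#' For gene g and cluster c the specificity index is the ratio of the mean
#' expression of g over the cells of c to the mean expression of g over all
#' cells. A gene equally expressed in all clusters has index 1 everywhere;
#' with balanced clusters the index is bounded by the number of clusters N
#' (a gene expressed in only one of N equal clusters scores N there, 0
#' elsewhere). The cell-fraction-weighted mean of every row is exactly 1.
#' Genes with zero overall mean are dropped with a warning.
#'
#' @param expr gene-by-cell matrix; log-normalized expression by default
#'   usage, raw counts if the caller prefers
#' @param clusters per-cell cluster labels aligned with \code{colnames(expr)}
#' @return list with \code{values} (genes x clusters matrix),
#'   \code{cluster_sizes} (cells per cluster) and \code{n_clusters}
#' @export
specificity_matrix <- function(expr, clusters) {
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == ncol(expr))
  lev <- unique(clusters)
  if (length(lev) < 2) stop("at least 2 clusters required")
  overall <- Matrix::rowMeans(expr)
  keep <- overall > 0
  if (any(!keep)) {
    warning(sum(!keep), " genes with zero overall mean dropped")
  }
  expr <- expr[keep, , drop = FALSE]
  overall <- overall[keep]
  cl_means <- vapply(lev, function(cl)
    Matrix::rowMeans(expr[, clusters == cl, drop = FALSE]), numeric(nrow(expr)))
  if (is.null(dim(cl_means))) cl_means <- matrix(cl_means, nrow = 1,
                                                 dimnames = list(rownames(expr), lev))
  values <- cl_means / overall
  list(values = values,
       cluster_sizes = setNames(as.vector(table(clusters)[lev]), lev),
       n_clusters = length(lev))
}

#' Shared feature genes between two datasets
#'
#' The common gene set for a cross-dataset comparison: the intersection of
#' each dataset's top variable genes, or — when the partner is a bulk table
#' without meaningful per-gene variance (e.g. a microarray) — of one
#' dataset's top set with the partner's full detected-gene universe.
#'
#' @param norm_a,norm_b gene-by-cell log-normalized matrices
#' @param n_top number of variable genes per dataset (default 5000)
#' @param universe_b if TRUE, use all genes of dataset B instead of its top
#'   variable set
#' @return character vector of shared genes
#' @export
shared_feature_genes <- function(norm_a, norm_b, n_top = 5000,
                                 universe_b = FALSE) {
  top_a <- select_variable_genes(norm_a, n_top)
  top_b <- if (universe_b) rownames(norm_b) else select_variable_genes(norm_b, n_top)
  shared <- intersect(top_a, top_b)
  if (!length(shared)) stop("no shared genes between the two datasets")
  shared
}

#' Spearman correspondence of two specificity matrices
#'
#' For every cluster pair (a, b), the Spearman correlation (midrank ties) of
#' the two specificity columns restricted to the shared genes. Constant
#' columns yield NA with a warning.
#'
#' @param spec_a,spec_b results of \code{\link{specificity_matrix}}
#' @param shared_genes genes present in both matrices (>= 10)
#' @return clusters_a x clusters_b matrix of correlations in [-1, 1]
#' @export
cross_dataset_correlation <- function(spec_a, spec_b, shared_genes) {
  va <- spec_a$values; vb <- spec_b$values
  shared_genes <- intersect(intersect(shared_genes, rownames(va)), rownames(vb))
  if (length(shared_genes) < 10) stop("fewer than 10 shared genes")
  va <- va[shared_genes, , drop = FALSE]
  vb <- vb[shared_genes, , drop = FALSE]
  const <- c(colnames(va)[apply(va, 2, function(x) length(unique(x)) == 1)],
             colnames(vb)[apply(vb, 2, function(x) length(unique(x)) == 1)])
  if (length(const)) {
    warning("constant specificity column(s): ", paste(const, collapse = ", "),
            "; correlation undefined, reported as NA")
  }
  suppressWarnings(stats::cor(va, vb, method = "spearman"))
}
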