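#' Two-sided Wilcoxon rank-sum test (midranks, exact or normal approximation)
#'
#' The workhorse test behind differential expression. Ties are handled by
#' midranks. When both groups have at most \code{exact_max} observations the
#' two-sided p-value is computed by exhaustive enumeration of all group
#' assignments of the observed (possibly tied) ranks,
#' \eqn{p = P(|W - E W| \ge |w - E W|)}; otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric vectors (the two groups)
#' @param exact force (TRUE) or forbid (FALSE) enumeration; NULL (default)
#'   enumerates iff both groups have at most \code{exact_max} values
#' @param exact_max group-size bound for the exact path (default 8)
#' @return list with \code{statistic} (rank sum of \code{x}) and
#'   \code{p_value}
#' @export
rank_sum_test <- function(x, y, exact = NULL, exact_max = 8) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * mean(r)
  if (is.null(exact)) exact <- nx <= exact_max && ny <= exact_max
  if (exact) {
    sums <- combn(n, nx, FUN = function(idx) sum(r[idx]))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-10)
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1))
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement,
#' order-preserving with the input vector.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# de-logged mean with pseudocount: mean(expm1(x)) + 1
delog_mean1 <- function(x) mean(expm1(x)) + 1

#' Wilcoxon differential expression between two cell groups
#'
#' Genes are tested only when \code{max(pct_group1, pct_group2) >= min_pct}
#' and \code{|log2FC| >= logfc_threshold}; BH adjustment is computed over
#' the tested genes only, so the multiplicity equals the number of genes
#' passing the gates. The fold change is the log2 ratio of de-logged group
#' means with pseudocount 1,
#' \code{log2((mean(expm1(xA)) + 1) / (mean(expm1(xB)) + 1))}, and pct
#' fields are the fractions of cells with normalized expression > 0.
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param cells_a,cells_b disjoint character vectors of cell ids (or integer
#'   column indices), each of at least 3 cells
#' @param min_pct minimum expression fraction gate (default 0.1)
#' @param logfc_threshold minimum |log2FC| gate (default 0.25)
#' @param exact passed to \code{\link{rank_sum_test}}
#' @return data.frame with columns gene, log2_fold_change, pct_group1,
#'   pct_group2, p_value, p_adjusted, ordered by p_value
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, min_pct = 0.1,
                        logfc_threshold = 0.25, exact = NULL) {
  if (length(intersect(cells_a, cells_b))) stop("cell groups must be disjoint")
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  if (ncol(a) < 3 || ncol(b) < 3) stop("each group needs at least 3 cells")
  pct1 <- rowMeans(a > 0)
  pct2 <- rowMeans(b > 0)
  lfc <- log2(apply(a, 1, delog_mean1) / apply(b, 1, delog_mean1))
  tested <- pmax(pct1, pct2) >= min_pct & abs(lfc) >= logfc_threshold
  idx <- which(tested)
  p <- vapply(idx, function(g) rank_sum_test(a[g, ], b[g, ], exact = exact)$p_value,
              numeric(1))
  out <- data.frame(gene = rownames(norm)[idx],
                    log2_fold_change = lfc[idx],
                    pct_group1 = pct1[idx], pct_group2 = pct2[idx],
                    p_value = p, p_adjusted = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-vs-rest marker detection across clusters
#'
#' Runs \code{\link{wilcoxon_de}} of each cluster against all other cells
#' and concatenates the tables with a \code{cluster} column. Clusters with
#' fewer than 3 cells are skipped with a warning.
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param clusters per-cell cluster labels, aligned with \code{colnames(norm)}
#' @param min_pct,logfc_threshold gates passed to \code{\link{wilcoxon_de}}
#'   (marker defaults 0.25 / 0.25)
#' @return data.frame of per-cluster marker tables
#' @export
find_all_markers <- function(norm, clusters, min_pct = 0.25,
                             logfc_threshold = 0.25) {
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == ncol(norm))
  lev <- unique(clusters)
  if (length(lev) < 2) stop("at least 2 clusters required")
  res <- list()
  for (cl in lev) {
    in_cl <- which(clusters == cl)
    if (length(in_cl) < 3) {
      warning("cluster '", cl, "' has fewer than 3 cells; skipped")
      next
    }
    tab <- wilcoxon_de(norm, in_cl, which(clusters != cl),
                       min_pct = min_pct, logfc_threshold = logfc_threshold)
    if (nrow(tab)) tab$cluster <- cl
    res[[cl]] <- tab
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gate cells positive for a marker by a scaled-expression percentile
#'
#' The threshold is the linear-interpolation percentile of the gene's scaled
#' expression over the cell subset; cells with value strictly greater are
#' returned (e.g. Ccr2+ macrophages above the 70th percentile of scaled
#' Ccr2).
#'
#' @param scaled gene-by-cell scaled matrix
#' @param gene gene symbol
#' @param percentile percentile in [0, 100) (default 70)
#' @param cells optional subset of cell ids over which both the threshold
#'   and the gate are computed (default: all cells)
#' @return character vector of gated cell ids
#' @export
gate_positive_cells <- function(scaled, gene, percentile = 70, cells = NULL) {
  if (!gene %in% rownames(scaled)) stop("gene '", gene, "' absent from matrix")
  if (is.null(cells)) cells <- colnames(scaled)
  if (!length(cells)) stop("empty cell subset")
  x <- as.numeric(scaled[gene, cells])
  thr <- pctl(x, percentile)
  cells[x > thr]
}

#' One-sided hypergeometric gene-set enrichment
#'
#' Upper-tail probability \eqn{P(X \ge k)} of observing at least the
#' realised overlap between a hit list and an annotation set drawn from a
#' finite gene universe.
#'
#' @param hits character vector of hit genes (subset of universe)
#' @param annotation character vector of annotated genes (subset of universe)
#' @param universe character vector, the gene universe
#' @return list with \code{p_value}, \code{overlap}, \code{expected}
#' @export
hypergeom_enrichment <- function(hits, annotation, universe) {
  hits <- unique(hits); annotation <- unique(annotation); universe <- unique(universe)
  if (length(setdiff(hits, universe))) stop("hit genes outside the universe")
  if (length(setdiff(annotation, universe))) stop("annotation genes outside the universe")
  k <- length(intersect(hits, annotation))
  m <- length(annotation); n <- length(universe)
  p <- stats::phyper(k - 1, m, n - m, length(hits), lower.tail = FALSE)
  list(p_value = p, overlap = k, expected = length(hits) * m / n)
}
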