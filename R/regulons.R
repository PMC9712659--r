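#' Rank-based AUC regulon activity per cell
#'
#' For each cell, all genes are ranked by decreasing expression (ties broken
#' by a fixed seeded permutation of gene order) and the step recovery curve
#' of regulon targets is accumulated over the top
#' \code{k = ceiling(top_fraction * n_genes)} positions. The score is the
#' area under that curve divided by the maximal achievable area (all targets
#' packed at the top ranks), so it lies in [0, 1]: 1 when every target sits
#' inside the window at the top, 0 when none enters the window.
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param regulons a character vector of target genes, or a named list of
#'   such vectors (one per regulon)
#' @param top_fraction fraction of the ranking forming the recovery window
#'   (default 0.05)
#' @param seed seed for the tie-breaking permutation
#' @return cells x regulons matrix of AUC scores in [0, 1]
#' @export
regulon_auc <- function(norm, regulons, top_fraction = 0.05, seed = 1L) {
  if (!is.list(regulons)) regulons <- list(regulon = regulons)
  stopifnot(top_fraction > 0, top_fraction <= 1)
  genes <- rownames(norm)
  n <- length(genes)
  k <- ceiling(top_fraction * n)
  idx_sets <- lapply(regulons, function(tg) which(genes %in% tg))
  empty <- vapply(idx_sets, length, integer(1)) == 0
  if (any(empty)) {
    stop("regulon(s) with no targets in the gene universe: ",
         paste(names(regulons)[empty], collapse = ", "))
  }
  tb <- with_seed(seed, sample.int(n))
  x <- as.matrix(norm)
  out <- matrix(0, ncol(x), length(regulons),
                dimnames = list(colnames(x), names(regulons)))
  maxarea <- vapply(idx_sets, function(ii) {
    m <- min(length(ii), k)
    sum(k - seq_len(m) + 1)
  }, numeric(1))
  pos <- integer(n)
  for (cell in seq_len(ncol(x))) {
    pos[order(-x[, cell], tb)] <- seq_len(n)
    for (j in seq_along(idx_sets)) {
      r <- pos[idx_sets[[j]]]
      out[cell, j] <- sum(pmax(0, k - r + 1)) / maxarea[j]
    }
  }
  out
}

# closed-form expected AUC of a random m-gene set (hypergeometric mean of
# the recovery curve): E[area] = (m/n) * k(k+1)/2 over the same maxarea
expected_random_auc <- function(n_genes, set_size, top_fraction = 0.05) {
  k <- ceiling(top_fraction * n_genes)
  m <- min(set_size, k)
  maxarea <- sum(k - seq_len(m) + 1)
  (set_size / n_genes) * k * (k + 1) / 2 / maxarea
}

#' Per-cell module score of a gene set
#'
#' Genes are binned into \code{n_bins} equal-frequency bins by average
#' expression; for every set gene, \code{n_ctrl} control genes are drawn
#' with replacement (seeded) from its bin. The score is the mean expression
#' of the set genes minus the mean expression of the pooled control draws,
#' per cell — a signed signature score robust to per-cell depth shifts
#' (adding a constant to every gene of a cell cancels out). Cell-cycle
#' scoring is this operation applied to phase gene sets.
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param gene_set character vector of gene symbols
#' @param n_bins number of expression bins (default 24)
#' @param n_ctrl control genes drawn per set gene (default 100)
#' @param seed seed for control sampling
#' @return named numeric vector of per-cell scores
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  genes <- rownames(norm)
  set_idx <- which(genes %in% gene_set)
  if (!length(set_idx)) stop("gene set has no genes in the universe")
  avg <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, length(genes))
  bin <- ceiling(n_bins * rank(avg, ties.method = "first") / length(genes))
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(set_idx, function(g) {
      pool <- which(bin == bin[g])
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  sig <- Matrix::colMeans(norm[set_idx, , drop = FALSE])
  ctrl <- Matrix::colMeans(norm[ctrl_idx, , drop = FALSE])
  sig - ctrl
}

#' Score several gene sets / regulons by module score
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param gene_sets named list of gene symbol vectors
#' @inheritParams module_score
#' @return cells x sets matrix of module scores
#' @export
module_score_matrix <- function(norm, gene_sets, n_bins = 24, n_ctrl = 100,
                                seed = 1L) {
  stopifnot(length(gene_sets) >= 1, !is.null(names(gene_sets)))
  scores <- vapply(seq_along(gene_sets), function(i)
    module_score(norm, gene_sets[[i]], n_bins, n_ctrl, seed + i - 1L),
    numeric(ncol(norm)))
  dimnames(scores) <- list(colnames(norm), names(gene_sets))
  scores
}

#' Differential-regulon ledger between two conditions
#'
#' Each regulon's per-cell module scores are compared between the two
#' conditions with a two-sided Wilcoxon rank-sum test, BH-adjusted over
#' regulons. A regulon passes the ledger only if (BH p < alpha) AND
#' (1) its mean score across all contrast cells is greater than 0,
#' (2) it contains at least one differentially expressed gene of the same
#' contrast, and (3) its DEG fraction is at least \code{deg_fraction} of the
#' regulon size.
#'
#' @param scores cells x regulons matrix of module scores (see
#'   \code{\link{module_score_matrix}})
#' @param condition per-cell labels, exactly 2 levels, aligned with score rows
#' @param de_table differential-expression table of the same contrast (needs
#'   columns gene and p_adjusted)
#' @param regulons named list of target-gene vectors matching the score
#'   columns
#' @param alpha significance cutoff for both the regulon test and the DEG
#'   definition (default 0.05)
#' @param deg_fraction minimum DEG fraction of the regulon size (default 0.05)
#' @param norm gene-by-cell log-normalized matrix over the same cells;
#'   required for the default \code{expression_criterion = "expression"}
#' @param group1 optional label naming the first group of the contrast (the
#'   one whose mean appears first); defaults to first label encountered
#' @param expression_criterion how the "regulon is expressed" gate is
#'   evaluated: \code{"expression"} (default) requires the mean normalized
#'   expression of the targets across all contrast cells to exceed 0;
#'   \code{"module_score"} requires the mean module score to exceed 0.
#'   Module scores are centered against matched controls and hover around
#'   zero even for clearly expressed programs, which makes them a poor
#'   expressed/not-expressed gate; the expression reading is the default.
#' @return data.frame (the ledger), one row per regulon, sorted by adjusted
#'   p: mean score per condition, score difference, mean expression, p,
#'   BH p, regulon size, n_DEG_targets, DEG_fraction, pass_flag
#' @export
differential_regulons <- function(scores, condition, de_table, regulons,
                                  alpha = 0.05, deg_fraction = 0.05,
                                  norm = NULL, group1 = NULL,
                                  expression_criterion = c("expression",
                                                           "module_score")) {
  condition <- as.character(condition)
  stopifnot(length(condition) == nrow(scores))
  expression_criterion <- match.arg(expression_criterion)
  if (expression_criterion == "expression" && is.null(norm)) {
    stop("norm matrix required for the expression criterion")
  }
  lev <- unique(condition)
  if (length(lev) != 2) stop("exactly 2 condition labels required")
  if (!is.null(group1)) lev <- c(group1, setdiff(lev, group1))
  regulons <- regulons[colnames(scores)]
  degs <- unique(de_table$gene[de_table$p_adjusted < alpha])
  ia <- condition == lev[1]
  res <- lapply(colnames(scores), function(rg) {
    s <- scores[, rg]
    p <- rank_sum_test(s[ia], s[!ia], exact = FALSE)$p_value
    size <- length(regulons[[rg]])
    ndeg <- length(intersect(regulons[[rg]], degs))
    mexpr <- if (is.null(norm)) NA_real_ else {
      tg <- intersect(regulons[[rg]], rownames(norm))
      if (length(tg)) mean(Matrix::rowMeans(norm[tg, , drop = FALSE])) else 0
    }
    data.frame(regulon = rg,
               mean_1 = mean(s[ia]), mean_2 = mean(s[!ia]),
               score_diff = mean(s[ia]) - mean(s[!ia]),
               mean_score = mean(s), mean_expression = mexpr,
               p_value = p, regulon_size = size,
               n_DEG_targets = ndeg, DEG_fraction = ndeg / size,
               stringsAsFactors = FALSE)
  })
  ledger <- do.call(rbind, res)
  names(ledger)[names(ledger) == "mean_1"] <- paste0("mean_", lev[1])
  names(ledger)[names(ledger) == "mean_2"] <- paste0("mean_", lev[2])
  ledger$p_adjusted <- bh_adjust(ledger$p_value)
  expressed <- if (expression_criterion == "expression") {
    ledger$mean_expression > 0
  } else {
    ledger$mean_score > 0
  }
  ledger$pass_flag <- ledger$p_adjusted < alpha &
    expressed &
    ledger$n_DEG_targets >= 1 &
    ledger$DEG_fraction >= deg_fraction
  ledger <- ledger[order(ledger$p_adjusted, ledger$p_value), , drop = FALSE]
  rownames(ledger) <- NULL
  ledger
}
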