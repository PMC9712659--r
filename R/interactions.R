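#' Standardize ligand-receptor orientation
#'
#' Interaction databases mix "ligand-receptor" and "receptor-ligand"
#' notation; this flips receptor-first rows (declared via an
#' \code{orientation} column with values \code{"ligand-receptor"} or
#' \code{"receptor-ligand"}) so every row reads ligand then receptor, and
#' collapses duplicates created by flipping.
#'
#' @param raw_pairs data.frame with columns ligand, receptor, orientation
#'   (and optionally family)
#' @return data.frame with columns ligand, receptor, family
#' @export
standardize_orientation <- function(raw_pairs) {
  stopifnot(all(c("ligand", "receptor", "orientation") %in% names(raw_pairs)))
  ok <- raw_pairs$orientation %in% c("ligand-receptor", "receptor-ligand")
  if (!all(ok)) {
    stop("unknown orientation value(s): ",
         paste(unique(raw_pairs$orientation[!ok]), collapse = ", "))
  }
  flip <- raw_pairs$orientation == "receptor-ligand"
  out <- raw_pairs
  out$ligand[flip] <- raw_pairs$receptor[flip]
  out$receptor[flip] <- raw_pairs$ligand[flip]
  if (is.null(out$family)) out$family <- NA_character_
  out <- out[, c("ligand", "receptor", "family")]
  dup <- duplicated(out[, c("ligand", "receptor")])
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) after orientation flip collapsed")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# per-cluster mean expression and expression fraction for a subset of genes
cluster_gene_stats <- function(norm, clusters, genes) {
  lev <- unique(clusters)
  sub <- as.matrix(norm[genes, , drop = FALSE])
  means <- vapply(lev, function(cl) rowMeans(sub[, clusters == cl, drop = FALSE]),
                  numeric(length(genes)))
  fracs <- vapply(lev, function(cl) rowMeans(sub[, clusters == cl, drop = FALSE] > 0),
                  numeric(length(genes)))
  if (length(genes) == 1) {
    means <- matrix(means, 1, dimnames = list(genes, lev))
    fracs <- matrix(fracs, 1, dimnames = list(genes, lev))
  }
  list(means = means, fracs = fracs, clusters = lev)
}

#' Cluster-pair ligand-receptor mean expression
#'
#' For every (sender cluster, receiver cluster, pair), the pair mean is the
#' arithmetic mean of the ligand's mean expression in the sender and the
#' receptor's mean expression in the receiver. A pair is flagged
#' non-expressed when the ligand is detected in fewer than
#' \code{min_expr_frac} of sender cells or the receptor in fewer than
#' \code{min_expr_frac} of receiver cells. Pairs with a gene absent from
#' the universe are skipped with a warning.
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param clusters per-cell cluster labels
#' @param pairs data.frame with ligand and receptor columns
#' @param min_expr_frac minimum expressing-cell fraction (default 0.1)
#' @return data.frame: sender, receiver, ligand, receptor, pair_mean,
#'   expressed_flag
#' @export
lr_pair_means <- function(norm, clusters, pairs, min_expr_frac = 0.1) {
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == ncol(norm), nrow(pairs) >= 1)
  present <- pairs$ligand %in% rownames(norm) & pairs$receptor %in% rownames(norm)
  if (any(!present)) {
    warning(sum(!present), " pair(s) with genes absent from the universe skipped")
    pairs <- pairs[present, , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no usable pairs")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  st <- cluster_gene_stats(norm, clusters, genes)
  grid <- expand.grid(sender = st$clusters, receiver = st$clusters,
                      pair = seq_len(nrow(pairs)),
                      stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$pair]; rec <- pairs$receptor[grid$pair]
  out <- data.frame(
    sender = grid$sender, receiver = grid$receiver,
    ligand = lig, receptor = rec,
    pair_mean = (st$means[cbind(lig, grid$sender)] +
                   st$means[cbind(rec, grid$receiver)]) / 2,
    expressed_flag = st$fracs[cbind(lig, grid$sender)] >= min_expr_frac &
      st$fracs[cbind(rec, grid$receiver)] >= min_expr_frac,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Permutation significance of cluster-pair interactions
#'
#' The null distribution of each (sender, receiver, pair) mean is generated
#' by shuffling the cluster labels \code{n_perm} times; the add-one p-value
#' is \code{(1 + #(permuted pair_mean >= observed)) / (n_perm + 1)}, so p
#' lies on the grid \code{1/(n_perm+1) .. 1} and is never 0. Non-expressed
#' pairs are reported with a missing p-value.
#'
#' @inheritParams lr_pair_means
#' @param n_perm number of label permutations (default 1000)
#' @param seed permutation seed
#' @return the \code{\link{lr_pair_means}} table with a \code{p_value}
#'   column
#' @export
lr_permutation_test <- function(norm, clusters, pairs, n_perm = 1000,
                                seed = 1L, min_expr_frac = 0.1) {
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2) stop("at least 2 clusters required")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value grid")
  obs <- lr_pair_means(norm, clusters, pairs, min_expr_frac)
  present <- pairs$ligand %in% rownames(norm) & pairs$receptor %in% rownames(norm)
  pairs <- pairs[present, , drop = FALSE]
  genes <- unique(c(pairs$ligand, pairs$receptor))
  sub <- as.matrix(norm[genes, , drop = FALSE])
  lev <- unique(clusters)
  lig <- obs$ligand; rec <- obs$receptor
  exceed <- numeric(nrow(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- clusters[sample.int(length(clusters))]
      means <- vapply(lev, function(cl)
        rowMeans(sub[, perm == cl, drop = FALSE]), numeric(length(genes)))
      if (length(genes) == 1) means <- matrix(means, 1, dimnames = list(genes, lev))
      pm <- (means[cbind(lig, obs$sender)] + means[cbind(rec, obs$receiver)]) / 2
      exceed <- exceed + (pm >= obs$pair_mean)
    }
  })
  obs$p_value <- (1 + exceed) / (n_perm + 1)
  obs$p_value[!obs$expressed_flag] <- NA_real_
  obs
}

#' Differential ligand-receptor pair expression between two groups
#'
#' Per cell, a pair's expression is the mean of its ligand and receptor
#' normalized expression; pairs are compared between groups with a
#' two-sided Wilcoxon rank-sum test, BH-adjusted over pairs. The fold
#' change is the log2 ratio of de-logged group means with pseudocount 1
#' (group A over group B), consistent with the differential-expression
#' convention.
#'
#' @param norm_a,norm_b gene-by-cell log-normalized matrices for the two
#'   groups (e.g. mutant and wild-type macrophages), each >= 3 cells
#' @param pairs data.frame with ligand and receptor columns
#' @return data.frame: ligand, receptor, mean_a, mean_b, log2_fold_change,
#'   p_value, p_adjusted
#' @export
lr_differential <- function(norm_a, norm_b, pairs) {
  if (ncol(norm_a) < 3 || ncol(norm_b) < 3) stop("each group needs at least 3 cells")
  present <- pairs$ligand %in% rownames(norm_a) & pairs$receptor %in% rownames(norm_a) &
    pairs$ligand %in% rownames(norm_b) & pairs$receptor %in% rownames(norm_b)
  if (any(!present)) {
    warning(sum(!present), " pair(s) absent from a universe skipped")
    pairs <- pairs[present, , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no usable pairs")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xa <- (as.numeric(norm_a[pairs$ligand[i], ]) +
             as.numeric(norm_a[pairs$receptor[i], ])) / 2
    xb <- (as.numeric(norm_b[pairs$ligand[i], ]) +
             as.numeric(norm_b[pairs$receptor[i], ])) / 2
    data.frame(ligand = pairs$ligand[i], receptor = pairs$receptor[i],
               mean_a = mean(xa), mean_b = mean(xb),
               log2_fold_change = log2(delog_mean1(xa) / delog_mean1(xb)),
               p_value = rank_sum_test(xa, xb, exact = FALSE)$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}
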