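#' Binned expression profile along pseudotime
#'
#' Cells are assigned to \code{n_bins} equal-width bins over the observed
#' pseudotime range; the profile is the mean normalized expression of the
#' gene per bin. Empty bins carry NA and are removed pairwise by the
#' downstream similarity test.
#'
#' @param norm gene-by-cell log-normalized matrix
#' @param pseudotime per-cell pseudotime, aligned with \code{colnames(norm)};
#'   cells with NA pseudotime are dropped
#' @param gene gene symbol
#' @param n_bins number of bins (default 20)
#' @return list with \code{gene}, \code{bin_means}, \code{bin_counts},
#'   \code{breaks}
#' @export
bin_profile <- function(norm, pseudotime, gene, n_bins = 20) {
  stopifnot(length(pseudotime) == ncol(norm), n_bins >= 2)
  if (!gene %in% rownames(norm)) stop("gene '", gene, "' absent from matrix")
  ok <- !is.na(pseudotime)
  t <- pseudotime[ok]
  x <- as.numeric(norm[gene, ok])
  if (!length(t)) stop("no cells with pseudotime")
  if (diff(range(t)) == 0) {
    stop("all cells share one pseudotime value; use fewer bins or check input")
  }
  breaks <- seq(min(t), max(t), length.out = n_bins + 1)
  bin <- cut(t, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  if (length(unique(bin)) == 1) {
    stop("all cells fall in one bin; use fewer bins")
  }
  means <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  agg <- tapply(x, bin, mean)
  means[as.integer(names(agg))] <- agg
  tab <- table(bin)
  counts[as.integer(names(tab))] <- as.integer(tab)
  list(gene = gene, n_bins = n_bins, bin_means = means, bin_counts = counts,
       breaks = breaks)
}

#' Cosine similarity of two vectors
#'
#' \code{dot(u, v) / (|u| |v|)}; positions where either vector is NA are
#' removed pairwise first. Zero-norm vectors yield NA.
#'
#' @param u,v numeric vectors of equal length
#' @return cosine similarity in [-1, 1], or NA
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  ok <- !is.na(u) & !is.na(v)
  u <- u[ok]; v <- v[ok]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Permutation test of cosine similarity between two binned profiles
#'
#' The null is generated by permuting the bin order of the second profile;
#' the two-sided add-one p-value is
#' \code{(1 + #(|cos_perm| >= |cos_obs|)) / (n_perm + 1)}, on the grid
#' \code{1/(n_perm+1) .. 1}.
#'
#' @param profile_a,profile_b results of \code{\link{bin_profile}} on the
#'   same bin grid, or plain numeric vectors
#' @param n_perm number of permutations (default 1000)
#' @param seed permutation seed
#' @return list with \code{cosine}, \code{p_value}, \code{n_perm},
#'   \code{seed}, \code{n_bins_used}
#' @export
cosine_perm_test <- function(profile_a, profile_b, n_perm = 1000, seed = 1L) {
  u <- if (is.list(profile_a)) profile_a$bin_means else as.numeric(profile_a)
  v <- if (is.list(profile_b)) profile_b$bin_means else as.numeric(profile_b)
  stopifnot(length(u) == length(v))
  ok <- !is.na(u) & !is.na(v)
  u <- u[ok]; v <- v[ok]
  if (length(u) < 4) stop("fewer than 4 usable bins: permutation space too small")
  obs <- cosine_similarity(u, v)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      abs(cosine_similarity(u, v[sample.int(length(v))])) >= abs(obs) - 1e-12
    }, logical(1)))
  })
  list(cosine = obs, p_value = (1 + exceed) / (n_perm + 1),
       n_perm = n_perm, seed = seed, n_bins_used = length(u))
}
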