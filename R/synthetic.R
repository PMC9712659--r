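#' Build a simulation configuration
#'
#' Describes a synthetic droplet scRNA-seq experiment with planted ground
#' truth: negative-binomial counts with cluster-specific marker programs,
#' genotype effects, TF-coupled regulon programs, cluster-restricted
#' ligand/receptor expression, a pseudotime expression ramp, and planted
#' doublets. All effect sizes are multiplicative fold changes on the
#' negative-binomial mean.
#'
#' @param cells data.frame with columns cluster, genotype, treatment, n —
#'   the number of cells per stratum
#' @param n_genes total gene universe size (filler genes are added up to it)
#' @param baseline_mean baseline NB mean per gene per cell; a scalar, or a
#'   vector with one entry per gene in universe order (real transcriptomes
#'   span orders of magnitude, which the mean-variance trend of
#'   variable-gene selection relies on)
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2),
#'   shared across genes
#' @param lib_sdlog sd of the log-normal per-cell library size factor
#' @param cluster_markers data.frame(gene, cluster, fold): marker genes
#'   up-regulated fold-fold in one cluster
#' @param genotype_effects data.frame(gene, genotype, fold): genes shifted in
#'   all cells of one genotype (the substrate for differential expression,
#'   differential regulons and differential ligand-receptor pairs)
#' @param regulons named list of regulons (character vectors of targets,
#'   names are TFs); combined with \code{regulon_active} to plant activity
#' @param regulon_active data.frame(regulon, cluster, fold) or
#'   data.frame(regulon, genotype, fold): where each regulon's targets (and
#'   its TF) are up-regulated
#' @param lr_spec data.frame(ligand, receptor, sender, receiver, fold):
#'   ligand up in sender cluster, receptor up in receiver cluster
#' @param pseudotime_spec data.frame(gene, direction, amplitude): genes with
#'   a multiplicative exponential ramp exp(amplitude * direction * t) along
#'   pseudotime
#' @param pseudotime_clusters clusters whose cells receive a pseudotime
#'   uniform on [0, 1] (others get NA)
#' @param doublet_fraction fraction of barcodes that are doublets, in [0, 1)
#' @param mito_genes number of mitochondrial ("mt-"-prefixed) genes included
#' @param gene_names optional explicit gene universe; every gene named in a
#'   spec must be present in it
#' @param seed integer seed; a fixed seed gives byte-identical output
#' @return a list of class \code{sim_config}
#' @export
sim_config <- function(cells = data.frame(cluster = rep(c("C1", "C2", "C3"), each = 2),
                                          genotype = rep(c("WT", "Mut"), 3),
                                          treatment = "AngII",
                                          n = 100),
                       n_genes = 200,
                       baseline_mean = 2,
                       nb_dispersion = 0.3,
                       lib_sdlog = 0.2,
                       cluster_markers = NULL,
                       genotype_effects = NULL,
                       regulons = NULL,
                       regulon_active = NULL,
                       lr_spec = NULL,
                       pseudotime_spec = NULL,
                       pseudotime_clusters = NULL,
                       doublet_fraction = 0,
                       mito_genes = 0,
                       gene_names = NULL,
                       seed = 1L) {
  stopifnot(is.data.frame(cells), all(cells$n > 0),
            n_genes >= 1, all(baseline_mean > 0), nb_dispersion > 0,
            doublet_fraction >= 0, doublet_fraction < 1)
  if (!is.null(cluster_markers) && any(cluster_markers$fold <= 0)) {
    config_error("marker fold changes must be > 0")
  }
  named <- unique(c(
    if (!is.null(cluster_markers)) cluster_markers$gene,
    if (!is.null(genotype_effects)) genotype_effects$gene,
    if (!is.null(regulons)) c(names(regulons), unlist(regulons, use.names = FALSE)),
    if (!is.null(regulon_active)) as.character(regulon_active$regulon),
    if (!is.null(lr_spec)) c(lr_spec$ligand, lr_spec$receptor),
    if (!is.null(pseudotime_spec)) pseudotime_spec$gene))
  if (is.null(gene_names)) {
    n_fill <- n_genes - length(named) - mito_genes
    if (n_fill < 0) config_error("n_genes smaller than the number of named genes")
    gene_names <- c(named,
                    if (mito_genes > 0) paste0("mt-Gene", seq_len(mito_genes)),
                    if (n_fill > 0) sprintf("Bg%04d", seq_len(n_fill)))
    if (anyDuplicated(gene_names)) {
      config_error("gene universe contains duplicate symbols")
    }
  } else {
    missing <- setdiff(named, gene_names)
    if (length(missing)) {
      config_error("genes named in a spec are absent from the gene universe: ",
                   paste(head(missing, 5), collapse = ", "))
    }
  }
  if (!length(baseline_mean) %in% c(1L, length(gene_names))) {
    config_error("baseline_mean must be a scalar or one value per gene")
  }
  structure(list(cells = cells, n_genes = length(gene_names),
                 baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
                 lib_sdlog = lib_sdlog,
                 cluster_markers = cluster_markers,
                 genotype_effects = genotype_effects,
                 regulons = regulons, regulon_active = regulon_active,
                 lr_spec = lr_spec,
                 pseudotime_spec = pseudotime_spec,
                 pseudotime_clusters = pseudotime_clusters,
                 doublet_fraction = doublet_fraction,
                 gene_names = gene_names, seed = as.integer(seed)),
            class = "sim_config")
}

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Simulate a single-cell dataset with planted ground truth
#'
#' Counts are negative binomial with gene-by-cell mean
#' \eqn{\mu = baseline \times cluster fold \times genotype fold \times
#' regulon fold \times e^{amplitude \cdot direction \cdot t}} times a
#' log-normal library-size factor. Planted doublets are the sum of the
#' barcode's own counts and those of another random cell, with a doublet
#' score drawn above 0.5 (singlets below 0.5).
#'
#' @param config a \code{\link{sim_config}}
#' @return list with elements \code{counts} (gene-by-cell sparse matrix),
#'   \code{meta} (per-cell data.frame: cell_id, cluster, genotype, treatment,
#'   pseudotime, doublet_score) and \code{truth} (planted markers, genotype
#'   effects, regulon activity, ligand-receptor pairs, doublet cell ids)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  cells <- config$cells
  n_cells <- sum(cells$n)
  genes <- config$gene_names
  n_genes <- length(genes)
  meta <- data.frame(
    cell_id = sprintf("cell_%05d", seq_len(n_cells)),
    cluster = rep(as.character(cells$cluster), cells$n),
    genotype = rep(as.character(cells$genotype), cells$n),
    treatment = rep(as.character(cells$treatment), cells$n),
    stringsAsFactors = FALSE)

  # pseudotime uniform on [0,1] within designated clusters
  meta$pseudotime <- NA_real_
  if (!is.null(config$pseudotime_clusters)) {
    idx <- meta$cluster %in% config$pseudotime_clusters
    meta$pseudotime[idx] <- runif(sum(idx))
  }

  # per-gene x per-cluster / per-genotype fold factors
  clusters <- unique(meta$cluster)
  genotypes <- unique(meta$genotype)
  fold_cl <- matrix(1, n_genes, length(clusters), dimnames = list(genes, clusters))
  fold_gt <- matrix(1, n_genes, length(genotypes), dimnames = list(genes, genotypes))
  # spec rows naming a cluster/genotype absent from this dataset are inert
  cm <- config$cluster_markers
  if (!is.null(cm)) {
    for (i in seq_len(nrow(cm))) {
      cl <- as.character(cm$cluster[i])
      if (!cl %in% clusters) next
      fold_cl[cm$gene[i], cl] <- fold_cl[cm$gene[i], cl] * cm$fold[i]
    }
  }
  ge <- config$genotype_effects
  if (!is.null(ge)) {
    for (i in seq_len(nrow(ge))) {
      gt <- as.character(ge$genotype[i])
      if (!gt %in% genotypes) next
      fold_gt[ge$gene[i], gt] <- fold_gt[ge$gene[i], gt] * ge$fold[i]
    }
  }
  ra <- config$regulon_active
  if (!is.null(ra)) {
    for (i in seq_len(nrow(ra))) {
      reg <- config$regulons[[as.character(ra$regulon[i])]]
      members <- unique(c(as.character(ra$regulon[i]), reg))
      if (!is.null(ra$cluster)) {
        cl <- as.character(ra$cluster[i])
        if (!cl %in% clusters) next
        fold_cl[members, cl] <- fold_cl[members, cl] * ra$fold[i]
      } else {
        gt <- as.character(ra$genotype[i])
        if (!gt %in% genotypes) next
        fold_gt[members, gt] <- fold_gt[members, gt] * ra$fold[i]
      }
    }
  }
  lr <- config$lr_spec
  if (!is.null(lr)) {
    for (i in seq_len(nrow(lr))) {
      snd <- as.character(lr$sender[i]); rcv <- as.character(lr$receiver[i])
      if (snd %in% clusters) {
        fold_cl[lr$ligand[i], snd] <- fold_cl[lr$ligand[i], snd] * lr$fold[i]
      }
      if (rcv %in% clusters) {
        fold_cl[lr$receptor[i], rcv] <- fold_cl[lr$receptor[i], rcv] * lr$fold[i]
      }
    }
  }

  # gene x cell mean matrix built column-block-wise per (cluster, genotype)
  libf <- rlnorm(n_cells, meanlog = 0, sdlog = config$lib_sdlog)
  mu <- fold_cl[, meta$cluster, drop = FALSE] * fold_gt[, meta$genotype, drop = FALSE]
  mu <- mu * config$baseline_mean
  pt <- config$pseudotime_spec
  if (!is.null(pt)) {
    t_cell <- ifelse(is.na(meta$pseudotime), 0, meta$pseudotime)
    for (i in seq_len(nrow(pt))) {
      mu[pt$gene[i], ] <- mu[pt$gene[i], ] *
        exp(pt$amplitude[i] * pt$direction[i] * t_cell)
    }
  }
  mu <- sweep(mu, 2, libf, "*")
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / config$nb_dispersion),
                   nrow = n_genes, dimnames = list(genes, meta$cell_id))

  # doublets: overwrite a random subset of barcodes with the sum of two cells
  n_doub <- round(config$doublet_fraction * n_cells)
  meta$doublet_score <- runif(n_cells, 0, 0.5)
  doublet_ids <- character(0)
  if (n_doub > 0) {
    doub <- sample.int(n_cells, n_doub)
    partner <- sample.int(n_cells, n_doub, replace = TRUE)
    counts[, doub] <- counts[, doub] + counts[, partner]
    meta$doublet_score[doub] <- runif(n_doub, 0.5, 1)
    doublet_ids <- meta$cell_id[doub]
  }

  truth <- list(cluster_markers = cm, genotype_effects = ge,
                regulon_active = ra, lr_spec = lr,
                pseudotime_spec = pt, doublets = doublet_ids)
  list(counts = as_dgc(counts), meta = meta, truth = truth)
}

#' Simulate two datasets with a known cluster correspondence
#'
#' Both datasets share the same marker programs for corresponding clusters
#' but are drawn with independent noise; dataset B's cluster labels are
#' renamed and shuffled so that the correspondence is non-trivial.
#'
#' @param n_shared_clusters number of shared clusters (>= 2)
#' @param n_cells_per_cluster cells per cluster in each dataset
#' @param n_genes gene universe size
#' @param n_markers_per_cluster marker genes planted per cluster
#' @param marker_fold fold change of the planted markers
#' @param seed integer seed
#' @return list with \code{a}, \code{b} (each a \code{simulate_dataset}
#'   result) and \code{correspondence} (data.frame cluster_a, cluster_b)
#' @export
simulate_paired_datasets <- function(n_shared_clusters = 3,
                                     n_cells_per_cluster = 100,
                                     n_genes = 300,
                                     n_markers_per_cluster = 10,
                                     marker_fold = 6,
                                     seed = 1L) {
  stopifnot(n_shared_clusters >= 2)
  k <- n_shared_clusters
  cl_a <- paste0("A", seq_len(k))
  markers <- data.frame(
    gene = sprintf("Marker%03d", seq_len(k * n_markers_per_cluster)),
    cluster = rep(cl_a, each = n_markers_per_cluster),
    fold = marker_fold, stringsAsFactors = FALSE)
  make_cfg <- function(cl_names, cl_map, s) {
    m <- markers
    m$cluster <- cl_map[m$cluster]
    sim_config(cells = data.frame(cluster = cl_names, genotype = "WT",
                                  treatment = "none", n = n_cells_per_cluster),
               n_genes = n_genes, cluster_markers = m, seed = s)
  }
  a <- simulate_dataset(make_cfg(cl_a, setNames(cl_a, cl_a), seed))
  # shuffle the labels of dataset B under a derived seed
  perm <- with_seed(seed + 1000L, sample.int(k))
  cl_b <- paste0("B", perm)
  map <- setNames(cl_b, cl_a)
  b <- simulate_dataset(make_cfg(sort(cl_b), map, seed + 2000L))
  list(a = a, b = b,
       correspondence = data.frame(cluster_a = cl_a, cluster_b = unname(map),
                                   stringsAsFactors = FALSE))
}
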