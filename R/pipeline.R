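#' Default demonstration pipeline configuration
#'
#' A complete configuration exercising every stage on simulated data:
#' three macrophage-like clusters with planted markers, a genotype effect
#' driving differential genes and one differential regulon, one planted
#' sender-receiver chemokine pair, a pseudotime ramp gene, and planted
#' doublets. Stage parameter defaults are the conventional droplet-QC and
#' marker thresholds (min 10 cells per gene, 10th-90th percentile cell
#' filter, doublet score 0.5, scale factor 10,000, min.pct 0.25, logfc
#' 0.25, FDR 0.05, 1000 permutations).
#'
#' @param seed integer seed recorded in, and used by, every stochastic stage
#' @return a nested list understood by \code{\link{run_pipeline}}
#' @export
default_pipeline_config <- function(seed = 1L) {
  regulons <- list(
    TF1 = sprintf("Gene%04d", 1:30),
    TF2 = sprintf("Gene%04d", 31:60),
    TF3 = sprintf("Gene%04d", 61:90))
  n_genes <- 800
  # baseline expression spread over orders of magnitude, as in real data
  baseline <- local({
    set.seed(seed)
    pmin(pmax(exp(rnorm(n_genes, log(1.5), 1)), 0.5), 20)
  })
  list(
    seed = as.integer(seed),
    simulate = list(
      cells = data.frame(cluster = rep(c("C1", "C2", "C3"), each = 2),
                         genotype = rep(c("WT", "Mut"), 3),
                         treatment = "AngII", n = 120),
      n_genes = n_genes,
      baseline_mean = baseline,
      cluster_markers = data.frame(
        gene = c("Ccr2", "Cd72", "Timd4", "Lyve1", "H2-Ab1", "Cd74"),
        cluster = rep(c("C1", "C2", "C3"), each = 2),
        fold = 8),
      genotype_effects = data.frame(
        gene = c("Ccl5", "Isg15", "Ifit3"),
        genotype = "Mut", fold = 3),
      regulons = regulons,
      regulon_active = data.frame(regulon = "TF1", genotype = "Mut", fold = 3),
      lr_spec = data.frame(ligand = "Ccl2", receptor = "Ccr2",
                           sender = "C3", receiver = "C1", fold = 8),
      pseudotime_spec = data.frame(gene = "Cd72", direction = 1, amplitude = 2),
      pseudotime_clusters = c("C1", "C2"),
      doublet_fraction = 0.05,
      mito_genes = 5),
    qc = list(min_cells = 10, lower_pct = 10, upper_pct = 90,
              doublet_threshold = 0.5, mito_prefix = "mt-",
              scale_factor = 10000),
    markers = list(min_pct = 0.25, logfc_threshold = 0.25),
    de = list(group_by = "genotype", contrast = c("Mut", "WT"),
              min_pct = 0.1, logfc_threshold = 0.25, fdr = 0.05),
    specificity = list(),
    regulons = list(contrast = c("Mut", "WT"), n_bins = 24, n_ctrl = 50,
                    alpha = 0.05, deg_fraction = 0.05),
    lr = list(pairs = data.frame(ligand = c("Ccl2", "Ccl5"),
                                 receptor = c("Ccr2", "Ccr2"),
                                 family = "chemokine"),
              n_perm = 200, min_expr_frac = 0.1),
    trajectory = list(genes = c("Ccr2", "Cd72"), n_bins = 10, n_perm = 500))
}

# coerce list-of-lists (e.g. parsed YAML) into the data.frames sim_config wants
as_sim_config <- function(sim, seed) {
  df_fields <- c("cells", "cluster_markers", "genotype_effects",
                 "regulon_active", "lr_spec", "pseudotime_spec")
  for (f in df_fields) {
    if (!is.null(sim[[f]]) && !is.data.frame(sim[[f]])) {
      sim[[f]] <- as.data.frame(sim[[f]], stringsAsFactors = FALSE)
    }
  }
  sim$seed <- seed
  do.call(sim_config, sim)
}

write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full downstream pipeline from one configuration
#'
#' Stages execute in a fixed order — simulate (or load) counts, QC and
#' normalization, cluster markers, genotype differential expression,
#' specificity matrix, regulon scoring and differential-regulon ledger,
#' ligand-receptor permutation and differential tests, pseudotime cosine
#' test — and all tabular results are written as TSV with a header, plus a
#' YAML manifest recording the seed, every stage's parameters and the
#' matrix dimensions after each filter. Given the same configuration the
#' run is deterministic.
#'
#' @param config a nested list (see \code{\link{default_pipeline_config}})
#'   or the path to a YAML file with the same structure; must contain an
#'   integer \code{seed}
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with all in-memory results and the manifest
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("pipeline config must declare a seed")
  seed <- as.integer(config$seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()
  stage <- "simulate"
  tryCatch({
    # ---- inputs
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(as_sim_config(config$simulate, seed))
      counts <- sim$counts; meta <- sim$meta
      results$truth <- sim$truth
      regulon_sets <- config$simulate$regulons
    } else {
      inp <- config$inputs
      counts <- read_counts_mtx(inp$matrix, inp$features, inp$barcodes)
      meta <- read_cell_meta(inp$meta)
      regulon_sets <- if (!is.null(inp$regulons)) read_regulons_tsv(inp$regulons)
    }
    # ---- qc
    stage <- "qc"
    qc <- config$qc
    pp <- preprocess(counts, meta,
                     min_cells = qc$min_cells %||% 10,
                     lower_pct = qc$lower_pct %||% 10,
                     upper_pct = qc$upper_pct %||% 90,
                     doublet_threshold = qc$doublet_threshold %||% 0.5,
                     mito_prefix = qc$mito_prefix %||% "mt-",
                     scale_factor = qc$scale_factor %||% 10000)
    norm <- pp$norm; meta <- pp$meta
    results$qc_log <- pp$log
    write_counts_mtx(pp$counts, file.path(out_dir, "filtered_counts"))
    write_tsv(meta, file.path(out_dir, "cell_meta.tsv"))
    # ---- markers
    if (!is.null(config$markers)) {
      stage <- "markers"
      mk <- config$markers
      results$markers <- find_all_markers(norm, meta$cluster,
                                          min_pct = mk$min_pct %||% 0.25,
                                          logfc_threshold = mk$logfc_threshold %||% 0.25)
      write_tsv(results$markers, file.path(out_dir, "markers.tsv"))
    }
    # ---- genotype DE
    if (!is.null(config$de)) {
      stage <- "de"
      de <- config$de
      grp <- meta[[de$group_by %||% "genotype"]]
      contrast <- de$contrast %||% unique(grp)[1:2]
      results$de <- wilcoxon_de(norm,
                                meta$cell_id[grp == contrast[1]],
                                meta$cell_id[grp == contrast[2]],
                                min_pct = de$min_pct %||% 0.1,
                                logfc_threshold = de$logfc_threshold %||% 0.25)
      write_tsv(results$de, file.path(out_dir, "de.tsv"))
    }
    # ---- specificity
    if (!is.null(config$specificity)) {
      stage <- "specificity"
      sp <- specificity_matrix(norm, meta$cluster)
      results$specificity <- sp
      write_tsv(data.frame(gene = rownames(sp$values), sp$values,
                           check.names = FALSE),
                file.path(out_dir, "specificity.tsv"))
    }
    # ---- regulons
    if (!is.null(config$regulons) && !is.null(regulon_sets)) {
      stage <- "regulons"
      rg <- config$regulons
      contrast <- rg$contrast %||% c("Mut", "WT")
      keep <- meta$genotype %in% contrast
      scores <- module_score_matrix(norm[, keep, drop = FALSE], regulon_sets,
                                    n_bins = rg$n_bins %||% 24,
                                    n_ctrl = rg$n_ctrl %||% 100, seed = seed)
      results$regulon_auc <- regulon_auc(norm, regulon_sets, seed = seed)
      results$regulon_ledger <- differential_regulons(
        scores, meta$genotype[keep], results$de, regulon_sets,
        alpha = rg$alpha %||% 0.05, deg_fraction = rg$deg_fraction %||% 0.05,
        norm = norm[, keep, drop = FALSE], group1 = contrast[1])
      write_tsv(results$regulon_ledger, file.path(out_dir, "regulon_ledger.tsv"))
    }
    # ---- ligand-receptor
    if (!is.null(config$lr)) {
      stage <- "lr"
      lr <- config$lr
      pairs <- lr$pairs
      if (is.character(pairs)) pairs <- read_lr_pairs(pairs)
      if (!is.data.frame(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
      results$lr_perm <- lr_permutation_test(norm, meta$cluster, pairs,
                                             n_perm = lr$n_perm %||% 1000,
                                             seed = seed,
                                             min_expr_frac = lr$min_expr_frac %||% 0.1)
      write_tsv(results$lr_perm, file.path(out_dir, "lr_permutation.tsv"))
      if (!is.null(config$de)) {
        grp <- meta[[config$de$group_by %||% "genotype"]]
        contrast <- config$de$contrast %||% unique(grp)[1:2]
        results$lr_diff <- lr_differential(
          norm[, grp == contrast[1], drop = FALSE],
          norm[, grp == contrast[2], drop = FALSE], pairs)
        write_tsv(results$lr_diff, file.path(out_dir, "lr_differential.tsv"))
      }
    }
    # ---- trajectory
    if (!is.null(config$trajectory) && !all(is.na(meta$pseudotime))) {
      stage <- "trajectory"
      tr <- config$trajectory
      genes <- tr$genes
      genes <- genes[genes %in% rownames(norm)]
      if (length(genes) >= 2) {
        profs <- lapply(genes, function(g)
          bin_profile(norm, meta$pseudotime, g, n_bins = tr$n_bins %||% 20))
        sim_res <- cosine_perm_test(profs[[1]], profs[[2]],
                                    n_perm = tr$n_perm %||% 1000, seed = seed)
        results$trajectory <- list(profiles = profs, similarity = sim_res)
        write_tsv(data.frame(gene = c(genes[1], genes[2]),
                             t(vapply(profs[1:2], function(p) p$bin_means,
                                      numeric(tr$n_bins %||% 20)))),
                  file.path(out_dir, "trajectory_profiles.tsv"))
        write_tsv(data.frame(gene_a = genes[1], gene_b = genes[2],
                             cosine = sim_res$cosine, p_value = sim_res$p_value,
                             n_perm = sim_res$n_perm),
                  file.path(out_dir, "trajectory_similarity.tsv"))
      }
    }
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  # ---- manifest
  manifest <- list(
    package = "scdownstream",
    version = as.character(utils::packageVersion("scdownstream")),
    seed = seed,
    stage_dimensions = lapply(results$qc_log, function(d)
      list(genes = d[1], cells = d[2])),
    table_rows = list(
      markers = if (!is.null(results$markers)) nrow(results$markers),
      de = if (!is.null(results$de)) nrow(results$de),
      regulon_ledger = if (!is.null(results$regulon_ledger)) nrow(results$regulon_ledger),
      lr_perm = if (!is.null(results$lr_perm)) nrow(results$lr_perm)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
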