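#' Read a 10x-style MatrixMarket count matrix
#'
#' Reads a MatrixMarket coordinate file together with its features and
#' barcodes sidecars and returns a sparse gene-by-cell count matrix. The
#' on-disk orientation follows the 10x convention (features in rows,
#' barcodes in columns); missing coordinates are zero.
#'
#' Feature files may have one column (symbol) or two or more tab-separated
#' columns (id, symbol, ...); in the multi-column case the second (symbol)
#' column is used and duplicate symbols are disambiguated by suffixing
#' ".1", ".2", ...
#'
#' @param matrix_path path to the MatrixMarket (.mtx) file
#' @param features_path path to the features/genes file, one entry per line
#' @param barcodes_path path to the barcodes file, one entry per line
#' @return a \code{dgCMatrix} of non-negative integer counts, genes in rows
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(barcodes_path)
  genes <- if (ncol(feats) >= 2) as.character(feats[[2]]) else as.character(feats[[1]])
  if (nrow(feats) != nrow(m)) {
    format_error("features file has ", nrow(feats), " entries but matrix header declares ",
                 nrow(m), " rows")
  }
  if (length(barcodes) != ncol(m)) {
    format_error("barcodes file has ", length(barcodes), " entries but matrix header declares ",
                 ncol(m), " columns")
  }
  genes <- make.unique(genes, sep = ".")
  m <- as_dgc(m)
  dimnames(m) <- list(genes, barcodes)
  validate_counts(m, integer_only = TRUE)
}

#' Write a count matrix as MatrixMarket plus sidecar files
#'
#' Inverse of \code{\link{read_counts_mtx}}: writes \code{matrix.mtx},
#' \code{features.tsv} and \code{barcodes.tsv} into \code{dir}. Integer
#' counts round-trip bit-exactly.
#'
#' @param counts gene-by-cell sparse count matrix with dimnames
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_counts_mtx <- function(counts, dir) {
  counts <- validate_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(counts, paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. The description is
#' discarded; duplicate genes within a line are removed with a warning.
#'
#' @param path path to a .gmt file
#' @return a named list of character vectors of gene symbols
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      format_error("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", fields[1], "' contains duplicate genes; deduplicated")
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
  }
  sets
}

#' Read a regulon table (long TSV: tf, target)
#'
#' @param path TSV with header columns \code{tf} and \code{target}
#' @return a named list of regulons; each element is the character vector of
#'   target symbols, named by its transcription factor
#' @export
read_regulons_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(tab))) {
    format_error("regulon table must have 'tf' and 'target' columns")
  }
  lapply(split(tab$target, tab$tf), unique)
}

#' Read a ligand-receptor pair table
#'
#' TSV with header columns \code{ligand} and \code{receptor}; an optional
#' \code{family} column carries the interaction family. Rows can be
#' restricted to the chemokine families (gene symbols starting CCL-, CCR-
#' or CX-, case-insensitively) with \code{chemokine_only}. Duplicate
#' (ligand, receptor) rows are collapsed with a warning.
#'
#' @param path path to the TSV
#' @param chemokine_only keep only pairs whose ligand or receptor symbol
#'   starts with a chemokine-family prefix (default FALSE)
#' @param families prefixes defining the chemokine families
#' @return data.frame with columns ligand, receptor, family
#' @export
read_lr_pairs <- function(path, chemokine_only = FALSE,
                          families = c("Ccl", "Ccr", "Cx")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab))) {
    format_error("ligand-receptor table must have 'ligand' and 'receptor' columns")
  }
  if (is.null(tab$family)) tab$family <- NA_character_
  tab <- tab[, c("ligand", "receptor", "family")]
  if (anyDuplicated(tab[, c("ligand", "receptor")])) {
    warning("duplicate (ligand, receptor) rows collapsed")
    tab <- tab[!duplicated(tab[, c("ligand", "receptor")]), , drop = FALSE]
  }
  if (chemokine_only) tab <- filter_chemokine_pairs(tab, families)
  rownames(tab) <- NULL
  tab
}

#' Restrict a pair table to chemokine-family pairs
#'
#' A pair is retained when its ligand or its receptor symbol begins with one
#' of the family prefixes (case-insensitive prefix match).
#'
#' @param pairs data.frame with ligand and receptor columns
#' @param families character vector of symbol prefixes
#' @return the filtered pair table
#' @export
filter_chemokine_pairs <- function(pairs, families = c("Ccl", "Ccr", "Cx")) {
  pat <- paste0("^(", paste(families, collapse = "|"), ")")
  keep <- grepl(pat, pairs$ligand, ignore.case = TRUE) |
    grepl(pat, pairs$receptor, ignore.case = TRUE)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read per-cell metadata
#'
#' TSV with header; must contain \code{cell_id}; typical further columns are
#' cluster, genotype, treatment, pseudotime and doublet_score.
#'
#' @param path path to the TSV
#' @return data.frame, one row per cell
#' @export
read_cell_meta <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(meta)) format_error("metadata must have a 'cell_id' column")
  validate_meta(meta)
}

#' Read a two-column ortholog map
#'
#' @param path TSV with header columns \code{source_symbol}, \code{target_symbol}
#' @return data.frame with those two columns
#' @export
read_ortholog_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_symbol", "target_symbol") %in% names(tab))) {
    format_error("ortholog map must have 'source_symbol' and 'target_symbol' columns")
  }
  tab[, c("source_symbol", "target_symbol")]
}

#' Rename genes through an ortholog map
#'
#' Renaming is the only symbol-translation mechanism in the package; symbols
#' are otherwise matched case-sensitively. Genes absent from the map keep
#' their symbol. Many-to-one collisions after mapping are disambiguated with
#' ".1", ".2" suffixes and reported with a warning.
#'
#' @param counts gene-by-cell matrix
#' @param map data.frame as returned by \code{\link{read_ortholog_map}}
#' @return the matrix with translated rownames
#' @export
apply_ortholog_map <- function(counts, map) {
  idx <- match(rownames(counts), map$source_symbol)
  new <- ifelse(is.na(idx), rownames(counts), map$target_symbol[idx])
  if (anyDuplicated(new)) {
    warning("ortholog mapping produced duplicate symbols; suffixed to keep unique")
    new <- make.unique(new, sep = ".")
  }
  rownames(counts) <- new
  counts
}
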