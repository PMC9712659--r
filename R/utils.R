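#' @importFrom methods as is
#' @importFrom stats quantile rnbinom rlnorm runif rbinom cor ks.test
#'   p.adjust phyper pnorm var lm residuals predict poly setNames
#'   complete.cases
#' @importFrom utils combn head read.delim write.table
NULL

# internal: stop with a consistent "format error" class so callers can test it
format_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("scd_format_error", "error")))
}

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("scd_config_error", "error")))
}

# dense or any sparse Matrix class -> dgCMatrix
as_dgc <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE, doDiag = FALSE)
  if (!methods::is(x, "sparseMatrix")) {
    format_error("counts must be a matrix or sparse Matrix (genes x cells)")
  }
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

# type-7 (linear interpolation between order statistics) percentile
pctl <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

# coerce to a sparse dgCMatrix, validating the count-matrix invariants:
# genes in rows, cells in columns, unique non-empty dimnames, no negatives
validate_counts <- function(counts, integer_only = FALSE) {
  counts <- as_dgc(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    format_error("counts must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) format_error("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) format_error("duplicate cell ids")
  if (length(counts@x) && min(counts@x) < 0) format_error("negative entries in count matrix")
  if (integer_only && length(counts@x) && any(counts@x != round(counts@x))) {
    format_error("non-integer values in count matrix")
  }
  counts
}

validate_meta <- function(meta, counts = NULL) {
  stopifnot(is.data.frame(meta), "cell_id" %in% names(meta))
  if (anyDuplicated(meta$cell_id)) format_error("duplicate cell_id in metadata")
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), meta$cell_id)
    if (length(missing)) {
      format_error("metadata missing ", length(missing), " cells (e.g. ",
                   missing[1], ")")
    }
    meta <- meta[match(colnames(counts), meta$cell_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

# subset metadata to the cells of a (possibly filtered) matrix, in order
align_meta <- function(meta, counts) {
  validate_meta(meta, counts)
}
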