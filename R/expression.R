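#' Read a gene x sample count matrix
#'
#' TSV with gene ids in the first column and one column per sample.
#'
#' @param path Path to the counts TSV.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Counts-per-million normalization
#'
#' `CPM = count / library_size * 1e6`, the per-sample normalization by total
#' mapped reads.  Library sizes default to the column sums of the supplied
#' matrix (the panel-restricted totals); pass genome-wide totals when
#' available.
#'
#' @param counts Genes x samples count matrix.
#' @param library_sizes Optional per-sample totals, aligned with columns.
#' @return A CPM matrix of the same shape.
#' @export
cpm_normalize <- function(counts, library_sizes = NULL) {
  lib <- library_sizes %||% colSums(counts)
  bad <- lib == 0 & colSums(counts) > 0
  if (any(bad))
    abort(paste0("zero library size with nonzero counts: ",
                 paste(colnames(counts)[bad], collapse = ", ")))
  lib[lib == 0] <- 1  # all-zero column stays all-zero
  edgeR::cpm(counts, lib.size = lib)
}

#' Flag genes with low expression everywhere
#'
#' A gene is flagged low when its CPM is below the threshold in every
#' sample (the rule used to set aside genes whose expression is too low to
#' interpret across all tissues).
#'
#' @param cpm A CPM matrix.
#' @param cpm_low_threshold Threshold (default 10).
#' @return Named logical vector, one entry per gene.
#' @export
flag_low_expression <- function(cpm, cpm_low_threshold = 10) {
  if (nrow(cpm) == 0) return(setNames(logical(0), character(0)))
  setNames(apply(cpm < cpm_low_threshold, 1, all), rownames(cpm))
}

#' Log2 transform and per-gene mean-centring
#'
#' `v = log2(CPM + pseudocount)` with each gene's row mean subtracted, the
#' standard heatmap preprocessing: every row averages to zero so colours
#' show relative, not absolute, expression.
#'
#' @param cpm A CPM matrix.
#' @param pseudocount Added before the log (default 1, keeping zeros at 0).
#' @return The centred log2 matrix.
#' @export
log2_center <- function(cpm, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  v <- log2(cpm + pseudocount)
  v - rowMeans(v)
}

#' Average CPM within tissues
#'
#' Arithmetic mean of CPM across the samples sharing a tissue label,
#' applied before [log2_center()] when a per-tissue heatmap is wanted.
#'
#' @param cpm A CPM matrix (columns = samples).
#' @param sample_meta Tibble with `sample_id`, `tissue_label` covering the
#'   columns.
#' @param allowed_tissues Controlled vocabulary (default [flax_tissues()]).
#' @return A genes x tissues matrix, columns in first-appearance order.
#' @export
tissue_aggregate <- function(cpm, sample_meta,
                             allowed_tissues = flax_tissues()) {
  meta <- sample_meta[match(colnames(cpm), sample_meta$sample_id), ]
  if (anyNA(meta$sample_id))
    abort(paste0("samples without metadata: ",
                 paste(setdiff(colnames(cpm), sample_meta$sample_id),
                       collapse = ", ")))
  bad <- setdiff(unique(meta$tissue_label), allowed_tissues)
  if (length(bad) > 0)
    abort(paste0("unknown tissue label(s): ", paste(bad, collapse = ", ")))
  tissues <- unique(meta$tissue_label)
  out <- sapply(tissues, function(t)
    rowMeans(cpm[, meta$tissue_label == t, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(cpm), tissues))
  out
}

#' Ward clustering of a heatmap matrix
#'
#' Euclidean distance plus Ward (ward.D2) trees over genes (rows), samples
#' (columns), or both, with the matrix reordered to the trees' leaf orders
#' for rendering.
#'
#' @param m A numeric matrix (typically [log2_center()] output).
#' @param axis `"genes"`, `"samples"` or `"both"`.
#' @return A list: `row_tree`, `col_tree` (either may be `NULL`) and
#'   `matrix`, leaf-ordered.
#' @export
cluster_heatmap <- function(m, axis = c("both", "genes", "samples")) {
  axis <- match.arg(axis)
  row_tree <- col_tree <- NULL
  if (axis %in% c("genes", "both")) {
    if (nrow(m) < 2) abort("need at least 2 rows to cluster genes")
    row_tree <- ward_cluster(dist(m))
    m <- m[row_tree$order, , drop = FALSE]
  }
  if (axis %in% c("samples", "both")) {
    if (ncol(m) < 2) abort("need at least 2 columns to cluster samples")
    col_tree <- ward_cluster(dist(t(m)))
    m <- m[, col_tree$order, drop = FALSE]
  }
  list(row_tree = row_tree, col_tree = col_tree, matrix = m)
}
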