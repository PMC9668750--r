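# Quality-control filters. Inequalities are strict on the removal side:
# cells are removed when they express *less than* `min_genes` genes or *more
# than* `max_mito` mitochondrial fraction, so boundary values are retained.

#' Compute per-observation QC metrics from counts
#'
#' @param counts Genes x barcodes count matrix.
#' @param mito_prefix Gene-ID prefix identifying mitochondrial genes
#'   (case-insensitive; default `"mt-"`).
#' @return data.frame with `barcode`, `n_genes_detected`, `n_umis`,
#'   `mito_fraction`.
#' @export
compute_qc_metrics <- function(counts, mito_prefix = "mt-") {
  counts <- as_count_matrix(counts)
  n_umis <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- grepl(paste0("^", mito_prefix), rownames(counts), ignore.case = TRUE)
  mito_umis <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE])
               else rep(0, ncol(counts))
  data.frame(barcode = colnames(counts),
             n_genes_detected = as.integer(n_genes),
             n_umis = as.integer(n_umis),
             mito_fraction = ifelse(n_umis > 0, mito_umis / n_umis, 0),
             stringsAsFactors = FALSE)
}

#' Filter low-quality cells
#'
#' Removes cells expressing less than `min_genes` genes or with more than
#' `max_mito` mitochondrial fraction (strict inequalities: a cell with
#' exactly `min_genes` genes and exactly `max_mito` mitochondrial reads is
#' retained). The gene set is unchanged.
#'
#' @param counts Genes x barcodes count matrix.
#' @param meta Optional per-observation metadata covering all barcodes; if it
#'   has `n_genes_detected` / `mito_fraction` columns these are used,
#'   otherwise they are computed from `counts`.
#' @param min_genes Minimum genes detected (default 200).
#' @param max_mito Maximum mitochondrial fraction (default 0.05).
#' @param mito_prefix Passed to [compute_qc_metrics()] when computing.
#' @return list with filtered `counts` and `meta`.
#' @export
qc_filter_cells <- function(counts, meta = NULL, min_genes = 200,
                            max_mito = 0.05, mito_prefix = "mt-") {
  counts <- as_count_matrix(counts)
  if (is.null(meta)) {
    meta <- compute_qc_metrics(counts, mito_prefix)
  } else {
    if (!all(colnames(counts) %in% meta$barcode))
      stop("meta does not cover all barcodes in counts")
    meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
    qcm <- compute_qc_metrics(counts, mito_prefix)
    if (is.null(meta$n_genes_detected))
      meta$n_genes_detected <- qcm$n_genes_detected
    if (is.null(meta$mito_fraction)) meta$mito_fraction <- qcm$mito_fraction
  }
  keep <- meta$n_genes_detected >= min_genes & meta$mito_fraction <= max_mito
  if (!any(keep)) warning("no cells pass QC filters")
  list(counts = counts[, keep, drop = FALSE],
       meta = meta[keep, , drop = FALSE])
}

#' Filter rarely expressed genes
#'
#' Removes genes expressed (non-zero) in less than `min_observations`
#' columns; a gene seen in exactly `min_observations` cells is retained.
#'
#' @param counts Genes x barcodes count matrix.
#' @param min_observations Minimum expressing columns (default 3).
#' @return Filtered count matrix.
#' @export
qc_filter_genes <- function(counts, min_observations = 3) {
  counts <- as_count_matrix(counts)
  keep <- Matrix::rowSums(counts > 0) >= min_observations
  counts[keep, , drop = FALSE]
}

#' Filter shallow spatial barcodes
#'
#' Removes barcodes with less than `min_umis` total UMIs (a barcode at
#' exactly `min_umis` is retained).
#'
#' @param counts Genes x barcodes count matrix.
#' @param min_umis Minimum total UMIs per barcode (default 5000).
#' @return Filtered count matrix.
#' @export
qc_filter_spatial_barcodes <- function(counts, min_umis = 5000) {
  counts <- as_count_matrix(counts)
  keep <- Matrix::colSums(counts) >= min_umis
  counts[, keep, drop = FALSE]
}
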