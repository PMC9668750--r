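# Fixtures are built in code at test time; nothing binary ships with the
# package.

# small genes x barcodes count matrix with controllable QC structure
toy_counts <- function(n_genes = 6, n_barcodes = 4, seed = 1,
                       gene_ids = sprintf("gene%d", seq_len(n_genes)),
                       barcodes = sprintf("cell%d", seq_len(n_barcodes))) {
  withr::local_seed(seed)
  m <- matrix(rpois(n_genes * n_barcodes, 3), n_genes, n_barcodes,
              dimnames = list(gene_ids, barcodes))
  m
}

# write a Matrix Market triplet by hand (independent of Matrix::writeMM)
write_mtx_fixture <- function(dir, n_genes, n_barcodes, entries,
                              genes = sprintf("g%d", seq_len(n_genes)),
                              barcodes = sprintf("b%d", seq_len(n_barcodes))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(n_genes, n_barcodes, nrow(entries)))
  if (nrow(entries))
    lines <- c(lines, apply(entries, 1, paste, collapse = " "))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}

# independent Mann-Whitney AUC oracle (base-R ranks, midrank ties)
auc_oracle <- function(scores, labels) {
  labels <- as.integer(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exhaustive per-condition nearest-neighbour oracle
knn_oracle <- function(center, coords, conditions, k) {
  i <- match(center, coords$barcode)
  out <- lapply(sort(unique(conditions)), function(cc) {
    sub <- coords[conditions == cc, , drop = FALSE]
    d <- sqrt((sub$x - coords$x[i])^2 + (sub$y - coords$y[i])^2)
    sub <- sub[order(d, sub$barcode), , drop = FALSE]
    sub$barcode[seq_len(k)]
  })
  names(out) <- sort(unique(conditions))
  out
}

# a pattern field with intensity 1 everywhere (full-strength DE)
full_pattern <- function() {
  structure(list(name = "full",
                 intensity = function(x, y) rep(1, length(x))),
            class = "pattern_field")
}

# small labelled multi-cell-type expression set: `de_type` gets full-strength
# DE between conditions, the others are null
toy_celltype_data <- function(n_types = 3, cells_per_cond = 40,
                              n_genes = 500, de_type = 1,
                              de_fac_loc = 1.5, seed = 1) {
  feats <- list(); metas <- list()
  for (t in seq_len(n_types)) {
    p <- splat_params(n_genes = n_genes, n_barcodes = 2 * cells_per_cond,
                      de_prob = if (t == de_type) 0.1 else 0,
                      de_fac_loc = de_fac_loc,
                      seed = derive_seed(seed, paste0("type", t)))
    ds <- simulate_spatial_pattern(full_pattern(), p)
    bc <- paste0("t", t, "_", ds$coords$barcode)
    colnames(ds$counts) <- bc
    feats[[t]] <- normalize_log1p_cpm(ds$counts)
    metas[[t]] <- data.frame(barcode = bc,
                             condition = unname(ds$conditions),
                             cell_type = paste0("type", t),
                             stringsAsFactors = FALSE)
  }
  list(features = do.call(rbind, feats), meta = do.call(rbind, metas))
}
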