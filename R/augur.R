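# Cell-type prioritization.
#
# Per cell type, the separability of two conditions is measured as the AUC of
# a random forest predicting the condition from expression, evaluated in
# stratified cross-validation on repeated fixed-size balanced subsamples.
# Fixed-size subsampling is what makes AUCs comparable between abundant and
# rare cell types: every subsample presents the classifier with the same
# amount of evidence.

#' Parameters for cell-type prioritization
#'
#' @param n_subsamples Balanced subsamples drawn per cell type (default 50).
#' @param subsample_size Cells drawn per condition per subsample (default 20).
#' @param n_folds CV folds (default 3).
#' @param n_trees Trees per forest (default 100).
#' @param var_quantile Fraction of variable features kept per subsample
#'   (default 0.5).
#' @param min_cells_per_condition Minimum cells a condition must have for a
#'   cell type to be scored (default `subsample_size`).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param min_node_size Minimal node size to attempt a split (default 10).
#' @param rng_seed Base seed; per-(cell type, subsample) streams are derived
#'   from it by stable hashing, so scoring is independent of processing
#'   order.
#' @return An `augur_params` list.
#' @export
augur_params <- function(n_subsamples = 50, subsample_size = 20, n_folds = 3,
                         n_trees = 100, var_quantile = 0.5,
                         min_cells_per_condition = subsample_size,
                         mtry = NULL, min_node_size = 10, rng_seed = 1) {
  stopifnot(n_folds >= 2, subsample_size >= n_folds,
            var_quantile > 0, var_quantile <= 1, n_subsamples >= 1)
  structure(list(n_subsamples = as.integer(n_subsamples),
                 subsample_size = as.integer(subsample_size),
                 n_folds = as.integer(n_folds),
                 n_trees = as.integer(n_trees),
                 var_quantile = var_quantile,
                 min_cells_per_condition = as.integer(min_cells_per_condition),
                 mtry = mtry, min_node_size = as.integer(min_node_size),
                 rng_seed = rng_seed),
            class = "augur_params")
}

#' Draw a balanced subsample of barcodes
#'
#' Samples exactly `size` barcodes per condition without replacement. If
#' either condition has fewer than `size` barcodes, returns `NULL` (the skip
#' signal; callers record the unit as skipped).
#'
#' @param barcodes Character vector of barcodes.
#' @param conditions Condition label per barcode (two levels).
#' @param size Barcodes per condition.
#' @param seed Seed for the draw.
#' @return Character vector of `2 * size` barcodes, or `NULL`.
#' @export
subsample_balanced <- function(barcodes, conditions, size, seed = 1) {
  stopifnot(length(barcodes) == length(conditions))
  lv <- unique(as.character(conditions))
  if (length(lv) != 2) stop("exactly two conditions required")
  by_cond <- split(as.character(barcodes), as.character(conditions))
  if (any(vapply(by_cond, length, integer(1)) < size)) return(NULL)
  with_seed(seed, {
    unlist(lapply(lv, function(cc) sample(by_cond[[cc]], size)),
           use.names = FALSE)
  })
}

#' Prioritize cell types by condition separability
#'
#' For each cell type, repeats `n_subsamples` times: draw a balanced
#' subsample, select variable features within it, and score a random forest
#' in stratified cross-validation. The per-subsample AUCs are averaged into
#' the cell type's score. Cell types with fewer than
#' `min_cells_per_condition` cells in either condition are marked skipped,
#' not silently dropped.
#'
#' @param features Observations x features matrix (log-normalized counts, or
#'   an RNA-velocity matrix via [feature_matrix()]; any finite numeric matrix
#'   is accepted). Rownames are barcodes.
#' @param meta data.frame with columns `barcode`, `condition`, `cell_type`.
#' @param comparison Character vector of the two condition labels to compare.
#' @param params An [augur_params()] object.
#' @return A `celltype_prioritization` object: `$scores` (one row per cell
#'   type), `$auc_samples` (named list of per-subsample AUC vectors),
#'   `$params`, `$comparison`.
#' @export
prioritize_cell_types <- function(features, meta,
                                  comparison, params = augur_params()) {
  stopifnot(is.data.frame(meta),
            all(c("barcode", "condition", "cell_type") %in% names(meta)))
  if (length(comparison) != 2) stop("comparison must name two conditions")
  present <- unique(as.character(meta$condition))
  absent <- setdiff(comparison, present)
  if (length(absent))
    stop("condition(s) not present in meta: ", paste(absent, collapse = ", "))
  meta <- meta[as.character(meta$condition) %in% comparison &
               !is.na(meta$cell_type), , drop = FALSE]
  if (!all(meta$barcode %in% rownames(features)))
    stop("features lack rows for some barcodes in meta")

  cell_types <- sort(unique(as.character(meta$cell_type)))
  samples <- list()
  rows <- lapply(cell_types, function(ct) {
    sub <- meta[meta$cell_type == ct, , drop = FALSE]
    n_by <- table(factor(as.character(sub$condition), levels = comparison))
    if (min(n_by) < params$min_cells_per_condition) {
      samples[[ct]] <<- numeric(0)
      return(data.frame(cell_type = ct, mean_auc = NA_real_, sd_auc = NA_real_,
                        n_repeats = 0L, n_cells_a = as.integer(n_by[1]),
                        n_cells_b = as.integer(n_by[2]), skipped = TRUE,
                        reason = "insufficient cells",
                        stringsAsFactors = FALSE))
    }
    aucs <- vapply(seq_len(params$n_subsamples), function(s) {
      sub_seed <- derive_seed(params$rng_seed, paste0(ct, "|sub|", s))
      bc <- subsample_balanced(sub$barcode, sub$condition,
                               params$subsample_size, sub_seed)
      X <- dense_block(features, bc)
      y <- as.integer(as.character(sub$condition[match(bc, sub$barcode)]) ==
                      comparison[2])
      sel <- tryCatch(select_variable_genes(X, params$var_quantile),
                      error = function(e) colnames(X))
      rf_cv_auc(X[, sel, drop = FALSE], y,
                n_folds = params$n_folds, n_trees = params$n_trees,
                mtry = params$mtry, min_node_size = params$min_node_size,
                seed = derive_seed(params$rng_seed, paste0(ct, "|rf|", s)))
    }, numeric(1))
    samples[[ct]] <<- aucs
    data.frame(cell_type = ct, mean_auc = mean(aucs), sd_auc = sd(aucs),
               n_repeats = length(aucs), n_cells_a = as.integer(n_by[1]),
               n_cells_b = as.integer(n_by[2]), skipped = FALSE, reason = "",
               stringsAsFactors = FALSE)
  })
  structure(list(scores = do.call(rbind, rows),
                 auc_samples = samples,
                 params = params,
                 comparison = comparison),
            class = "celltype_prioritization")
}

#' @export
print.celltype_prioritization <- function(x, ...) {
  cat("Cell type prioritization:", x$comparison[1], "vs", x$comparison[2],
      "\n")
  df <- x$scores[order(-x$scores$mean_auc), ]
  print(df[, c("cell_type", "mean_auc", "n_repeats", "skipped")],
        row.names = FALSE)
  invisible(x)
}

#' Min-max scale AUCs within each comparison
#'
#' For heat-map display across comparisons: within each comparison, mean
#' AUCs across cell types are scaled to \[0, 1\]. If all AUCs in a comparison
#' are equal the scaled values are all 0.
#'
#' @param scores A named list of `celltype_prioritization` objects (one per
#'   comparison), or a data.frame with columns `comparison`, `cell_type`,
#'   `mean_auc`.
#' @return Matrix of scaled AUCs, cell types x comparisons (NA where a cell
#'   type was skipped or absent).
#' @export
scale_scores <- function(scores) {
  if (inherits(scores, "celltype_prioritization")) scores <- list(scores)
  if (is.data.frame(scores)) {
    stopifnot(all(c("comparison", "cell_type", "mean_auc") %in%
                  names(scores)))
    long <- scores
  } else {
    if (is.null(names(scores)))
      names(scores) <- vapply(scores, function(s)
        paste(s$comparison, collapse = " vs "), character(1))
    long <- do.call(rbind, lapply(names(scores), function(nm) {
      df <- scores[[nm]]$scores
      data.frame(comparison = nm, cell_type = df$cell_type,
                 mean_auc = df$mean_auc, stringsAsFactors = FALSE)
    }))
  }
  cts <- sort(unique(long$cell_type))
  cmps <- unique(long$comparison)
  out <- matrix(NA_real_, length(cts), length(cmps),
                dimnames = list(cts, cmps))
  for (cmp in cmps) {
    sub <- long[long$comparison == cmp, ]
    v <- sub$mean_auc
    rng <- range(v, na.rm = TRUE)
    scaled <- if (!all(is.finite(rng)) || rng[1] == rng[2])
      rep(0, length(v)) else (v - rng[1]) / (rng[2] - rng[1])
    scaled[is.na(v)] <- NA_real_
    out[sub$cell_type, cmp] <- scaled
  }
  out
}
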