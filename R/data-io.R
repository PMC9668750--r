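# Readers and writers for the standard on-disk formats: Matrix Market count
# triplets (matrix.mtx + features.tsv + barcodes.tsv, as emitted by Cell
# Ranger / Space Ranger), dense TSV counts, spatial positions tables, and the
# scores TSV produced by the prioritization functions.

read_id_column <- function(path) {
  tab <- tryCatch(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE, sep = "\t"),
    error = function(e) stop("failed to read '", path, "': ",
                             conditionMessage(e)))
  as.character(tab[[1]])
}

#' Read a Matrix Market count triplet
#'
#' Reads `matrix.mtx` (1-based coordinate format) together with the
#' features/genes and barcodes TSVs, preserving file ordering. Gene IDs are
#' taken from the first column of the features file.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path Path to the features/genes TSV (first column = ID).
#' @param barcodes_path Path to the barcodes TSV (one barcode per line).
#' @return A sparse genes x barcodes count matrix (see [as_count_matrix()]).
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: '", p, "'")
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("malformed Matrix Market file '",
                                         matrix_path, "': ",
                                         conditionMessage(e)))
  genes <- read_id_column(features_path)
  barcodes <- read_id_column(barcodes_path)
  if (nrow(m) != length(genes))
    stop("dimension mismatch: '", matrix_path, "' declares ", nrow(m),
         " rows but '", features_path, "' has ", length(genes), " features")
  if (ncol(m) != length(barcodes))
    stop("dimension mismatch: '", matrix_path, "' declares ", ncol(m),
         " columns but '", barcodes_path, "' has ", length(barcodes),
         " barcodes")
  if (length(m@x) && any(m@x != round(m@x)))
    stop("non-integer entries in '", matrix_path, "'")
  dimnames(m) <- list(genes, barcodes)
  as_count_matrix(m)
}

#' Write a count matrix as a Matrix Market triplet
#'
#' @param counts Genes x barcodes count matrix.
#' @param dir Output directory (created if needed). Writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_mtx_triplet <- function(counts, dir) {
  counts <- as_count_matrix(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense TSV count matrix
#'
#' Fallback format: first column gene IDs, remaining columns one barcode each
#' (header row holds barcodes).
#'
#' @param path Path to the TSV.
#' @return A sparse genes x barcodes count matrix.
#' @export
read_dense_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  as_count_matrix(m)
}

#' Read a spatial positions table
#'
#' Expects a TSV or CSV with header columns `barcode`, `x`, `y`, `section`,
#' `condition` (extra columns are kept). Visium `tissue_positions` tables can
#' be converted by renaming `barcode`/`pxl_col_in_fullres`/
#' `pxl_row_in_fullres` to `barcode`/`x`/`y` and adding `section` and
#' `condition` columns.
#'
#' @param path Path to the table; comma- vs tab-separation is sniffed from
#'   the header line.
#' @param counts Optional count matrix; positions for barcodes absent from it
#'   are reported and dropped.
#' @return A data.frame with one row per barcode.
#' @export
read_spatial_positions <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header, fixed = TRUE) &&
             !grepl("\t", header, fixed = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("barcode", "x", "y", "section", "condition")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("positions table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$barcode <- as.character(tab$barcode)
  if (anyDuplicated(tab$barcode))
    stop("duplicate barcode(s) in positions table: ",
         paste(unique(tab$barcode[duplicated(tab$barcode)]), collapse = ", "))
  if (any(!is.finite(tab$x)) || any(!is.finite(tab$y)))
    stop("missing or non-finite coordinate(s) in positions table")
  if (!is.null(counts)) {
    absent <- setdiff(tab$barcode, colnames(counts))
    if (length(absent)) {
      warning(length(absent),
              " barcode(s) in positions table absent from counts; dropped")
      tab <- tab[!tab$barcode %in% absent, , drop = FALSE]
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Write a prioritization scores table
#'
#' Tab-separated, one row per unit (cell type or barcode), columns `unit_id`,
#' `mean_auc`, `n_repeats`, `sd_auc` plus any extra columns present. Values
#' round-trip losslessly at 6 decimals through [read_scores_table()].
#'
#' @param scores A `celltype_prioritization` or `spatial_prioritization`
#'   object, or a data.frame with at least `unit_id` and `mean_auc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_table <- function(scores, path) {
  df <- scores_as_table(scores)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 6))
  status <- tryCatch({
    tmp <- paste0(path, ".tmp")
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, path)
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)),
     warning = function(w) stop("cannot write '", path, "': ",
                                conditionMessage(w)))
  if (!isTRUE(status)) stop("cannot write '", path, "'")
  invisible(path)
}

#' @rdname write_scores_table
#' @export
read_scores_table <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  read.delim(path, stringsAsFactors = FALSE)
}

# normalize the various score containers to the on-disk table layout
scores_as_table <- function(scores) {
  if (inherits(scores, "celltype_prioritization")) {
    df <- scores$scores
    out <- data.frame(unit_id = df$cell_type, mean_auc = df$mean_auc,
                      n_repeats = df$n_repeats, sd_auc = df$sd_auc,
                      skipped = df$skipped, reason = df$reason,
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (inherits(scores, "spatial_prioritization")) {
    df <- scores$scores
    out <- data.frame(unit_id = df$barcode, mean_auc = df$mean_auc,
                      n_repeats = df$n_repeats, sd_auc = df$sd_auc,
                      x = df$x, y = df$y,
                      skipped = df$skipped, reason = df$reason,
                      stringsAsFactors = FALSE)
    return(out)
  }
  df <- as.data.frame(scores)
  if (!all(c("unit_id", "mean_auc") %in% names(df)))
    stop("scores table needs at least columns unit_id and mean_auc")
  if (is.null(df$n_repeats)) df$n_repeats <- NA_integer_
  if (is.null(df$sd_auc)) df$sd_auc <- NA_real_
  df
}
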