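# Core containers.
#
# A count matrix is a genes x observations matrix (base or Matrix sparse)
# with unique rownames (gene IDs) and colnames (barcodes), non-negative and
# integral. A feature matrix is observations x features, finite real, with a
# "kind" attribute recording what the values are (log-normalized counts, an
# RNA-velocity matrix passed through untouched, or raw values).

#' Validate and canonicalize a count matrix
#'
#' Checks that `x` is a genes x observations matrix of non-negative integral
#' values with identifiers, and returns it as a sparse `dgCMatrix`. Duplicate
#' gene IDs are made unique by suffixing (with a warning); duplicate barcodes
#' are an error, since every downstream structure keys on them.
#'
#' @param x Matrix-like, genes in rows, observations (cells/barcodes) in
#'   columns, with dimnames.
#' @return A `dgCMatrix` with unique dimnames.
#' @export
as_count_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count matrix must carry gene IDs (rownames) and barcodes (colnames)")
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  m <- as(as(x, "CsparseMatrix"), "generalMatrix")
  if (!is(m, "dsparseMatrix")) m <- as(m, "dMatrix")
  v <- m@x
  if (any(!is.finite(v)))
    stop("count matrix contains non-finite entries")
  if (any(v < 0))
    stop("count matrix contains negative entries")
  if (any(v != round(v)))
    stop("count matrix contains non-integer entries")
  if (anyDuplicated(colnames(m)))
    stop("duplicate barcodes in count matrix")
  if (anyDuplicated(rownames(m))) {
    warning("duplicate gene IDs made unique by suffixing")
    rownames(m) <- make.unique(rownames(m))
  }
  m
}

#' Construct a feature matrix
#'
#' An observations x features real matrix, the input expected by the
#' prioritization functions. `kind` records provenance: `"velocity"` matrices
#' bypass normalization by design, `"log_normalized_counts"` is what
#' [normalize_log1p_cpm()] produces.
#'
#' @param values Numeric matrix, observations in rows, features in columns,
#'   with dimnames.
#' @param kind One of `"log_normalized_counts"`, `"velocity"`, `"raw"`.
#' @return `values` with class `feature_matrix` semantics (a plain matrix with
#'   attributes `kind`).
#' @export
feature_matrix <- function(values,
                           kind = c("raw", "log_normalized_counts",
                                    "velocity")) {
  kind <- match.arg(kind)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature matrix must carry barcodes (rownames) and feature IDs (colnames)")
  dense <- if (inherits(values, "Matrix")) values else as.matrix(values)
  vals <- if (inherits(dense, "Matrix")) dense@x else dense
  if (any(!is.finite(vals)))
    stop("feature matrix contains non-finite entries")
  attr(dense, "kind") <- kind
  dense
}

feature_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) "raw" else k
}

# densify an observations x features block (rows = barcodes)
dense_block <- function(features, rows) {
  as.matrix(features[rows, , drop = FALSE])
}
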