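#' Counts-per-10k log normalization
#'
#' Transforms raw counts to `log(1 + scale_factor * count / column_sum)` and
#' transposes to the observations x features orientation used by the
#' classifiers. Velocity matrices should bypass this and go through
#' [feature_matrix()] with `kind = "velocity"` instead.
#'
#' @param counts Genes x barcodes count matrix.
#' @param scale_factor Library-size target (default `1e4`).
#' @return A sparse observations x features matrix with attribute
#'   `kind = "log_normalized_counts"`.
#' @export
normalize_log1p_cpm <- function(counts, scale_factor = 1e4) {
  counts <- as_count_matrix(counts)
  csums <- Matrix::colSums(counts)
  if (any(csums == 0))
    stop("zero-sum column(s): ",
         paste(colnames(counts)[csums == 0], collapse = ", "))
  scaled <- counts %*% Matrix::Diagonal(x = scale_factor / csums)
  out <- Matrix::t(scaled)
  out@x <- log1p(out@x)
  dimnames(out) <- list(colnames(counts), rownames(counts))
  attr(out, "kind") <- "log_normalized_counts"
  out
}

#' Mirror coordinates onto one side of the x axis
#'
#' Replaces each barcode's x coordinate by its absolute value, pooling the
#' two sides of a bilaterally symmetric tissue to mitigate registration
#' artefacts. y and section are unchanged.
#'
#' @param coords data.frame with columns `barcode`, `x`, `y` (and optionally
#'   `section`).
#' @return The same data.frame with `x = abs(x)`.
#' @export
mirror_x <- function(coords) {
  stopifnot(is.data.frame(coords), all(c("barcode", "x", "y") %in%
                                       names(coords)))
  coords$x <- abs(coords$x)
  coords
}
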