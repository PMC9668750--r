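#' Select highly variable features
#'
#' Ranks features by the residual of a locally weighted regression of
#' log(variance) on log(mean) — i.e. by how much more variable a feature is
#' than others of comparable abundance — and returns the top `var_quantile`
#' fraction. Zero-variance features are never selected when
#' `var_quantile < 1` (nor when it is 1: a constant feature carries no
#' signal).
#'
#' @param features Observations x features matrix (dense or sparse) with
#'   feature IDs as colnames.
#' @param var_quantile Fraction of positive-variance features to keep, in
#'   (0, 1] (default 0.5).
#' @return Character vector of selected feature IDs, ordered by decreasing
#'   residual.
#' @export
select_variable_genes <- function(features, var_quantile = 0.5) {
  stopifnot(var_quantile > 0, var_quantile <= 1)
  if (ncol(features) < 2) stop("need at least 2 features")
  ids <- colnames(features)
  if (is.null(ids)) stop("features must have column names")
  n <- nrow(features)
  mu <- Matrix::colMeans(features)
  ex2 <- Matrix::colSums(features^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  v <- pmax(v, 0)  # guard tiny negative from cancellation
  pos <- which(v > 1e-12 & mu > 0)
  if (!length(pos)) stop("all features have zero variance")
  n_sel <- max(1L, ceiling(var_quantile * length(pos)))
  if (length(pos) == 1L) return(ids[pos])

  lx <- log(mu[pos])
  ly <- log(v[pos])
  if (length(pos) >= 5) {
    fit <- lowess(lx, ly, f = 2/3, iter = 3)
    trend <- approx(fit$x, fit$y, xout = lx, rule = 2, ties = mean)$y
  } else {
    # too few points for a local fit: detrend linearly
    trend <- tryCatch(fitted(stats::lm(ly ~ lx)), error = function(e) mean(ly))
  }
  resid <- ly - trend
  ord <- order(-resid, ids[pos])
  ids[pos][ord][seq_len(n_sel)]
}
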