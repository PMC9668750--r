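# Smoothing, evaluation and cross-method concordance of prioritization maps.

#' Two-dimensional locally weighted smoothing
#'
#' At each point of a regular grid over the bounding box, fits a local linear
#' regression to the `span` fraction of nearest data points with tricube
#' distance weights, the standard loess recipe. Degenerate windows (fewer
#' than 3 points, or collinear) are widened with a warning; if widening to
#' all points still fails, the tricube-weighted mean is used. Predictions
#' are clamped to the observed value range so the smoothed field never
#' exceeds the data.
#'
#' @param coords data.frame with `x`, `y` (and optionally `barcode`).
#' @param values Numeric vector, one per row of `coords`.
#' @param span Fraction of points in each local window, in (0, 1\]
#'   (default 0.3).
#' @param grid_resolution Grid points per axis (default 50).
#' @return A `smoothed_field`: `$grid` (data.frame x, y, value), `$span`,
#'   `$grid_resolution`.
#' @export
loess_smooth_2d <- function(coords, values, span = 0.3,
                            grid_resolution = 50) {
  stopifnot(span > 0, span <= 1, nrow(coords) == length(values))
  ok <- is.finite(values) & is.finite(coords$x) & is.finite(coords$y)
  x <- coords$x[ok]; y <- coords$y[ok]; v <- values[ok]
  n <- length(v)
  if (n < 10) stop("need at least 10 points to smooth")
  q <- max(3L, ceiling(span * n))
  if (q > n) q <- n
  gx <- seq(min(x), max(x), length.out = grid_resolution)
  gy <- seq(min(y), max(y), length.out = grid_resolution)
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  vr <- range(v)
  widened <- FALSE

  fit_one <- function(px, py, q_use) {
    d <- sqrt((x - px)^2 + (y - py)^2)
    dq <- sort(d, partial = q_use)[q_use]
    w <- pmax(0, 1 - (d / max(dq, .Machine$double.eps))^3)^3
    use <- w > 0
    if (sum(use) < 3) return(NA_real_)
    X <- cbind(1, x[use] - px, y[use] - py)
    W <- w[use]
    XtWX <- crossprod(X, X * W)
    if (abs(det(XtWX)) < 1e-12) return(NA_real_)
    beta <- solve(XtWX, crossprod(X, W * v[use]))
    beta[1]
  }

  vals <- vapply(seq_len(nrow(grid)), function(i) {
    est <- fit_one(grid$x[i], grid$y[i], q)
    if (is.na(est)) {
      widened <<- TRUE
      est <- fit_one(grid$x[i], grid$y[i], n)
      if (is.na(est)) {
        # fully degenerate geometry: tricube-weighted mean
        d <- sqrt((x - grid$x[i])^2 + (y - grid$y[i])^2)
        w <- pmax(0, 1 - (d / max(max(d), .Machine$double.eps))^3)^3 + 1e-12
        est <- sum(w * v) / sum(w)
      }
    }
    est
  }, numeric(1))
  if (widened)
    warning("degenerate local window(s) widened to all points")
  grid$value <- pmin(pmax(vals, vr[1]), vr[2])
  structure(list(grid = grid, span = span,
                 grid_resolution = as.integer(grid_resolution)),
            class = "smoothed_field")
}

#' Concordance between two sets of scores
#'
#' Correlates per-unit scores (e.g. cell-type AUCs placed at coordinates)
#' with per-location scores (e.g. a spatial AUC map) after matching each row
#' of `scores_a` to a row of `scores_b` — by shared barcode when both have a
#' `barcode` column, otherwise by nearest coordinate. When `scores_a` has a
#' `group` column, per-group means of the matched `scores_b` values are also
#' returned.
#'
#' @param scores_a data.frame with `value` plus `barcode` or `x`,`y`
#'   (optionally `group`).
#' @param scores_b data.frame with `value` plus `barcode` or `x`,`y`.
#' @param match `"barcode"` or `"nearest"` (default: barcode if available).
#' @return List with `pearson`, `spearman`, `n_pairs`, `pairs` (matched
#'   data.frame) and `group_means` (or NULL).
#' @export
concordance <- function(scores_a, scores_b,
                        match = if (!is.null(scores_a$barcode) &&
                                    !is.null(scores_b$barcode)) "barcode"
                                else "nearest") {
  match <- match.arg(match, c("barcode", "nearest"))
  stopifnot(!is.null(scores_a$value), !is.null(scores_b$value))
  if (match == "barcode") {
    idx <- base::match(scores_a$barcode, scores_b$barcode)
  } else {
    stopifnot(all(c("x", "y") %in% names(scores_a)),
              all(c("x", "y") %in% names(scores_b)))
    idx <- vapply(seq_len(nrow(scores_a)), function(i) {
      which.min((scores_b$x - scores_a$x[i])^2 +
                (scores_b$y - scores_a$y[i])^2)
    }, integer(1))
  }
  keep <- !is.na(idx) & is.finite(scores_a$value) &
          is.finite(scores_b$value[idx])
  a <- scores_a$value[keep]; b <- scores_b$value[idx[keep]]
  if (length(a) < 3) stop("need at least 3 matched pairs")
  group_means <- NULL
  if (!is.null(scores_a$group)) {
    group_means <- tapply(b, scores_a$group[keep], mean)
    group_means <- data.frame(group = names(group_means),
                              mean_value_b = as.numeric(group_means),
                              stringsAsFactors = FALSE)
  }
  list(pearson = cor(a, b),
       spearman = cor(a, b, method = "spearman"),
       n_pairs = length(a),
       pairs = data.frame(value_a = a, value_b = b),
       group_means = group_means)
}

#' Evaluate recovery of a known perturbation field
#'
#' Compares a spatial AUC map with ground-truth perturbation intensity:
#' Spearman correlation of `mean_auc` with intensity, and the detection
#' AUROC of `mean_auc` for identifying barcodes with intensity above
#' `positive_threshold` (Mann-Whitney with 0.5 tie credit). `recovered`
#' requires both `spearman_truth >= spearman_min` and
#' `detection_auroc >= auroc_min`. With no positive (or no negative)
#' barcodes the AUROC is undefined and flagged; the grand-mean AUC is always
#' reported so null fields can be checked for absence of signal.
#'
#' @param auc_map A `spatial_prioritization` object or data.frame with
#'   `barcode` and `mean_auc` (skipped barcodes are excluded).
#' @param truth_intensity data.frame with `barcode` and `intensity`, or a
#'   named numeric vector.
#' @param positive_threshold Intensity above which a barcode counts as
#'   perturbed (default 0.5).
#' @param spearman_min,auroc_min Recovery thresholds (defaults 0.4, 0.8).
#' @return A `recovery_report` list: `spearman_truth`, `detection_auroc`,
#'   `auroc_defined`, `recovered`, `grand_mean_auc`, `n_scored`.
#' @export
recovery_score <- function(auc_map, truth_intensity,
                           positive_threshold = 0.5, spearman_min = 0.4,
                           auroc_min = 0.8) {
  df <- if (inherits(auc_map, "spatial_prioritization")) auc_map$scores
        else as.data.frame(auc_map)
  stopifnot(all(c("barcode", "mean_auc") %in% names(df)))
  if (!is.null(df$skipped)) df <- df[!df$skipped, , drop = FALSE]
  if (is.data.frame(truth_intensity)) {
    ti <- stats::setNames(truth_intensity$intensity,
                          truth_intensity$barcode)
  } else ti <- truth_intensity
  if (!all(df$barcode %in% names(ti)))
    stop("truth intensity missing for some scored barcodes")
  intensity <- unname(ti[df$barcode])

  pos <- intensity > positive_threshold
  auroc_defined <- any(pos) && any(!pos)
  auroc <- if (auroc_defined) mann_whitney_auc(df$mean_auc, pos) else NA_real_
  spear <- if (sd(intensity) > 0 && sd(df$mean_auc) > 0)
    cor(df$mean_auc, intensity, method = "spearman") else NA_real_
  recovered <- isTRUE(auroc_defined) && !is.na(spear) &&
    spear >= spearman_min && auroc >= auroc_min
  structure(list(spearman_truth = spear,
                 detection_auroc = auroc,
                 auroc_defined = auroc_defined,
                 recovered = recovered,
                 grand_mean_auc = mean(df$mean_auc),
                 n_scored = nrow(df),
                 positive_threshold = positive_threshold,
                 spearman_min = spearman_min, auroc_min = auroc_min),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report", if (!is.null(x$pattern)) paste0("(", x$pattern, ")"),
      "\n  spearman vs truth:", round(x$spearman_truth, 3),
      "\n  detection AUROC:",
      if (x$auroc_defined) round(x$detection_auroc, 3) else "undefined",
      "\n  grand-mean AUC:", round(x$grand_mean_auc, 3),
      "\n  recovered:", x$recovered, "\n")
  invisible(x)
}
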