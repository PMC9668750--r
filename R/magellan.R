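# Spatial prioritization.
#
# For each barcode, take its k nearest neighbours *from each condition* in
# the common coordinate system (2k barcodes in total), and score how well a
# random forest can tell the two conditions apart within that window, in
# repeated stratified cross-validation. Sliding the window over every barcode
# yields an AUC map: 0.5 where the conditions are locally indistinguishable,
# approaching 1 where the perturbation footprint is strong.

#' Parameters for spatial prioritization
#'
#' @param k Neighbours per condition (default 20, so windows hold 2k
#'   barcodes).
#' @param n_repeats Cross-validation repetitions per barcode (default 50);
#'   fold assignment is re-randomized each repeat and the repeat AUCs are all
#'   retained.
#' @param n_folds CV folds (default 3); each fold withholds `1/n_folds` of
#'   the window's labels.
#' @param n_trees Trees per forest (default 100).
#' @param var_quantile Fraction of variable features kept per window
#'   (default 0.5); feature selection is computed once per window on the
#'   pooled 2k barcodes, so repeats average only partition noise.
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param min_node_size Minimal node size to attempt a split (default 10).
#' @param rng_seed Base seed; per-barcode streams are derived by stable
#'   hashing, so maps are reproducible under barcode reordering.
#' @param distance Distance metric; only `"euclidean"` is implemented.
#' @return A `magellan_params` list.
#' @export
magellan_params <- function(k = 20, n_repeats = 50, n_folds = 3,
                            n_trees = 100, var_quantile = 0.5, mtry = NULL,
                            min_node_size = 10, rng_seed = 1,
                            distance = "euclidean") {
  stopifnot(k >= n_folds, n_repeats >= 1, n_folds >= 2,
            var_quantile > 0, var_quantile <= 1)
  distance <- match.arg(distance, "euclidean")
  structure(list(k = as.integer(k), n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds), n_trees = as.integer(n_trees),
                 var_quantile = var_quantile, mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 rng_seed = rng_seed, distance = distance),
            class = "magellan_params")
}

#' k nearest neighbours per condition
#'
#' For one centre barcode, returns the `k` barcodes of each condition closest
#' to it in Euclidean distance. The centre is eligible for its own
#' condition's set (it is a labelled observation like any other). Distance
#' ties are broken by lexicographic barcode ID for reproducibility.
#'
#' @param center Barcode ID of the centre.
#' @param coords data.frame with `barcode`, `x`, `y`.
#' @param conditions Condition label per coords row (two levels).
#' @param k Neighbours per condition.
#' @return Named list with one character vector of `k` barcodes per
#'   condition (ordered by distance), or `NULL` if either condition has
#'   fewer than `k` barcodes (the skip signal).
#' @export
knn_per_condition <- function(center, coords, conditions, k) {
  stopifnot(is.data.frame(coords), all(c("barcode", "x", "y") %in%
                                       names(coords)))
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == nrow(coords))
  i <- match(center, coords$barcode)
  if (is.na(i)) stop("centre barcode '", center, "' not in coords")
  lv <- sort(unique(conditions))
  if (length(lv) != 2) stop("exactly two conditions required")
  out <- lapply(lv, function(cc) {
    sel <- conditions == cc
    if (sum(sel) < k) return(NULL)
    bc <- coords$barcode[sel]
    d2 <- (coords$x[sel] - coords$x[i])^2 + (coords$y[sel] - coords$y[i])^2
    bc[order(d2, bc)[seq_len(k)]]
  })
  names(out) <- lv
  if (any(vapply(out, is.null, logical(1)))) return(NULL)
  out
}

# All-centres neighbour search: for each condition, an n_centres x k matrix
# of barcode IDs. Chunked so the distance block stays modest.
knn_all <- function(coords, conditions, k, centers) {
  lv <- sort(unique(conditions))
  ci <- match(centers, coords$barcode)
  res <- list()
  for (cc in lv) {
    sel <- which(conditions == cc)
    bc <- coords$barcode[sel]
    ord_bc <- order(bc)  # pre-order for stable tie-breaking
    sel <- sel[ord_bc]; bc <- bc[ord_bc]
    mx <- coords$x[sel]; my <- coords$y[sel]
    nn <- matrix(NA_character_, length(centers), k)
    chunk <- max(1L, as.integer(2e6 / max(1L, length(sel))))
    for (start in seq(1L, length(centers), by = chunk)) {
      idx <- start:min(start + chunk - 1L, length(centers))
      dx <- outer(coords$x[ci[idx]], mx, "-")
      dy <- outer(coords$y[ci[idx]], my, "-")
      d2 <- dx * dx + dy * dy
      for (r in seq_along(idx)) {
        # order() on (distance, position); positions are already in barcode
        # order, so ties resolve lexicographically
        nn[idx[r], ] <- bc[order(d2[r, ])[seq_len(k)]]
      }
    }
    res[[cc]] <- nn
  }
  res
}

#' AUC samples for one spatial window
#'
#' Scores a neighbourhood: selects variable features once on the pooled
#' window, then runs `n_repeats` independent rounds of stratified
#' `n_folds`-fold cross-validated random-forest AUC.
#'
#' @param features Observations x features matrix restricted to the window
#'   (2k rows).
#' @param labels Binary condition labels for the rows.
#' @param params A [magellan_params()] object.
#' @param seed Seed for this window.
#' @return Numeric vector of `n_repeats` AUCs.
#' @export
barcode_auc <- function(features, labels, params = magellan_params(),
                        seed = 1) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  sel <- tryCatch(select_variable_genes(X, params$var_quantile),
                  error = function(e) colnames(X))
  if (!is.null(sel)) X <- X[, sel, drop = FALSE]
  rf_cv_auc(X, labels, n_folds = params$n_folds, n_trees = params$n_trees,
            n_repeats = params$n_repeats, mtry = params$mtry,
            min_node_size = params$min_node_size, seed = seed)
}

#' Spatial prioritization map
#'
#' Runs the windowed separability score at every labelled barcode (or a
#' subset), returning a per-barcode AUC map. Barcodes whose window cannot be
#' formed are marked skipped with a reason, never silently dropped; if either
#' condition has fewer than `k` barcodes globally, every barcode is skipped
#' and a warning summarizes the failure.
#'
#' @param features Observations x features matrix (rownames = barcodes);
#'   typically [normalize_log1p_cpm()] output.
#' @param coords data.frame with `barcode`, `x`, `y` for every labelled
#'   barcode.
#' @param conditions Named vector (names = barcodes) of condition labels with
#'   exactly two levels, or a data.frame with `barcode` and `condition`.
#' @param params A [magellan_params()] object.
#' @param barcodes Optional subset of barcodes to score (windows still draw
#'   neighbours from all labelled barcodes).
#' @return A `spatial_prioritization` object: `$scores` (barcode, x, y,
#'   mean_auc, sd_auc, n_repeats, skipped, reason), `$auc_samples` (scored
#'   barcodes x n_repeats matrix), `$params`, `$conditions` (the two levels).
#' @export
prioritize_map <- function(features, coords, conditions,
                           params = magellan_params(), barcodes = NULL) {
  if (is.data.frame(conditions)) {
    stopifnot(all(c("barcode", "condition") %in% names(conditions)))
    cond <- stats::setNames(as.character(conditions$condition),
                            conditions$barcode)
  } else {
    if (is.null(names(conditions)))
      stop("conditions must be named by barcode (or be a data.frame)")
    cond <- stats::setNames(as.character(conditions), names(conditions))
  }
  lv <- sort(unique(cond))
  if (length(lv) != 2) stop("exactly two conditions required")

  labelled <- names(cond)
  if (!all(labelled %in% coords$barcode))
    stop("coordinates missing for ",
         sum(!labelled %in% coords$barcode), " labelled barcode(s)")
  if (!all(labelled %in% rownames(features)))
    stop("features missing for some labelled barcodes")
  coords <- coords[match(labelled, coords$barcode), , drop = FALSE]
  condv <- unname(cond)

  if (is.null(barcodes)) barcodes <- labelled
  stopifnot(all(barcodes %in% labelled))

  k <- params$k
  n_by <- table(factor(condv, levels = lv))
  global_short <- n_by < k

  empty_samples <- matrix(NA_real_, 0, params$n_repeats)
  if (any(global_short)) {
    warning("condition(s) with fewer than k = ", k, " barcodes: ",
            paste(lv[global_short], collapse = ", "),
            "; all barcodes skipped")
    scores <- data.frame(barcode = barcodes,
                         x = coords$x[match(barcodes, coords$barcode)],
                         y = coords$y[match(barcodes, coords$barcode)],
                         mean_auc = NA_real_, sd_auc = NA_real_,
                         n_repeats = 0L, skipped = TRUE,
                         reason = "insufficient barcodes in condition",
                         stringsAsFactors = FALSE)
    return(structure(list(scores = scores, auc_samples = empty_samples,
                          params = params, conditions = lv),
                     class = "spatial_prioritization"))
  }

  nn <- knn_all(coords, condv, k, barcodes)
  dense_all <- prod(dim(features)) <= 2e7
  if (dense_all) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
  }

  samples <- matrix(NA_real_, length(barcodes), params$n_repeats,
                    dimnames = list(barcodes, NULL))
  mean_auc <- sd_auc <- rep(NA_real_, length(barcodes))
  for (r in seq_along(barcodes)) {
    nb <- c(nn[[1]][r, ], nn[[2]][r, ])
    X <- if (dense_all) features[nb, , drop = FALSE]
         else dense_block(features, nb)
    y <- c(rep(0L, k), rep(1L, k))
    aucs <- barcode_auc(X, y, params,
                        seed = derive_seed(params$rng_seed,
                                           paste0("bc|", barcodes[r])))
    samples[r, ] <- aucs
    mean_auc[r] <- mean(aucs)
    sd_auc[r] <- sd(aucs)
  }

  scores <- data.frame(barcode = barcodes,
                       x = coords$x[match(barcodes, coords$barcode)],
                       y = coords$y[match(barcodes, coords$barcode)],
                       mean_auc = mean_auc, sd_auc = sd_auc,
                       n_repeats = params$n_repeats, skipped = FALSE,
                       reason = "", stringsAsFactors = FALSE)
  structure(list(scores = scores, auc_samples = samples, params = params,
                 conditions = lv),
            class = "spatial_prioritization")
}

#' @export
print.spatial_prioritization <- function(x, ...) {
  ok <- !x$scores$skipped
  cat("Spatial prioritization:", x$conditions[1], "vs", x$conditions[2],
      "\n", sum(ok), "barcodes scored,", sum(!ok), "skipped; k =",
      x$params$k, "\n")
  if (any(ok))
    cat("mean AUC:", round(mean(x$scores$mean_auc[ok]), 3), " range:",
        paste(round(range(x$scores$mean_auc[ok]), 3), collapse = " - "),
        "\n")
  invisible(x)
}

#' Split-half convergence diagnostic
#'
#' Splits each barcode's AUC samples into first and second halves and
#' correlates the half-means across barcodes: high correlation means the
#' number of repeats suffices for a stable per-barcode estimate (the
#' design check is 100 repeats, first 50 vs second 50).
#'
#' @param x A `spatial_prioritization` object, or a barcodes x repeats
#'   matrix of AUC samples.
#' @return List with `half_means` (data.frame: barcode, first_half,
#'   second_half), `correlation` (Pearson, across barcodes), and `degenerate`
#'   (TRUE when a half has zero variance so the correlation is undefined).
#' @export
convergence_diagnostic <- function(x) {
  m <- if (inherits(x, "spatial_prioritization")) x$auc_samples else as.matrix(x)
  n_rep <- ncol(m)
  if (n_rep < 2 || n_rep %% 2 != 0)
    stop("need an even number of repeats >= 2")
  keep <- rowSums(is.na(m)) == 0
  m <- m[keep, , drop = FALSE]
  h1 <- rowMeans(m[, seq_len(n_rep / 2), drop = FALSE])
  h2 <- rowMeans(m[, n_rep / 2 + seq_len(n_rep / 2), drop = FALSE])
  degenerate <- nrow(m) < 3 || sd(h1) == 0 || sd(h2) == 0
  list(half_means = data.frame(barcode = rownames(m), first_half = h1,
                               second_half = h2, stringsAsFactors = FALSE,
                               row.names = NULL),
       correlation = if (degenerate) NA_real_ else cor(h1, h2),
       degenerate = degenerate)
}
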