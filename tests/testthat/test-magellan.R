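test_that("knn_per_condition matches the hand-worked 1D example", {
  coords <- data.frame(
    barcode = c("center", paste0("a", 1:3), paste0("b", 1:3)),
    x = c(0, 1, 2, 3, 1.5, 2.5, 3.5),
    y = 0)
  cond <- c("A", "A", "A", "A", "B", "B", "B")
  nn <- knn_per_condition("center", coords, cond, k = 2)
  expect_equal(nn$A, c("center", "a1"))
  expect_equal(nn$B, c("b1", "b2"))

  # without the center in its own condition pool, the example's answer
  coords2 <- coords[-1, ]; cond2 <- cond[-1]
  coords2 <- rbind(data.frame(barcode = "c0", x = 0, y = 0), coords2)
  cond2 <- c("B", cond2)
  nn2 <- knn_per_condition("c0", coords2, cond2, k = 2)
  expect_equal(nn2$A, c("a1", "a2"))

  # k = full condition size returns everyone
  nn3 <- knn_per_condition("center", coords, cond, k = 3)
  expect_setequal(nn3$B, paste0("b", 1:3))

  # skip signal when a condition is too small
  expect_null(knn_per_condition("center", coords, cond, k = 4))
})

test_that("distance ties break to the lexicographically smaller barcode", {
  coords <- data.frame(barcode = c("z_far", "m_tie", "a_tie", "ctr"),
                       x = c(5, 1, -1, 0), y = 0)
  cond <- c("B", "B", "B", "A")
  nn <- knn_per_condition("ctr", coords, cond, k = 1)
  expect_equal(nn$B, "a_tie")
})

test_that("knn_per_condition matches exhaustive search on random layouts", {
  withr::local_seed(99)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    coords <- data.frame(barcode = sprintf("bc%03d", sample(900, n)),
                         x = round(runif(n), 2), y = round(runif(n), 2))
    cond <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.5, 0.5))
    if (min(table(cond)) < 4) next
    k <- sample(2:min(table(cond)), 1)
    center <- sample(coords$barcode, 1)
    expect_identical(knn_per_condition(center, coords, cond, k),
                     knn_oracle(center, coords, cond, k))
  }
})

test_that("the vectorized all-centre search agrees with the public kNN", {
  withr::local_seed(17)
  n <- 80
  coords <- data.frame(barcode = sprintf("bc%03d", sample(500, n)),
                       x = runif(n), y = runif(n))
  cond <- rep(c("A", "B"), each = n / 2)
  centers <- sample(coords$barcode, 10)
  nn <- perturbmap:::knn_all(coords, cond, 5, centers)
  for (i in seq_along(centers)) {
    single <- knn_per_condition(centers[i], coords, cond, 5)
    expect_equal(nn$A[i, ], single$A)
    expect_equal(nn$B[i, ], single$B)
  }
})

test_that("barcode_auc saturates on disjoint supports and stays null on noise", {
  withr::local_seed(23)
  k <- 6
  X <- matrix(0, 2 * k, 40,
              dimnames = list(sprintf("c%02d", 1:(2 * k)),
                              sprintf("g%02d", 1:40)))
  X[1:k, 1:20] <- rpois(k * 20, 8)
  X[(k + 1):(2 * k), 21:40] <- rpois(k * 20, 8)
  y <- rep(0:1, each = k)
  p <- magellan_params(k = k, n_repeats = 10, rng_seed = 1)
  aucs <- barcode_auc(X, y, p, seed = 5)
  expect_equal(unname(aucs), rep(1, 10))

  # a single 40-cell window has across-dataset null sd ~0.08, so the +-0.07
  # calibration band is checked on the mean over several label shuffles
  Xn <- matrix(rnorm(40 * 200), 40,
               dimnames = list(sprintf("c%02d", 1:40),
                               sprintf("g%03d", 1:200)))
  p50 <- magellan_params(k = 20, n_repeats = 50, rng_seed = 1)
  nulls <- vapply(1:6, function(s) {
    yn <- withr::with_seed(s, sample(rep(0:1, each = 20)))
    anull <- barcode_auc(Xn, yn, p50, seed = 11)
    expect_length(anull, 50L)
    mean(anull)
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.07)
})

# shared small simulation for the map-level tests
map_sim <- local({
  p <- splat_params(n_genes = 250, n_barcodes = 160, de_fac_loc = 1.2,
                    seed = 41)
  ds <- simulate_spatial_pattern("half_border", p)
  list(ds = ds, features = normalize_log1p_cpm(ds$counts))
})

test_that("prioritize_map scores every labelled barcode and finds the border", {
  prm <- magellan_params(k = 8, n_repeats = 5, rng_seed = 7)
  map <- prioritize_map(map_sim$features, map_sim$ds$coords,
                        map_sim$ds$conditions, prm)
  sc <- map$scores
  expect_equal(nrow(sc), nrow(map_sim$ds$coords))
  expect_false(any(sc$skipped))
  expect_equal(dim(map$auc_samples), c(nrow(sc), 5L))
  expect_equal(sc$mean_auc, unname(rowMeans(map$auc_samples)))

  perturbed <- map_sim$ds$truth_barcodes$intensity > 0.5
  expect_gt(mean(sc$mean_auc[perturbed]) - mean(sc$mean_auc[!perturbed]),
            0.2)

  # determinism: bit-identical maps under the same seed
  map2 <- prioritize_map(map_sim$features, map_sim$ds$coords,
                         map_sim$ds$conditions, prm)
  expect_identical(map$auc_samples, map2$auc_samples)

  # barcode subsetting restricts scoring but not the neighbour pool
  sub <- map_sim$ds$coords$barcode[1:10]
  map3 <- prioritize_map(map_sim$features, map_sim$ds$coords,
                         map_sim$ds$conditions, prm, barcodes = sub)
  expect_equal(map3$scores$barcode, sub)
  expect_identical(map3$auc_samples[sub, ], map$auc_samples[sub, ])
})

test_that("maps are invariant under rigid motions of the coordinates", {
  prm <- magellan_params(k = 6, n_repeats = 3, rng_seed = 13)
  map_a <- prioritize_map(map_sim$features, map_sim$ds$coords,
                          map_sim$ds$conditions, prm,
                          barcodes = map_sim$ds$coords$barcode[1:25])
  th <- 0.6
  co <- map_sim$ds$coords
  rot <- data.frame(barcode = co$barcode,
                    x = cos(th) * co$x - sin(th) * co$y + 3,
                    y = sin(th) * co$x + cos(th) * co$y - 1)
  map_b <- prioritize_map(map_sim$features, rot, map_sim$ds$conditions, prm,
                          barcodes = co$barcode[1:25])
  expect_identical(map_a$auc_samples, map_b$auc_samples)
})

test_that("a condition too small for k skips everything with a warning", {
  co <- map_sim$ds$coords
  cond <- map_sim$ds$conditions
  few_b <- c(names(cond)[cond == "A"], head(names(cond)[cond == "B"], 3))
  expect_warning(
    map <- prioritize_map(map_sim$features, co[co$barcode %in% few_b, ],
                          cond[few_b], magellan_params(k = 8, n_repeats = 2)),
    "fewer than k")
  expect_true(all(map$scores$skipped))
  expect_equal(nrow(map$scores), length(few_b))
  expect_match(unique(map$scores$reason), "insufficient")
})

test_that("maps at different k are concordant", {
  p <- splat_params(n_genes = 250, n_barcodes = 200, de_fac_loc = 1.2,
                    seed = 51)
  ds <- simulate_spatial_pattern("linear_gradient", p)
  f <- normalize_log1p_cpm(ds$counts)
  m1 <- prioritize_map(f, ds$coords, ds$conditions,
                       magellan_params(k = 20, n_repeats = 8, rng_seed = 3))
  m2 <- prioritize_map(f, ds$coords, ds$conditions,
                       magellan_params(k = 50, n_repeats = 8, rng_seed = 3))
  expect_gt(cor(m1$scores$mean_auc, m2$scores$mean_auc), 0.7)
})

test_that("convergence_diagnostic splits and correlates half-means", {
  m <- rbind(bc1 = rep(0.6, 10), bc2 = rep(0.9, 10))
  cd <- convergence_diagnostic(m)
  expect_equal(cd$half_means$first_half, c(0.6, 0.9))
  expect_equal(cd$half_means$second_half, c(0.6, 0.9))
  expect_true(cd$degenerate)  # < 3 barcodes: correlation undefined
  expect_true(is.na(cd$correlation))

  # constant samples across many barcodes: degenerate, halves equal
  mc <- matrix(0.7, 10, 8, dimnames = list(sprintf("b%d", 1:10), NULL))
  cdc <- convergence_diagnostic(mc)
  expect_true(cdc$degenerate)
  expect_equal(cdc$half_means$first_half, cdc$half_means$second_half)

  expect_error(convergence_diagnostic(matrix(0.5, 5, 7)), "even number")

  withr::local_seed(2)
  spread <- matrix(rep(seq(0.4, 0.9, length.out = 20), each = 40) +
                   rnorm(800, sd = 0.02), 20, 40, byrow = TRUE,
                   dimnames = list(sprintf("b%02d", 1:20), NULL))
  cds <- convergence_diagnostic(spread)
  expect_false(cds$degenerate)
  expect_gt(cds$correlation, 0.9)
})

test_that("magellan_params validates its invariants", {
  expect_error(magellan_params(k = 2, n_folds = 3))
  expect_error(magellan_params(n_repeats = 0))
  expect_error(magellan_params(distance = "manhattan"))
  p <- magellan_params()
  expect_equal(p$k, 20L)
  expect_equal(p$n_repeats, 50L)
  expect_equal(p$n_folds, 3L)
})
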